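#include <R.h>
#include <Rinternals.h>
#include <openssl/evp.h>

/* PBKDF2-HMAC-SHA256 via libcrypto; passphrase and salt arrive as raw
 * vectors, the derived key is returned as a raw vector of dklen bytes. */
SEXP C_pbkdf2_sha256(SEXP pass, SEXP salt, SEXP iterations, SEXP dklen)
{
    int iter = asInteger(iterations);
    int dk = asInteger(dklen);

    if (TYPEOF(pass) != RAWSXP || TYPEOF(salt) != RAWSXP)
        error("passphrase and salt must be raw vectors");
    if (iter == NA_INTEGER || iter < 1)
        error("iterations must be a positive integer");
    if (dk == NA_INTEGER || dk < 1 || dk > 1024)
        error("derived key length out of range");

    SEXP out = PROTECT(allocVector(RAWSXP, dk));
    if (!PKCS5_PBKDF2_HMAC((const char *) RAW(pass), LENGTH(pass),
                           RAW(salt), LENGTH(salt),
                           iter, EVP_sha256(), dk, RAW(out)))
        error("PBKDF2 key derivation failed");
    UNPROTECT(1);
    return out;
}

static const R_CallMethodDef CallEntries[] = {
    {"C_pbkdf2_sha256", (DL_FUNC) &C_pbkdf2_sha256, 4},
    {NULL, NULL, 0}
};

void R_init_drrseal(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
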