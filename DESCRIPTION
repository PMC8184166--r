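Package: drrseal
Title: Tamper Detection for DICOM Image Series via Sealed Digitally
    Reconstructed Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seals a CT-style DICOM image series against in-transit
    tampering and detects any insertion, deletion, or pixel modification in
    the transmitted series. The sender reconstructs an isotropic
    Hounsfield-unit volume from the sorted slices, computes a mean-projection
    digitally reconstructed radiograph (DRR), partitions it into an equal
    block grid traversed in zig-zag order, and AES-encrypts each block into a
    JSON sidecar manifest. The receiver regenerates the DRR from the received
    series and compares it with the decrypted blocks using per-block integer
    histograms and a global root-mean-square error, yielding a PASS/FAIL
    verdict. Includes a deterministic synthetic DICOM phantom generator, an
    adversary module simulating slice insertion, deletion, and pixel
    modification, and a benchmark harness that aggregates verification runs
    into a tidy results grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    openssl,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
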