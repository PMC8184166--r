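[
  {"tag": "0008,0016", "name": "SOPClassUID", "type_class": "type1"},
  {"tag": "0008,0018", "name": "SOPInstanceUID", "type_class": "type1"},
  {"tag": "0028,0010", "name": "Rows", "type_class": "type1"},
  {"tag": "0028,0011", "name": "Columns", "type_class": "type1"},
  {"tag": "0028,0100", "name": "BitsAllocated", "type_class": "type1"},
  {"tag": "7FE0,0010", "name": "PixelData", "type_class": "type1"},
  {"tag": "0010,0010", "name": "PatientName", "type_class": "type2"},
  {"tag": "0010,0020", "name": "PatientID", "type_class": "type2"},
  {"tag": "0020,1041", "name": "SliceLocation", "type_class": "type1c", "condition_tag": "0020,0032"}
]
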