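# Example cloverleaf structure specifications in tRNA-local 1-based
# coordinates. Each arm pairs a 5' interval with a 3' interval of equal
# length (the 3' interval is read inward when pairing). Structures are
# inputs to the stem analysis, not predictions made by this package.
#
# trnS(AGY) lacks the DHU arm, as is typical for metazoan mitochondria.
trnF:
  length: 72
  arms:
    AA:  {five: [1, 7],   three: [66, 72]}
    DHU: {five: [10, 13], three: [22, 25]}
    AC:  {five: [27, 31], three: [39, 43]}
    TPC: {five: [49, 53], three: [61, 65]}
  anticodon: [34, 36]
trnV:
  length: 72
  arms:
    AA:  {five: [1, 7],   three: [66, 72]}
    DHU: {five: [10, 13], three: [22, 25]}
    AC:  {five: [27, 31], three: [39, 43]}
    TPC: {five: [49, 53], three: [61, 65]}
  anticodon: [34, 36]
trnG:
  length: 69
  arms:
    AA:  {five: [1, 7],   three: [63, 69]}
    DHU: {five: [10, 12], three: [21, 23]}
    AC:  {five: [25, 29], three: [37, 41]}
    TPC: {five: [46, 50], three: [58, 62]}
  anticodon: [32, 34]
"trnS(AGY)":
  length: 66
  arms:
    AA:  {five: [1, 7],   three: [60, 66]}
    AC:  {five: [10, 14], three: [22, 26]}
    TPC: {five: [40, 44], three: [52, 56]}
  anticodon: [17, 19]
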