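# Default conserved-element library for avian control regions.
#
# provenance:
#   phylloscopus_cr1      - element sequence as determined in P. fuscatus CR1
#   approximate_consensus - approximate vertebrate consensus included only so
#                           the absence of the element is reportable; these
#                           are not expected to occur in passerine CR1.
#
# The E box is stored contiguously (the source listing breaks it with a
# space after position 17); same for the C box.
- box: C-string
  pattern: CCCCCCCCCTCCCCCCCC
  max_mismatch: 3
  expected_domain: I
  provenance: phylloscopus_cr1
- box: F
  pattern: GCGCTTCTCACGAGAACCGAGCTACTCAAT
  max_mismatch: 3
  expected_domain: II
  provenance: phylloscopus_cr1
- box: E
  pattern: GTTATTGGCGTCAGGGACAT
  max_mismatch: 3
  expected_domain: II
  provenance: phylloscopus_cr1
- box: D
  pattern: CCTCCCGTGGTAACTTCAGGACCAT
  max_mismatch: 3
  expected_domain: II
  provenance: phylloscopus_cr1
- box: C
  pattern: CTGCCCTTCACTGATACTAGTGGTCGGTT
  max_mismatch: 3
  expected_domain: II
  provenance: phylloscopus_cr1
- box: bird-similarity
  pattern: CACTGATGCACTTTG
  max_mismatch: 3
  expected_domain: II
  provenance: phylloscopus_cr1
- box: B
  pattern: TCCCATTCATGGAC
  max_mismatch: 3
  expected_domain: II
  provenance: phylloscopus_cr1
- box: CSB1
  pattern: TATATAATGCAATGGTCACCGGACATG
  max_mismatch: 3
  expected_domain: III
  provenance: phylloscopus_cr1
- box: CSB2
  pattern: CAAACCCCCCCTACCCCCC
  max_mismatch: 2
  expected_domain: III
  provenance: approximate_consensus
- box: CSB3
  pattern: TGCCAAACCCCAAAAACAAGA
  max_mismatch: 2
  expected_domain: III
  provenance: approximate_consensus
- box: OH
  pattern: AAAGACATAATAATGTCATGC
  max_mismatch: 2
  expected_domain: III
  provenance: approximate_consensus
- box: LSP
  pattern: TTAACAGTGCATAACGCTTAA
  max_mismatch: 2
  expected_domain: III
  provenance: approximate_consensus
- box: HSP
  pattern: AGGGATAAGCACCATGCTTGA
  max_mismatch: 2
  expected_domain: III
  provenance: approximate_consensus
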