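# Shared fixtures: everything is generated in code at test time.

synth_fixture <- function(seed = 7, ...) {
  generate_mitogenome(synth_config(seed = seed, ...))
}

default_domains <- function() {
  cr_domain_spec(c(1, 424), c(425, 859), c(860, 1104))
}

# a minimal hand-built record: two toy genes on a 60 bp circle
toy_record <- function() {
  seq <- paste0("ATGAAATTTCCCGGGTAA",              # 18 bp toy CDS (J)
                "ACGTACGTACGTACGTACGTACGT",        # filler
                "GGGCCCAAATTTGGGCCC")              # filler to 60
  mito_record("TOY1", "Toyus toyus", seq,
              features = gene_features(c("nad2", "trnF"),
                                       c(1L, 19L), c(18L, 42L),
                                       c("J", "J"), c(1L, NA)))
}

# standard cloverleaf spec used across tRNA tests (72 nt layout)
toy_cloverleaf <- function() {
  cloverleaf_spec("trnF",
                  list(AA = list(five = c(1, 7), three = c(66, 72)),
                       DHU = list(five = c(10, 13), three = c(22, 25)),
                       AC = list(five = c(27, 31), three = c(39, 43)),
                       TPC = list(five = c(49, 53), three = c(61, 65))),
                  anticodon = c(34, 36))
}

random_cds_set <- function(n_cds, min_codons = 20, max_codons = 80) {
  lapply(seq_len(n_cds), function(i) {
    n <- sample(min_codons:max_codons, 1)
    random_dna(3 * n)
  })
}

# independent 3-mer counting oracle for RSCU: naive stepping over each CDS
naive_codon_counts <- function(cds_set) {
  counts <- integer(0)
  for (s in unlist(cds_set)) {
    cc <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    cc <- cc[-length(cc)]
    for (codon in cc) counts[codon] <- (counts[codon] %||% 0L) + 1L
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
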