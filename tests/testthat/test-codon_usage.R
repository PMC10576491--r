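test_that("assemble_cds pads incomplete stops by the polyadenylation rule", {
  # CDS of length 1 mod 3 ending in T: stop recorded "T", padded to TAA
  body <- "ATGAAACCCGGG"
  rec <- mito_record("X", "Toy", paste0(body, "T", random_dna(20)),
                     features = gene_features("nad4", 1, 13, "J", 1))
  a <- assemble_cds(rec, "nad4")
  expect_identical(a$profile$stop_codon, "T")
  expect_true(a$profile$padded)
  expect_identical(substr(a$sequence, nchar(a$sequence) - 2,
                          nchar(a$sequence)), "TAA")
  # complete stop: no padding
  rec2 <- mito_record("X", "Toy", paste0("ATGAAATAA", random_dna(20)),
                      features = gene_features("nad1", 1, 9, "J", 1))
  b <- assemble_cds(rec2, "nad1")
  expect_identical(b$profile$start_codon, "ATG")
  expect_identical(b$profile$stop_codon, "TAA")
  expect_false(b$profile$padded)
})

test_that("assemble_cds returns the planted coding-sense N-strand gene", {
  g <- synth_fixture(seed = 8)
  a <- assemble_cds(g$record, "nad6")
  expect_identical(a$sequence, g$truth$cds$nad6$sequence)
  # and the planted incomplete stops round-trip
  expect_identical(assemble_cds(g$record, "nad2")$profile$stop_codon, "TA")
  expect_identical(assemble_cds(g$record, "nad4")$profile$stop_codon, "T")
})

test_that("internal stops and short CDS are rejected", {
  rec <- mito_record("X", "Toy", paste0("ATGTAACCCGGGTAA", random_dna(10)),
                     features = gene_features("nad1", 1, 15, "J", 1))
  expect_error(assemble_cds(rec, "nad1"), "internal stop")
  rec2 <- mito_record("X", "Toy", "ATGAC",
                      features = gene_features("nad1", 1, 5, "J", 1))
  expect_error(assemble_cds(rec2, "nad1"), "too short")
})

test_that("rscu matches hand-computed values", {
  # all six Leu codons once each -> every Leu RSCU is 1
  leu6 <- c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG")
  tab <- rscu(paste0("ATG", paste(leu6, collapse = ""), "TAA"))
  expect_equal(tab$rscu[tab$codon %in% leu6], rep(1, 6))
  # CTA x2 + CTG x1, no other Leu: rscu(CTA) = 2*6/3 = 4
  tab2 <- rscu("ATGCTACTACTGTAA")
  expect_equal(tab2$rscu[tab2$codon == "CTA"], 4)
  expect_equal(tab2$rscu[tab2$codon == "CTG"], 2)
  expect_equal(tab2$rscu[tab2$codon == "TTA"], 0)
  # sub-family display labels
  expect_identical(unique(tab2$family[tab2$codon %in% c("TTA", "TTG")]), "L1")
  expect_identical(unique(tab2$family[tab2$codon == "CTA"]), "L2")
  expect_identical(unique(tab2$family[tab2$codon %in% c("AGT", "AGC")]), "S1")
  expect_identical(unique(tab2$family[tab2$codon == "TCC"]), "S2")
})

test_that("rscu family sums, count-weighted means and order invariance hold", {
  set.seed(21)
  for (i in 1:20) {
    cds <- random_cds_set(sample(1:4, 1))
    tab <- rscu(cds)
    sums <- tapply(tab$rscu, tab$amino_acid, sum)
    sizes <- tapply(tab$rscu, tab$amino_acid, length)
    tots <- tapply(tab$count, tab$amino_acid, sum)
    nz <- tots > 0
    expect_equal(unname(sums[nz]), unname(sizes[nz]), tolerance = 1e-9)
    # mean RSCU across a family's codons is 1 whenever the family is used
    fm <- tapply(tab$rscu, tab$amino_acid, mean)
    expect_equal(as.numeric(fm[nz]), rep(1, sum(nz)), tolerance = 1e-9)
    # invariant to concatenation order
    tab_rev <- rscu(rev(cds))
    expect_equal(tab$rscu, tab_rev$rscu)
  }
})

test_that("rscu counts agree with the naive 3-mer oracle", {
  set.seed(22)
  cds <- random_cds_set(3)
  tab <- rscu(cds)
  oracle <- naive_codon_counts(cds)
  for (codon in tab$codon)
    expect_identical(tab$count[tab$codon == codon],
                     as.integer(oracle[codon] %||% 0L))
})

test_that("rscu skips ambiguous codons with a counter", {
  tab <- rscu("ATGNNNCTATAA")
  expect_identical(attr(tab, "skipped"), 1L)
  expect_equal(tab$count[tab$codon == "CTA"], 1L)
})

test_that("codon inventory reports verbatim codons, GTG starts included", {
  g <- synth_fixture(seed = 10)
  inv <- codon_inventory(g$record)
  expect_identical(nrow(inv), 13L)
  expect_true(all(inv$start_codon == "ATG"))
  expect_identical(inv$stop_codon[inv$gene == "nad2"], "TA")
  expect_identical(inv$stop_codon[inv$gene == "nad4"], "T")
  expect_identical(inv$stop_codon[inv$gene == "cox1"], "AGG")
  expect_identical(inv$stop_codon[inv$gene == "nad5"], "AGA")
  # a GTG-start gene is reported, not rejected
  rec <- mito_record("X", "Toy", paste0("GTGAAACCCTAG", random_dna(20)),
                     features = gene_features("nad3", 1, 12, "J", 1))
  inv2 <- suppressWarnings(codon_inventory(rec))
  expect_identical(inv2$start_codon[inv2$gene == "nad3"], "GTG")
  expect_identical(inv2$stop_codon[inv2$gene == "nad3"], "TAG")
})

test_that("an annotation-free record yields an empty inventory with 13 warnings", {
  rec <- mito_record("X", "Toy", random_dna(100))
  w <- capture_warnings(inv <- codon_inventory(rec))
  expect_length(w, 13)
  expect_identical(nrow(inv), 0L)
})
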