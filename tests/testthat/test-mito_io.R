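test_that("GenBank write/read round-trips a synthetic record", {
  g <- synth_fixture(seed = 3)
  tf <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g$record, tf)
  back <- read_genbank(tf)
  expect_length(back, 1)
  r2 <- back[[1]]
  expect_identical(r2$sequence, g$record$sequence)
  expect_identical(r2$features, g$record$features)
  expect_identical(r2$record_id, g$record$record_id)
  expect_identical(r2$species, g$record$species)
  expect_identical(r2$is_circular, TRUE)
  expect_equal(nrow(r2$features), 39)  # 37 genes + CR1 + CR2
})

test_that("feature labels resolve through the synonym table", {
  expect_identical(resolve_gene_name(c("ND2", "COI", "CYTB", "12S rRNA",
                                       "tRNA-Phe", "D-loop")),
                   c("nad2", "cox1", "cytb", "rrnS", "trnF", "CR1"))
  expect_true(is.na(resolve_gene_name("completely unknown")))
})

test_that("a record with a CDS labelled ND2 maps to nad2/PCG and unknowns warn", {
  gb <- c(
    "LOCUS       TST1 60 bp    DNA     circular VRT 01-JAN-2024",
    "DEFINITION  Toyus toyus mitochondrion.",
    "ACCESSION   TST1",
    "  ORGANISM  Toyus toyus",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    '                     /organism="Toyus toyus"',
    "     CDS             1..18",
    '                     /gene="ND2"',
    "                     /codon_start=1",
    "     tRNA            19..42",
    '                     /product="tRNA-Phe"',
    "     misc_feature    43..60",
    '                     /note="mystery element"',
    "ORIGIN",
    paste0("        1 atgaaatttc ccgggtaaac gtacgtacgt acgtacgtac",
           " gtgggcccaa atttgggccc"),
    "//")
  tf <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, tf)
  rec <- read_genbank(tf)[[1]]
  expect_identical(rec$features$name, c("nad2", "trnF"))
  expect_identical(rec$features$ftype, c("PCG", "tRNA"))
  expect_length(rec$warnings, 1)
  expect_match(rec$warnings, "unmappable")
})

test_that("extract_region handles wraps, strands and planted features", {
  rec <- mito_record("X1", "Toy", "ACGTACGTAC")
  expect_identical(extract_region(rec, 9, 2), "ACAC")
  expect_identical(extract_region(rec, 1, 4, "N"), "ACGT")  # palindrome
  expect_error(extract_region(rec, 0, 4), "out of range")
  expect_error(extract_region(mito_record("X2", "Toy", "ACGT",
                                          is_circular = FALSE), 3, 2),
               "circular")
  g <- synth_fixture(seed = 5)
  ft <- g$record$features
  rrnS <- ft[ft$name == "rrnS", ]
  expect_identical(extract_feature(g$record, "rrnS"),
                   substr(g$record$sequence, rrnS$start, rrnS$end))
})

test_that("J extraction is the reverse complement of N extraction", {
  rec <- mito_record("X1", "Toy", random_dna(200))
  for (iv in list(c(5, 60), c(100, 180), c(190, 20))) {
    expect_identical(extract_region(rec, iv[1], iv[2], "J"),
                     revcomp(extract_region(rec, iv[1], iv[2], "N")))
  }
})

test_that("a partition of the circle sums to genome length", {
  g <- synth_fixture(seed = 9)
  rec <- g$record
  cuts <- c(1, 3000, 9000, 16000)
  pieces <- mapply(function(s, e) extract_region(rec, s, e),
                   cuts, c(cuts[-1] - 1, rec$length_bp))
  expect_identical(sum(nchar(pieces)), rec$length_bp)
  # wrapping partition too
  p1 <- extract_region(rec, 100, 99)
  expect_identical(nchar(p1), rec$length_bp)
})

test_that("writer handles an annotation-free record and reader flags it", {
  rec <- mito_record("EMPTY1", "Toy", random_dna(120))
  tf <- withr::local_tempfile(fileext = ".gb")
  write_genbank(rec, tf)
  expect_error(read_genbank(tf), "annotation error")
})

test_that("record invariants are enforced", {
  expect_error(mito_record("X", "T", ""), "empty")
  expect_error(mito_record("X", "T", "ACGT",
                           features = gene_features("trnF", 1, 9, "J")),
               "outside")
  expect_error(mito_record("X", "T", "ACGTACGT", is_circular = FALSE,
                           features = gene_features("trnF", 6, 2, "J")),
               "wrapping")
  expect_error(gene_features("notagene", 1, 5, "J"), "unknown gene")
})

test_that("FASTA round trip preserves sequences", {
  seqs <- setNames(c(random_dna(50), random_dna(80)), c("a", "b"))
  tf <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, tf)
  expect_identical(read_fasta(tf), seqs)
})
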