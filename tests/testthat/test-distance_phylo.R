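test_that("p-distance matches hand counts on toy alignments", {
  ident <- alignment_matrix(setNames(c("ACGTAC", "ACGTAC"), c("a", "b")))
  expect_true(all(p_distance(ident)$d == 0))
  d <- p_distance(alignment_matrix(setNames(c("ACGT", "ACGA"),
                                            c("a", "b"))))$d
  expect_equal(d["a", "b"], 0.25)
  # complete deletion drops the gapped column for all pairs
  aln <- alignment_matrix(setNames(c("AC-T", "ACGT", "ACGA"),
                                   c("r1", "r2", "r3")))
  dc <- p_distance(aln, "complete")$d
  expect_equal(dc["r1", "r2"], 0)
  expect_equal(dc["r1", "r3"], 1 / 3)
  expect_equal(dc["r2", "r3"], 1 / 3)
  # pairwise deletion keeps the column for the ungapped pair
  dp <- p_distance(aln, "pairwise")$d
  expect_equal(dp["r2", "r3"], 1 / 4)
  expect_equal(dp["r1", "r2"], 0)
  # symmetry and zero diagonal
  expect_identical(dc, t(dc))
  expect_true(all(diag(dc) == 0))
})

test_that("deletion modes agree when there are no gaps or ambiguities", {
  set.seed(19)
  seqs <- setNames(vapply(1:4, function(i) random_dna(300), ""),
                   paste0("t", 1:4))
  aln <- alignment_matrix(seqs)
  expect_equal(p_distance(aln, "complete")$d, p_distance(aln, "pairwise")$d)
})

test_that("ambiguity codes are excluded and empty overlap errors", {
  aln <- alignment_matrix(setNames(c("ANNN", "A---"), c("a", "b")))
  expect_equal(p_distance(aln, "pairwise")$d["a", "b"], 0)
  aln2 <- alignment_matrix(setNames(c("ANN", "-AA"), c("a", "b")))
  expect_error(p_distance(aln2, "pairwise"), "no comparable sites")
})

test_that("cross-check against an independent raw-distance implementation", {
  set.seed(23)
  seqs <- setNames(vapply(1:5, function(i) random_dna(200), ""),
                   paste0("sp", 1:5))
  ours <- p_distance(alignment_matrix(seqs))$d
  bin <- ape::as.DNAbin(ape::as.alignment(lapply(seqs, function(s)
    strsplit(tolower(s), "")[[1]])))
  theirs <- as.matrix(ape::dist.dna(bin, model = "raw"))
  expect_equal(ours[rownames(theirs), colnames(theirs)], theirs,
               tolerance = 1e-12)
})

test_that("NJ recovers the additive 4-taxon split and 3-taxon closed form", {
  # tree ((A:1,B:2):1,(C:3,D:1)) -> additive distances
  d <- matrix(c(0, 3, 5, 3,
                3, 0, 6, 4,
                5, 6, 0, 4,
                3, 4, 4, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- ape::read.tree(text = neighbor_joining(d))
  expect_true(ape::is.monophyletic(tr, c("A", "B")) ||
                ape::is.monophyletic(tr, c("C", "D")))
  d3 <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  expect_identical(neighbor_joining(d3),
                   "(x:0.050000,y:0.150000,z:0.250000);")
})

test_that("NJ is deterministic on tie-heavy matrices and rejects bad input", {
  d <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(d) <- 0
  expect_identical(neighbor_joining(d), neighbor_joining(d))
  expect_silent(ape::read.tree(text = neighbor_joining(d)))
  d[1, 2] <- d[2, 1] <- NA
  expect_error(neighbor_joining(d), "non-finite")
})

test_that("NJ reconstructs random additive trees and matches ape's NJ", {
  set.seed(33)
  for (i in 1:10) {
    n <- sample(5:8, 1)
    phy <- ape::rtree(n, rooted = FALSE)
    d <- ape::cophenetic.phylo(phy)
    d <- d[sort(rownames(d)), sort(colnames(d))]
    ours <- ape::read.tree(text = neighbor_joining(d))
    expect_equal(ape::dist.topo(ape::unroot(ours), ape::unroot(phy)), 0,
                 ignore_attr = TRUE)
    theirs <- ape::nj(d)
    expect_equal(ape::dist.topo(ape::unroot(ours), ape::unroot(theirs)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("alignment readers agree on FASTA and relaxed PHYLIP", {
  seqs <- setNames(c("ACGTACGT", "ACGAACGT", "ACGTTCGT"),
                   c("sp1", "sp2", "sp3"))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, fa)
  ph <- withr::local_tempfile(fileext = ".phy")
  writeLines(c("3 8", paste(names(seqs), seqs)), ph)
  a1 <- read_alignment_fasta(fa)
  a2 <- read_alignment_phylip(ph)
  expect_identical(unclass(a1), unclass(a2))
})
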