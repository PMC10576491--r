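test_that("domain partition reproduces the 424/435/245 split and reassembles", {
  spec <- default_domains()
  cr <- random_dna(1104)
  parts <- partition_domains(cr, spec)
  expect_identical(nchar(parts$I), 424L)
  expect_identical(nchar(parts$II), 435L)
  expect_identical(nchar(parts$III), 245L)
  expect_identical(paste0(parts$I, parts$II, parts$III), cr)
  # even split of an arbitrary sequence reassembles
  s <- random_dna(300)
  p2 <- partition_domains(s, cr_domain_spec(c(1, 100), c(101, 200),
                                            c(201, 300)))
  expect_identical(paste0(p2$I, p2$II, p2$III), s)
  expect_error(partition_domains(random_dna(1104),
                                 cr_domain_spec(c(1, 424), c(425, 859),
                                                c(860, 1200))),
               "coordinate error")
  expect_error(cr_domain_spec(c(1, 424), c(430, 859), c(860, 1104)),
               "contiguous")
})

test_that("scan_motifs finds planted boxes exactly and within budget", {
  spec <- default_domains()
  lib <- motif_library()
  bird <- Filter(function(m) m$box == "bird-similarity", lib)[[1]]
  set.seed(77)
  cr <- strsplit(random_dna(1104), "")[[1]]
  cr[700:(700 + nchar(bird$pattern) - 1)] <- strsplit(bird$pattern, "")[[1]]
  hits <- scan_motifs(paste(cr, collapse = ""), list(bird), spec)
  expect_identical(hits$start, 700L)
  expect_identical(hits$mismatches, 0L)
  expect_identical(hits$domain, "II")
  # pattern beyond budget: no hit
  none <- scan_motifs("TTTT", list(list(box = "X", pattern = "AAAA",
                                        max_mismatch = 1)))
  expect_identical(nrow(none), 0L)
  # planted F box with 2 substitutions reports mismatches = 2
  f <- Filter(function(m) m$box == "F", lib)[[1]]
  fp <- strsplit(f$pattern, "")[[1]]
  fp[c(5, 20)] <- vapply(fp[c(5, 20)], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], "")
  cr2 <- strsplit(random_dna(600), "")[[1]]
  cr2[100:(99 + length(fp))] <- fp
  hit2 <- scan_motifs(paste(cr2, collapse = ""), list(f))
  expect_identical(hit2$start, 100L)
  expect_identical(hit2$mismatches, 2L)
})

test_that("zero-mismatch scanning agrees with naive substring search", {
  set.seed(41)
  for (i in 1:10) {
    s <- random_dna(400)
    pat <- substr(s, 151, 162)
    m <- list(list(box = "probe", pattern = pat, max_mismatch = 0))
    hit <- scan_motifs(s, m)
    naive <- as.integer(gregexpr(pat, s, fixed = TRUE)[[1]][1])
    expect_identical(hit$start, naive)
    expect_identical(hit$mismatches, 0L)
  }
})

test_that("C-string detection follows the interruption rules", {
  hits <- find_cstring("CCCCCCCCCTCCCCCCCC", min_len = 10,
                       max_interruptions = 1)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$length, 18L)
  expect_identical(nrow(find_cstring("CCCCC", min_len = 10)), 0L)
  # only the best single-interruption window, not the whole string
  h3 <- find_cstring("CCCTCCCTCCC", min_len = 5, max_interruptions = 1)
  expect_identical(nrow(h3), 1L)
  expect_identical(h3$length, 7L)
  expect_identical(h3$start, 1L)
  expect_error(find_cstring("CCCC", min_len = 4), ">= 5")
})

test_that("tandem repeats built from the observed CR2 units are recovered", {
  units <- cr2_repeat_units()
  set.seed(42); left <- random_dna(100)
  set.seed(43); right <- random_dna(100)
  s46 <- paste0(left, strrep(units[["fuscatus"]], 2), right)
  r46 <- find_tandem_repeats(s46, 10, 200, 1.8, 80)
  expect_gte(nrow(r46), 1)
  expect_identical(r46$period[1], 46L)
  expect_equal(round(r46$copy_number[1], 1), 2.0)
  expect_identical(r46$consensus[1], unname(units[["fuscatus"]]))
  set.seed(44); left <- random_dna(100)
  set.seed(45); right <- random_dna(100)
  u45 <- units[["proregulus"]]
  s45 <- paste0(left, strrep(u45, 2), substr(u45, 1, 14), right)
  r45 <- find_tandem_repeats(s45, 10, 200, 1.8, 80)
  expect_identical(r45$period[1], 45L)
  expect_equal(round(r45$copy_number[1], 1), 2.3)
})

test_that("random sequence yields no spurious repeat calls", {
  set.seed(1)
  s <- random_dna(500)
  hits <- find_tandem_repeats(s, 10, 200, 1.8, 90)
  expect_identical(nrow(hits), 0L)
})

test_that("planted (period, copies) combinations are recovered across seeds", {
  combos <- expand.grid(p = c(10, 20, 45, 46), cop = c(2.0, 2.5, 3.0))
  for (seed in 1:20) {
    set.seed(seed)
    k <- combos[sample(nrow(combos), 1), ]
    unit <- random_dna(k$p)
    reg_len <- round(k$p * k$cop)
    reps <- substr(strrep(unit, ceiling(k$cop)), 1, reg_len)
    uc <- strsplit(unit, "")[[1]]
    # flank guard bases so the planted extent is the maximal periodic one
    left <- random_dna(80)
    if (substr(left, 80, 80) == uc[k$p])
      substr(left, 80, 80) <- setdiff(c("A", "C", "G", "T"), uc[k$p])[1]
    nxt <- uc[(reg_len %% k$p) + 1]
    right <- random_dna(80)
    if (substr(right, 1, 1) == nxt)
      substr(right, 1, 1) <- setdiff(c("A", "C", "G", "T"), nxt)[1]
    s <- paste0(left, reps, right)
    hits <- find_tandem_repeats(s, 5, 100, 1.8, 80)
    expect_gte(nrow(hits), 1)
    expect_identical(hits$period[1], as.integer(k$p))
    # a flank base continuing the periodicity may be absorbed, so allow
    # slightly more than one base of slack on the fractional copy count
    expect_equal(hits$copy_number[1], k$cop, tolerance = 0.15)
    # conservation: copy_number x period = region length before rounding
    expect_equal(hits$copy_number[1] * hits$period[1],
                 hits$end[1] - hits$start[1] + 1, tolerance = 1e-9)
    # consensus of identical planted units is the unit (up to the cyclic
    # rotation induced by absorbed flank bases)
    rots <- vapply(seq_len(k$p), function(r)
      paste0(substr(unit, r, k$p), substr(unit, 1, r - 1)), "")
    expect_true(hits$consensus[1] %in% rots)
  }
})
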