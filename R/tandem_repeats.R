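# Tandem-repeat detection: k-mer-seeded period candidates, identity-bounded
# greedy extension along the (i, i+p) match diagonal, boundary refinement by
# consensus score, and columnwise majority consensus. This is a deliberate
# simplification of full wraparound-DP repeat finders: no indels inside
# units, substitutions only.

TR_SEED_K <- 8L
TR_MAX_TRIM <- 12L    # boundary refinement range per end (bases)
TR_SCORE_DROP <- 12L  # extension stops this far below the running maximum
TR_MM_PENALTY <- 5L   # mismatch cost relative to a +1 match

#' Detect tandem repeats in a sequence
#'
#' Candidate periods come from recurrence distances of exact 8-mers. For a
#' candidate period p, the match diagonal (positions i with
#' `seq[i] == seq[i+p]`) is extended greedily from the seed while the run
#' identity stays at or above `min_identity`; the repeat region is then
#' refined by trying small trims at both ends and keeping the
#' consensus-score-maximal region. The consensus is the columnwise majority
#' over the stacked units (ties resolved to the first unit's base);
#' `copy_number` is region length / period (reported to 1 decimal, stored
#' unrounded). Overlapping detections are resolved highest score first.
#'
#' @param seq DNA string.
#' @param min_period,max_period period search range (bp).
#' @param min_copies minimum copy number of a reported repeat.
#' @param min_identity minimum percent identity of region vs consensus.
#' @return data.frame (start, end, period, copy_number, consensus,
#'   pct_identity, score), best score first.
#' @export
find_tandem_repeats <- function(seq, min_period = 10L, max_period = 200L,
                                min_copies = 1.8, min_identity = 80) {
  sc <- strsplit(toupper(seq), "")[[1]]
  L <- length(sc)
  if (min_period < 2L) stop("min_period must be >= 2")
  max_period <- min(max_period, floor(L / min_copies))
  if (max_period < min_period) return(empty_repeat_df())
  cands <- repeat_candidates(sc, min_period, max_period)
  hits <- list()
  for (ci in seq_len(nrow(cands))) {
    pos <- cands$pos[ci]
    p <- cands$period[ci]
    covered <- FALSE
    for (h in hits) {
      if (h$period == p && pos >= h$start && pos <= h$end) {
        covered <- TRUE
        break
      }
    }
    if (covered) next
    reg <- extend_diagonal(sc, pos, p, min_identity)
    reg <- refine_region(sc, reg$a, reg$b, p, min_copies)
    if (is.null(reg)) next
    len <- reg$b - reg$a + 1L
    if (len / p < min_copies) next
    if (reg$identity < min_identity) next
    hits[[length(hits) + 1L]] <-
      list(start = reg$a, end = reg$b, period = p,
           copy_number = len / p, consensus = reg$consensus,
           pct_identity = reg$identity, score = reg$score)
  }
  if (!length(hits)) return(empty_repeat_df())
  df <- do.call(rbind, lapply(hits, as.data.frame,
                              stringsAsFactors = FALSE))
  df <- df[order(-df$score, df$start), , drop = FALSE]
  kept <- df[0, ]
  for (k in seq_len(nrow(df))) {
    row <- df[k, ]
    if (!nrow(kept) || all(row$end < kept$start | row$start > kept$end))
      kept <- rbind(kept, row)
  }
  rownames(kept) <- NULL
  kept
}

empty_repeat_df <- function() {
  data.frame(start = integer(), end = integer(), period = integer(),
             copy_number = numeric(), consensus = character(),
             pct_identity = numeric(), score = numeric(),
             stringsAsFactors = FALSE)
}

# (pos, period) candidates from consecutive occurrences of each 8-mer
repeat_candidates <- function(sc, min_period, max_period) {
  L <- length(sc)
  k <- TR_SEED_K
  if (L < k + min_period)
    return(data.frame(pos = integer(), period = integer()))
  n <- L - k + 1L
  kmers <- vapply(seq_len(n), function(i)
    paste(sc[i:(i + k - 1L)], collapse = ""), character(1))
  grp <- split(seq_len(n), kmers)
  pos <- integer()
  per <- integer()
  for (g in grp) {
    if (length(g) < 2) next
    d <- diff(g)
    ok <- d >= min_period & d <= max_period
    pos <- c(pos, g[-length(g)][ok])
    per <- c(per, d[ok])
  }
  out <- unique(data.frame(pos = pos, period = per))
  out[order(out$period, out$pos), , drop = FALSE]
}

# Greedy extension of the (i, i+p) match diagonal around a seed using a
# +1/-1 match/mismatch score; each direction stops when the running score
# drops TR_SCORE_DROP below its maximum and is trimmed back to the
# maximum. Returns region [a, b] in sequence coordinates (b includes the
# trailing p bases of the last unit).
extend_diagonal <- function(sc, pos, p, min_identity) {
  L <- length(sc)
  i <- pos
  j <- min(pos + TR_SEED_K - 1L, L - p)
  # right
  s <- 0L; smax <- 0L; jbest <- j; t <- j + 1L
  while (t + p <= L) {
    s <- s + if (sc[t] == sc[t + p]) 1L else -TR_MM_PENALTY
    if (s > smax) { smax <- s; jbest <- t }
    if (smax - s > TR_SCORE_DROP) break
    t <- t + 1L
  }
  j <- jbest
  # left
  s <- 0L; smax <- 0L; ibest <- i; t <- i - 1L
  while (t >= 1L) {
    s <- s + if (sc[t] == sc[t + p]) 1L else -TR_MM_PENALTY
    if (s > smax) { smax <- s; ibest <- t }
    if (smax - s > TR_SCORE_DROP) break
    t <- t - 1L
  }
  i <- ibest
  list(a = i, b = j + p)
}

# Try small trims at each end; keep the consensus-score-maximal region.
refine_region <- function(sc, a0, b0, p, min_copies) {
  best <- NULL
  min_len <- ceiling(min_copies * p)
  for (lt in 0:min(TR_MAX_TRIM, b0 - a0)) {
    for (rt in 0:min(TR_MAX_TRIM, b0 - a0 - lt)) {
      a <- a0 + lt
      b <- b0 - rt
      len <- b - a + 1L
      if (len < min_len) next
      cs <- region_consensus(sc, a, b, p)
      # signed score (match +1, mismatch -TR_MM_PENALTY) trims junk flanks
      signed <- (1L + TR_MM_PENALTY) * cs$score - TR_MM_PENALTY * len
      if (is.null(best) || signed > best$signed ||
          (signed == best$signed && len > (best$b - best$a + 1L))) {
        best <- c(list(a = a, b = b, signed = signed), cs)
      }
    }
  }
  best
}

# Columnwise majority consensus (ties -> first unit's base), plus the
# number of region positions matching the consensus (score) and percent
# identity.
region_consensus <- function(sc, a, b, p) {
  len <- b - a + 1L
  idx <- a:b
  col <- (idx - a) %% p + 1L
  cons <- character(p)
  score <- 0L
  for (c0 in seq_len(p)) {
    bases <- sc[idx[col == c0]]
    tt <- table(bases)
    mx <- max(tt)
    top <- names(tt)[tt == mx]
    cons[c0] <- if (length(top) == 1L) top else {
      first <- bases[1]  # base from the earliest unit covering this column
      if (first %in% top) first else top[1]
    }
    score <- score + sum(bases == cons[c0])
  }
  list(consensus = paste(cons, collapse = ""),
       score = score, identity = 100 * score / len)
}
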