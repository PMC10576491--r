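# Control-region annotation: ETAS/central/CSB domain partitioning,
# conserved-box scanning by Hamming distance, and C-string detection.
# All coordinates are CR-local and 1-based.

#' Control-region domain specification
#'
#' Three contiguous, non-overlapping, ordered domains in CR-local 1-based
#' coordinates: ETAS domain I, central conserved domain II, CSB domain III.
#'
#' @param d1,d2,d3 length-2 integer vectors (start, end).
#' @return Object of class `CRDomainSpec`.
#' @examples
#' cr_domain_spec(c(1, 424), c(425, 859), c(860, 1104))
#' @export
cr_domain_spec <- function(d1, d2, d3) {
  b <- rbind(I = d1, II = d2, III = d3)
  if (any(b[, 2] < b[, 1])) stop("domain end before start")
  if (b["II", 1] != b["I", 2] + 1 || b["III", 1] != b["II", 2] + 1)
    stop("domains must be contiguous and ordered I < II < III")
  structure(list(boundaries = b), class = "CRDomainSpec")
}

#' Partition a control region into its three domains
#'
#' @param cr_seq control-region DNA string.
#' @param spec a [cr_domain_spec()] whose boundaries lie within the
#'   sequence.
#' @return Named list of the three subsequences (`I`, `II`, `III`); their
#'   concatenation reproduces `cr_seq` over the spanned range.
#' @export
partition_domains <- function(cr_seq, spec) {
  stopifnot(inherits(spec, "CRDomainSpec"))
  b <- spec$boundaries
  if (max(b) > nchar(cr_seq))
    stop(sprintf("coordinate error: boundary %d beyond %d nt sequence",
                 max(b), nchar(cr_seq)))
  out <- lapply(rownames(b), function(d)
    substr(cr_seq, b[d, 1], b[d, 2]))
  names(out) <- rownames(b)
  out
}

domain_of_position <- function(pos, spec) {
  if (is.null(spec)) return(NA_character_)
  b <- spec$boundaries
  hit <- rownames(b)[pos >= b[, 1] & pos <= b[, 2]]
  if (length(hit)) hit[1] else NA_character_
}

#' Load the default conserved-element motif library
#'
#' @param path optional YAML path (defaults to the shipped library, which
#'   contains the F/E/D/C/bird-similarity/B boxes, C-string and CSB1, plus
#'   approximate-consensus CSB2/CSB3/OH/LSP/HSP entries so their absence is
#'   reportable).
#' @return List of motif definitions (box, pattern, max_mismatch,
#'   expected_domain, provenance).
#' @export
motif_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cr_motifs.yaml", package = "mitochar")
  yaml::read_yaml(path)
}

# Hamming distances of a pattern against all windows of seq.
hamming_profile <- function(seq_chars, pattern) {
  p <- strsplit(toupper(pattern), "")[[1]]
  m <- length(p)
  L <- length(seq_chars)
  if (L < m) return(integer(0))
  d <- integer(L - m + 1L)
  for (j in seq_len(m))
    d <- d + (seq_chars[j:(j + L - m)] != p[j])
  d
}

#' Scan a control region for conserved boxes
#'
#' For each motif, the minimum-Hamming-distance window within the motif's
#' mismatch budget is reported (ties broken by leftmost start). Motifs with
#' no window within budget are simply absent from the result, mirroring
#' how elements like CSB2/CSB3 are reported as not identified.
#'
#' @param cr_seq control-region DNA string.
#' @param library list of motif definitions, see [motif_library()].
#' @param spec optional [cr_domain_spec()] used to label each hit's domain.
#' @return data.frame (box, start, end, mismatches, matched_seq, domain).
#' @export
scan_motifs <- function(cr_seq, library = motif_library(), spec = NULL) {
  if (!length(library)) stop("empty motif library")
  sc <- strsplit(toupper(cr_seq), "")[[1]]
  rows <- list()
  for (m in library) {
    prof <- hamming_profile(sc, m$pattern)
    if (!length(prof)) next
    best <- min(prof)
    if (best > m$max_mismatch) next
    start <- which(prof == best)[1]
    end <- start + nchar(m$pattern) - 1L
    rows[[length(rows) + 1L]] <- data.frame(
      box = m$box, start = start, end = end, mismatches = best,
      matched_seq = substr(cr_seq, start, end),
      domain = domain_of_position(start, spec),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(box = character(), start = integer(), end = integer(),
                      mismatches = integer(), matched_seq = character(),
                      domain = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Find C-strings (poly-C runs with limited single-base interruptions)
#'
#' A C-string is a maximal run of C allowing up to `max_interruptions`
#' single non-C bases, each flanked by at least one C on both sides.
#' Overlapping candidates are reduced to maximal non-overlapping hits
#' (longest first, leftmost on ties).
#'
#' @param cr_seq DNA string.
#' @param min_len minimum reported length (>= 5).
#' @param max_interruptions maximum number of single-base interruptions.
#' @return data.frame (start, end, length).
#' @examples
#' find_cstring("CCCCCCCCCTCCCCCCCC", min_len = 10)  # one 18-nt hit
#' @export
find_cstring <- function(cr_seq, min_len = 10L, max_interruptions = 1L) {
  if (min_len < 5) stop("min_len must be >= 5")
  sc <- strsplit(toupper(cr_seq), "")[[1]]
  r <- rle(sc == "C")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  crun <- which(r$values)
  if (!length(crun)) return(empty_cstring_df())
  # candidate: C-runs i..j chained by single-base gaps, j - i interruptions
  cands <- list()
  for (a in seq_along(crun)) {
    i <- crun[a]
    j <- i
    ints <- 0L
    repeat {
      len <- ends[j] - starts[i] + 1L
      cands[[length(cands) + 1L]] <- c(starts[i], ends[j], len)
      nxt <- j + 2L  # next C-run separated by one interruption run
      if (nxt > length(r$lengths) || !r$values[nxt] ||
          r$lengths[j + 1L] != 1L || ints + 1L > max_interruptions) break
      ints <- ints + 1L
      j <- nxt
    }
  }
  df <- as.data.frame(do.call(rbind, cands))
  names(df) <- c("start", "end", "length")
  df <- df[df$length >= min_len, , drop = FALSE]
  if (!nrow(df)) return(empty_cstring_df())
  # greedy maximal non-overlapping: longest first, leftmost on ties
  df <- df[order(-df$length, df$start), , drop = FALSE]
  kept <- df[0, ]
  for (k in seq_len(nrow(df))) {
    row <- df[k, ]
    if (!nrow(kept) ||
        all(row$end < kept$start | row$start > kept$end))
      kept <- rbind(kept, row)
  }
  kept <- kept[order(kept$start), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

empty_cstring_df <- function() {
  data.frame(start = integer(), end = integer(), length = integer())
}
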