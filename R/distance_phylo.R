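# p-distance matrices on aligned sequence matrices and a neighbor-joining
# summary. Sites containing gaps, N or other ambiguity codes are treated
# as missing (excluded), never partially matched; the deletion mode
# follows the conventional complete/pairwise distinction (complete is the
# default, matching the common distance-tool default).

#' Construct an alignment matrix
#'
#' @param seqs named character vector of equal-length aligned sequences
#'   over A/C/G/T/-/N/ambiguity.
#' @return Object of class `AlignmentMatrix` (character matrix, taxa as
#'   rownames).
#' @export
alignment_matrix <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique taxon names")
  if (length(unique(nchar(seqs))) != 1)
    stop("alignment error: rows have unequal lengths")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- names(seqs)
  structure(mat, class = c("AlignmentMatrix", "matrix"))
}

#' Read an aligned FASTA file as an AlignmentMatrix
#' @param path FASTA path.
#' @return [alignment_matrix()].
#' @export
read_alignment_fasta <- function(path) {
  alignment_matrix(read_fasta(path))
}

#' Read a relaxed (sequential) PHYLIP alignment
#'
#' First line `ntaxa nsites`; each following non-empty line is
#' `name sequence` separated by whitespace.
#' @param path file path.
#' @return [alignment_matrix()].
#' @export
read_alignment_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hd <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  body <- lines[-1]
  if (length(body) != hd[1]) stop("parse error: taxon count mismatch")
  parts <- strsplit(trimws(body), "\\s+")
  seqs <- setNames(vapply(parts, function(p)
    paste(p[-1], collapse = ""), character(1)),
    vapply(parts, `[[`, "", 1L))
  if (any(nchar(seqs) != hd[2])) stop("parse error: site count mismatch")
  alignment_matrix(seqs)
}

#' Proportion-of-differing-sites (p) distance matrix
#'
#' @param aln an [alignment_matrix()] (or named character vector).
#' @param mode `"complete"` drops every column containing a gap or
#'   ambiguous base for all pairs; `"pairwise"` excludes such sites per
#'   pair.
#' @return Object of class `PDistanceMatrix`: list with `taxa`, symmetric
#'   matrix `d` of proportions, and `deletion_mode`.
#' @export
p_distance <- function(aln, mode = c("complete", "pairwise")) {
  mode <- match.arg(mode)
  if (!inherits(aln, "AlignmentMatrix")) aln <- alignment_matrix(aln)
  taxa <- rownames(aln)
  if (length(taxa) < 2) stop("need at least two taxa")
  valid <- matrix(aln %in% c("A", "C", "G", "T"), nrow = nrow(aln))
  if (mode == "complete") {
    keep <- apply(valid, 2, all)
    aln <- aln[, keep, drop = FALSE]
    valid <- valid[, keep, drop = FALSE]
  }
  n <- length(taxa)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- valid[i, ] & valid[j, ]
      m <- sum(ok)
      if (m == 0)
        stop(sprintf("undefined distance: no comparable sites for %s vs %s",
                     taxa[i], taxa[j]))
      d[i, j] <- d[j, i] <- sum(aln[i, ok] != aln[j, ok]) / m
    }
  }
  structure(list(taxa = taxa, d = d, deletion_mode = mode),
            class = "PDistanceMatrix")
}

#' Write a distance matrix as TSV (lower triangle) and full-square CSV
#' @param dm a [p_distance()] result.
#' @param path_tsv,path_csv output paths (either may be NULL to skip).
#' @return invisible NULL.
#' @export
write_distance_matrix <- function(dm, path_tsv = NULL, path_csv = NULL) {
  d <- round(dm$d, 4)
  if (!is.null(path_tsv)) {
    con <- file(path_tsv, "w")
    for (i in seq_along(dm$taxa)) {
      row <- c(dm$taxa[i],
               if (i > 1) format(d[i, 1:(i - 1)], trim = TRUE) else NULL)
      writeLines(paste(row, collapse = "\t"), con)
    }
    close(con)
  }
  if (!is.null(path_csv))
    utils::write.csv(d, path_csv)
  invisible(NULL)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration with two determinism rules: ties in the
#' Q-criterion are broken by the lexicographically smallest pair of
#' subtree labels, and a negative branch length is clamped to zero with
#' the deficit moved to its sister edge (their sum is preserved). The
#' unrooted tree is written with a trifurcating root and branch lengths to
#' 6 decimals.
#'
#' @param dm a [p_distance()] result, or a symmetric numeric matrix with
#'   dimnames.
#' @return Newick string.
#' @export
neighbor_joining <- function(dm) {
  D <- if (inherits(dm, "PDistanceMatrix")) dm$d else dm
  if (!all(is.finite(D))) stop("domain error: non-finite distances")
  labels <- rownames(D)
  n <- nrow(D)
  if (n < 2) stop("need at least two taxa")
  newick <- labels        # growing subtree strings
  sortkey <- labels       # smallest taxon label within each subtree
  fmt <- function(x) sprintf("%.6f", x)
  while (n > 3) {
    r <- rowSums(D)
    best <- NULL
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        q <- (n - 2) * D[i, j] - r[i] - r[j]
        key <- paste(sort(c(sortkey[i], sortkey[j])), collapse = "\r")
        if (is.null(best) || q < best$q - 1e-12 ||
            (abs(q - best$q) <= 1e-12 && key < best$key))
          best <- list(i = i, j = j, q = q, key = key)
      }
    }
    i <- best$i; j <- best$j
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)
    nn <- sprintf("(%s:%s,%s:%s)", newick[i], fmt(li), newick[j], fmt(lj))
    nk <- min(sortkey[i], sortkey[j])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    newick <- c(newick[keep], nn)
    sortkey <- c(sortkey[keep], nk)
    rownames(D2) <- colnames(D2) <- sortkey
    D <- D2
    n <- n - 1
  }
  if (n == 2)
    return(sprintf("(%s:%s,%s:%s);", newick[1], fmt(D[1, 2] / 2),
                   newick[2], fmt(D[1, 2] / 2)))
  # trifurcating root: three-point closed form, negatives clamped to zero
  x <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  y <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  z <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  sprintf("(%s:%s,%s:%s,%s:%s);",
          newick[1], fmt(max(x, 0)), newick[2], fmt(max(y, 0)),
          newick[3], fmt(max(z, 0)))
}
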