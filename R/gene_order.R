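# Circular gene orders: representation, comparison, strand census, and an
# exhaustive single-event tandem duplication-random loss (TDRL) search.
#
# An arrangement is an ordered, stranded list of genes on the circle,
# canonically rotated to start at the anchor (trnF by default, which is
# adjacent to rrnS in both the ancestral and the rearranged order). Two
# arrangements are equal iff some rotation makes them elementwise equal;
# rotation is a pure relabeling.

#' Construct a circular gene arrangement
#'
#' @param genes character vector of gene names in circular order.
#' @param strands character vector of `"J"`/`"N"`, one per gene.
#' @param anchor canonical rotation start (default `"trnF"`); if present,
#'   the stored order starts there.
#' @return Object of class `GeneArrangement`: data.frame (name, strand)
#'   with attribute `anchor`.
#' @export
gene_arrangement <- function(genes, strands, anchor = "trnF") {
  stopifnot(length(genes) == length(strands))
  if (!all(strands %in% c("J", "N"))) stop("strand must be 'J' or 'N'")
  non_cr <- genes[!genes %in% CR_NAMES]
  if (anyDuplicated(non_cr))
    stop("annotation error: duplicate non-CR gene names: ",
         paste(unique(non_cr[duplicated(non_cr)]), collapse = ", "))
  df <- data.frame(name = as.character(genes), strand = as.character(strands),
                   stringsAsFactors = FALSE)
  i <- match(anchor, df$name)
  if (!is.na(i) && i > 1L)
    df <- df[c(i:nrow(df), 1:(i - 1L)), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("GeneArrangement", "data.frame"), anchor = anchor)
}

#' Load a shipped gene-order template
#'
#' @param name `"phylloscopus"` (rearranged, duplicated control region) or
#'   `"ancestral_avian"` (typical Gallus-like order).
#' @param path optional path to a template YAML (defaults to the shipped
#'   file).
#' @return A [gene_arrangement()].
#' @export
gene_order_template <- function(name = c("phylloscopus", "ancestral_avian"),
                                path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "gene_orders.yaml", package = "mitochar")
  templates <- yaml::read_yaml(path)
  name <- if (length(name) > 1) name[1] else name
  if (!name %in% names(templates))
    stop("unknown gene-order template: ", name)
  tpl <- templates[[name]]
  gene_arrangement(vapply(tpl, `[[`, "", 1L), vapply(tpl, `[[`, "", 2L))
}

#' Extract the gene arrangement of an annotated record
#'
#' Features are sorted by circular start position and rotated to the
#' anchor, so records whose file happens to start mid-genome yield the same
#' arrangement.
#'
#' @param rec a [mito_record()] with at least two features.
#' @param anchor rotation anchor gene.
#' @return A [gene_arrangement()].
#' @export
extract_arrangement <- function(rec, anchor = "trnF") {
  ft <- rec$features
  if (nrow(ft) < 2) stop("record has fewer than two features")
  ord <- order(ft$start)
  gene_arrangement(ft$name[ord], ft$strand[ord], anchor = anchor)
}

rotations_of <- function(arr) {
  n <- nrow(arr)
  lapply(seq_len(n), function(k) {
    idx <- ((seq_len(n) + k - 2L) %% n) + 1L
    arr[idx, , drop = FALSE]
  })
}

#' Test equality of circular arrangements (rotation-aware)
#' @param a,b [gene_arrangement()] objects.
#' @return TRUE iff some rotation of `a` equals `b` elementwise (names and
#'   strands).
#' @export
arrangements_equal <- function(a, b) {
  if (nrow(a) != nrow(b)) return(FALSE)
  key_b <- paste(b$name, b$strand)
  for (rot in rotations_of(a)) {
    if (identical(paste(rot$name, rot$strand), key_b)) return(TRUE)
  }
  FALSE
}

#' Strand census over the 37-gene complement
#'
#' Control regions are excluded. The arrangement must cover the standard
#' avian complement; missing genes raise a completeness error listing the
#' absences.
#'
#' @param arr a [gene_arrangement()].
#' @return Named integer vector `c(J = , N = )` with `J + N = 37`.
#' @examples
#' strand_census(gene_order_template("phylloscopus"))
#' @export
strand_census <- function(arr) {
  genes <- arr[!arr$name %in% CR_NAMES, , drop = FALSE]
  missing <- setdiff(standard_gene_complement(), genes$name)
  if (length(missing))
    stop("completeness error: missing genes: ",
         paste(missing, collapse = ", "))
  c(J = sum(genes$strand == "J"), N = sum(genes$strand == "N"))
}

cr_base_name <- function(x) ifelse(x %in% CR_NAMES, "CR", x)

adjacency_pairs <- function(arr) {
  nm <- cr_base_name(arr$name)
  n <- length(nm)
  data.frame(from = nm, to = nm[c(2:n, 1L)], stringsAsFactors = FALSE)
}

#' Breakpoints between two circular gene orders
#'
#' Directed adjacencies in the J-strand reading order of `a` that are not
#' adjacencies of `b` (rotation-aware). CR1/CR2 are compared as a single
#' `CR` identity, so orders differing only in control-region multiplicity
#' remain comparable.
#'
#' @param a,b [gene_arrangement()] objects over the same gene universe (up
#'   to CR duplication).
#' @return data.frame (from, to) of breakpoint adjacencies; zero rows iff
#'   the arrangements are equal up to rotation.
#' @export
compare_orders <- function(a, b) {
  ua <- sort(unique(cr_base_name(a$name)))
  ub <- sort(unique(cr_base_name(b$name)))
  if (!identical(ua, ub))
    stop("domain error: arrangements have different gene sets")
  pa <- adjacency_pairs(a)
  pb <- adjacency_pairs(b)
  key_b <- paste(pb$from, pb$to, sep = "\r")
  bp <- pa[!paste(pa$from, pa$to, sep = "\r") %in% key_b, , drop = FALSE]
  rownames(bp) <- NULL
  bp
}

# ---- TDRL -------------------------------------------------------------

#' Apply a single TDRL event to an arrangement
#'
#' The contiguous block starting at circular position `start` of length
#' `length(survivors)` is duplicated in tandem; then, for each position of
#' the block, `"first"` keeps the upstream copy, `"second"` the downstream
#' copy, `"both"` keeps both. Strands are preserved (TDRL does not invert).
#'
#' @param arr ancestral [gene_arrangement()].
#' @param start 1-based circular index of the first block element in the
#'   stored rotation of `arr`.
#' @param survivors character vector over `{"first","second","both"}`.
#' @return The derived [gene_arrangement()].
#' @export
apply_tdrl <- function(arr, start, survivors) {
  n <- nrow(arr)
  k <- length(survivors)
  stopifnot(k >= 1, k <= n)
  idx <- ((start - 1L + 0:(k - 1L)) %% n) + 1L
  rest <- setdiff_circular(n, idx)
  block <- arr[idx, , drop = FALSE]
  keep1 <- block[survivors %in% c("first", "both"), , drop = FALSE]
  keep2 <- block[survivors %in% c("second", "both"), , drop = FALSE]
  new <- rbind(keep1, keep2, arr[rest, , drop = FALSE])
  rownames(new) <- NULL
  # no duplicate validation here: retain_both legitimately duplicates genes
  structure(new, class = c("GeneArrangement", "data.frame"),
            anchor = attr(arr, "anchor"))
}

# circular complement of idx, starting just after the block
setdiff_circular <- function(n, idx) {
  after <- (idx[length(idx)] %% n) + 1L
  ord <- ((after - 1L + 0:(n - 1L)) %% n) + 1L
  ord[!ord %in% idx]
}

# A survivor pattern of the form first^j second^(k-j) with no "both" leaves
# the order unchanged; such no-op events are excluded from the search.
is_noop_pattern <- function(survivors) {
  if (any(survivors == "both")) return(FALSE)
  sec <- which(survivors == "second")
  if (!length(sec)) return(TRUE)
  all(survivors[seq(min(sec), length(survivors))] == "second")
}

#' Exhaustive search for single TDRL explanations of a rearrangement
#'
#' Enumerates every contiguous block (length `<= max_block`) of the
#' ancestral circular order and every survivor pattern (genes in
#' `retain_both` may keep both copies), and returns the events whose
#' application yields the observed order. Control regions are matched by CR
#' identity, so an ancestral single CR can explain an observed CR1/CR2
#' pair when `"CR"` is in `retain_both`. No-op survivor patterns (which
#' reproduce the ancestral order trivially) are excluded, so identical
#' orders yield an empty result.
#'
#' @param ancestral,observed [gene_arrangement()] objects.
#' @param retain_both character vector of gene names allowed to keep both
#'   copies (use `"CR"` for the control region).
#' @param max_block maximum duplicated-block length (default 8, keeping the
#'   survivor enumeration exhaustive at desk scale).
#' @return List of solutions, each a list with `start`, `block`
#'   (data.frame of the duplicated genes), and `survivors`. Empty list
#'   means no single-event explanation exists.
#' @export
tdrl_search <- function(ancestral, observed, retain_both = character(),
                        max_block = 8L) {
  anc <- ancestral
  obs_key <- arrangement_key(observed)
  n <- nrow(anc)
  nm <- cr_base_name(anc$name)
  # Which genes must keep both copies is forced by the gene counts: a
  # single TDRL changes the copy number of gene g by +1 exactly when g
  # survives in both copies. Anything outside {0, +1}, or +1 for a gene
  # not in retain_both, rules out a single-event explanation outright.
  # Strand multisets must also agree (TDRL never inverts).
  cnt_a <- table(paste(nm, anc$strand))
  cnt_o <- table(paste(cr_base_name(observed$name), observed$strand))
  all_keys <- union(names(cnt_a), names(cnt_o))
  extra <- setNames(rep(0L, length(all_keys)), all_keys)
  extra[names(cnt_o)] <- extra[names(cnt_o)] + as.integer(cnt_o)
  extra[names(cnt_a)] <- extra[names(cnt_a)] - as.integer(cnt_a)
  if (any(extra < 0L | extra > 1L)) return(list())
  needed_keys <- names(extra)[extra == 1L]
  needed <- sub(" [JN]$", "", needed_keys)
  if (!all(needed %in% cr_base_name(retain_both))) return(list())
  if (!length(needed) && identical(arrangement_key(anc), obs_key))
    return(list())  # only no-op events reproduce an identical order
  solutions <- list()
  for (start in seq_len(n)) {
    for (k in seq_len(min(max_block, n))) {
      idx <- ((start - 1L + 0:(k - 1L)) %% n) + 1L
      both_pos <- which(nm[idx] %in% needed)
      if (length(both_pos) != length(needed)) next
      free <- setdiff(seq_len(k), both_pos)
      grid <- if (length(free))
        expand.grid(rep(list(c("first", "second")), length(free)),
                    stringsAsFactors = FALSE)
      else data.frame(row.names = 1)
      for (r in seq_len(nrow(grid))) {
        surv <- character(k)
        surv[both_pos] <- "both"
        if (length(free)) surv[free] <- as.character(grid[r, ])
        if (is_noop_pattern(surv)) next
        cand <- apply_tdrl(anc, start, surv)
        if (identical(arrangement_key(cand), obs_key)) {
          solutions[[length(solutions) + 1L]] <-
            list(start = start, block = anc[idx, , drop = FALSE],
                 survivors = surv)
        }
      }
    }
  }
  solutions
}

# Canonical rotation key for fast cyclic comparison: rotate to the unique
# anchor occurrence when possible, otherwise the lexicographically smallest
# rotation. CR names are normalized to "CR".
arrangement_key <- function(arr) {
  lab <- paste(cr_base_name(arr$name), arr$strand)
  n <- length(lab)
  anchor <- attr(arr, "anchor")
  ai <- which(cr_base_name(arr$name) == anchor)
  if (length(ai) == 1L) {
    idx <- ((ai - 1L + 0:(n - 1L)) %% n) + 1L
    return(paste(lab[idx], collapse = "|"))
  }
  keys <- vapply(seq_len(n), function(k) {
    idx <- ((k - 1L + 0:(n - 1L)) %% n) + 1L
    paste(lab[idx], collapse = "|")
  }, character(1))
  min(keys)
}
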