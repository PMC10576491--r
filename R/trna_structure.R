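# tRNA cloverleaf stem analysis. Structures are supplied as specifications
# (tRNA-local 1-based intervals per arm), not predicted here. Sequences are
# handled as DNA (T, not U); rendering as RNA is a display concern.

#' Cloverleaf structure specification
#'
#' @param trna_name canonical tRNA symbol.
#' @param arms named list over `AA`, `DHU`, `AC`, `TPC`; each element a
#'   list with `five` and `three` length-2 intervals of equal length (the
#'   3' interval is read inward when pairing). `DHU` may be omitted (as in
#'   mitochondrial trnS(AGY)).
#' @param anticodon length-2 interval of the anticodon triplet.
#' @return Object of class `CloverleafSpec`.
#' @export
cloverleaf_spec <- function(trna_name, arms, anticodon = NULL) {
  known <- c("AA", "DHU", "AC", "TPC")
  if (!all(names(arms) %in% known))
    stop("unknown arm name(s): ",
         paste(setdiff(names(arms), known), collapse = ", "))
  for (nm in names(arms)) {
    a <- arms[[nm]]
    if (diff(a$five) != diff(a$three))
      stop("spec error: unequal stem strand lengths in arm ", nm)
  }
  structure(list(trna_name = trna_name, arms = arms, anticodon = anticodon),
            class = "CloverleafSpec")
}

#' Load shipped example cloverleaf specifications
#' @param path optional YAML path.
#' @return Named list of [cloverleaf_spec()] objects.
#' @export
cloverleaf_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "trna_cloverleaf.yaml",
                        package = "mitochar")
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    arms <- lapply(raw[[nm]]$arms, function(a)
      list(five = unlist(a$five), three = unlist(a$three)))
    cloverleaf_spec(nm, arms, unlist(raw[[nm]]$anticodon))
  })
  setNames(out, names(raw))
}

classify_one_pair <- function(b5, b3) {
  pair <- sort(c(b5, b3))
  if (identical(pair, c("A", "T")) || identical(pair, c("C", "G")))
    "WatsonCrick"
  else if (identical(pair, c("G", "T")))
    "GU_wobble"
  else
    "mismatch"
}

#' Classify stem base pairs of a tRNA
#'
#' Each stem position pairs base i of the 5' interval with base i counted
#' inward from the end of the 3' interval. Categories depend only on the
#' unordered base pair: A-T and G-C are Watson-Crick, G-T (G-U in the RNA)
#' is a wobble pair, anything else a mismatch.
#'
#' @param seq tRNA DNA string.
#' @param spec a [cloverleaf_spec()] whose intervals lie within `seq`.
#' @return data.frame (arm, index, base5, base3, category).
#' @export
classify_pairs <- function(seq, spec) {
  stopifnot(inherits(spec, "CloverleafSpec"))
  sc <- strsplit(toupper(seq), "")[[1]]
  rows <- list()
  for (arm in names(spec$arms)) {
    a <- spec$arms[[arm]]
    if (max(a$five, a$three) > length(sc))
      stop("spec error: arm ", arm, " outside sequence")
    n <- a$five[2] - a$five[1] + 1L
    for (i in seq_len(n)) {
      b5 <- sc[a$five[1] + i - 1L]
      b3 <- sc[a$three[2] - i + 1L]
      rows[[length(rows) + 1L]] <-
        data.frame(arm = arm, index = i, base5 = b5, base3 = b3,
                   category = classify_one_pair(b5, b3),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-species stem conservation per arm
#'
#' For each arm, the percentage of stem columns (positions of both stem
#' strands) at which all species carry the identical base. Arms absent
#' from the spec are reported as `NA` (e.g. the DHU arm of trnS(AGY)).
#'
#' @param aligned_trnas named character vector (species -> tRNA string),
#'   pre-aligned to equal length; at least two species.
#' @param spec a [cloverleaf_spec()].
#' @return Named numeric vector over AA, DHU, AC, TPC (percent, or NA).
#' @export
stem_conservation <- function(aligned_trnas, spec) {
  if (length(aligned_trnas) < 2) stop("need at least two species")
  lens <- nchar(aligned_trnas)
  if (length(unique(lens)) != 1)
    stop("alignment error: unequal tRNA lengths")
  mat <- do.call(rbind, strsplit(toupper(aligned_trnas), ""))
  out <- setNames(rep(NA_real_, 4), c("AA", "DHU", "AC", "TPC"))
  for (arm in names(spec$arms)) {
    a <- spec$arms[[arm]]
    cols <- c(seq(a$five[1], a$five[2]), seq(a$three[1], a$three[2]))
    ident <- vapply(cols, function(cc)
      length(unique(mat[, cc])) == 1L, logical(1))
    out[arm] <- 100 * mean(ident)
  }
  out
}
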