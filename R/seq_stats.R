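# Base composition, A+T content, and strand-skew statistics.
#
# AT-skew = (A - T) / (A + T);  GC-skew = (G - C) / (G + C).
# Percentages are computed over unambiguous bases only; IUPAC ambiguity
# codes (including N) are counted under "other" and excluded from both the
# percentage denominators and the skew formulas. Internal values keep full
# precision; rounding (2 decimals for percentages, 4 for skews) happens
# only in reports.

#' Base composition and skew summary of a sequence
#'
#' @param seq non-empty DNA string.
#' @param label region label carried into reports.
#' @return Object of class `CompositionSummary`: list with `region_label`,
#'   `counts` (A/C/G/T/other), `pct` (percent of unambiguous bases),
#'   `at_content` (percent), `at_skew`, `gc_skew` (NA when the denominator
#'   is zero).
#' @examples
#' composition("GGC")$gc_skew   # (2-1)/(2+1)
#' @export
composition <- function(seq, label = "region") {
  seq <- toupper(as.character(seq))
  if (!nzchar(seq)) stop("domain error: empty sequence")
  af <- Biostrings::alphabetFrequency(Biostrings::DNAString(seq))
  counts <- c(A = unname(af[["A"]]), C = unname(af[["C"]]),
              G = unname(af[["G"]]), T = unname(af[["T"]]))
  other <- nchar(seq) - sum(counts)
  tot <- sum(counts)
  pct <- if (tot > 0) 100 * counts / tot else counts * NA_real_
  at <- counts[["A"]] + counts[["T"]]
  gc <- counts[["G"]] + counts[["C"]]
  structure(list(
    region_label = label,
    counts = c(counts, other = other),
    pct = pct,
    at_content = if (tot > 0) 100 * at / tot else NA_real_,
    at_skew = if (at > 0) (counts[["A"]] - counts[["T"]]) / at else NA_real_,
    gc_skew = if (gc > 0) (counts[["G"]] - counts[["C"]]) / gc else NA_real_
  ), class = "CompositionSummary")
}

#' @export
print.CompositionSummary <- function(x, ...) {
  cat(sprintf("Composition [%s]: n=%d (+%d ambiguous)\n", x$region_label,
              sum(x$counts[c("A", "C", "G", "T")]), x$counts[["other"]]))
  cat(sprintf("  A %.2f%%  C %.2f%%  G %.2f%%  T %.2f%% | A+T %.2f%%\n",
              x$pct[["A"]], x$pct[["C"]], x$pct[["G"]], x$pct[["T"]],
              x$at_content))
  cat(sprintf("  AT-skew %s  GC-skew %s\n",
              format(round(x$at_skew, 4)), format(round(x$gc_skew, 4))))
  invisible(x)
}

composition_row <- function(cs, present = TRUE) {
  data.frame(region = cs$region_label, present = present,
             A = cs$counts[["A"]], C = cs$counts[["C"]],
             G = cs$counts[["G"]], T = cs$counts[["T"]],
             other = cs$counts[["other"]],
             pct_A = cs$pct[["A"]], pct_C = cs$pct[["C"]],
             pct_G = cs$pct[["G"]], pct_T = cs$pct[["T"]],
             at_content = cs$at_content,
             at_skew = cs$at_skew, gc_skew = cs$gc_skew,
             stringsAsFactors = FALSE)
}

#' Composition by codon position
#'
#' Concatenates the in-frame coding-sense CDS set, removes each CDS's
#' terminal (stop) codon, and summarizes positions 1, 2 and 3 separately.
#'
#' @param cds_set list/vector of in-frame CDS strings (each length
#'   divisible by 3; incomplete stops must be pre-padded, see
#'   [assemble_cds()]). Optionally named so frame errors name the gene.
#' @return List of three `CompositionSummary` objects (`pos1`, `pos2`,
#'   `pos3`).
#' @export
codon_position_composition <- function(cds_set) {
  cds_set <- unlist(cds_set)
  bad <- which(nchar(cds_set) %% 3 != 0)
  if (length(bad)) {
    nm <- names(cds_set)[bad[1]]
    stop("frame error: CDS length not divisible by 3",
         if (!is.null(nm) && nzchar(nm)) paste0(" (", nm, ")") else "")
  }
  trimmed <- vapply(cds_set, function(s) substr(s, 1, nchar(s) - 3),
                    character(1))
  trimmed <- trimmed[nchar(trimmed) > 0]
  chars <- strsplit(paste(trimmed, collapse = ""), "")[[1]]
  pos <- (seq_along(chars) - 1L) %% 3L + 1L
  out <- lapply(1:3, function(p)
    composition(paste(chars[pos == p], collapse = ""),
                label = paste0("pos", p)))
  names(out) <- c("pos1", "pos2", "pos3")
  out
}

#' Per-region composition report for a record
#'
#' One row per region: whole genome, the concatenated 13 PCGs (coding
#' sense, termination codons removed), rrnS, rrnL, CR1 and CR2. Regions
#' absent from the annotation are flagged (`present = FALSE`), never
#' fabricated.
#'
#' @param rec a [mito_record()].
#' @return data.frame with counts, percentages, A+T content and skews.
#' @export
per_region_report <- function(rec) {
  rows <- list(composition_row(composition(rec$sequence, "whole_genome")))
  pcg_present <- intersect(PCG_NAMES, rec$features$name)
  if (length(pcg_present)) {
    cds <- vapply(pcg_present, function(g) {
      a <- assemble_cds(rec, g)
      substr(a$sequence, 1, nchar(a$sequence) - 3)  # drop (padded) stop
    }, character(1))
    rows[[length(rows) + 1L]] <-
      composition_row(composition(paste(cds, collapse = ""), "PCG"))
  } else {
    rows[[length(rows) + 1L]] <- missing_region_row("PCG")
  }
  for (g in c("rrnS", "rrnL", "CR1", "CR2")) {
    if (g %in% rec$features$name) {
      rows[[length(rows) + 1L]] <-
        composition_row(composition(extract_feature(rec, g), g))
    } else {
      rows[[length(rows) + 1L]] <- missing_region_row(g)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

missing_region_row <- function(label) {
  data.frame(region = label, present = FALSE,
             A = NA_integer_, C = NA_integer_, G = NA_integer_,
             T = NA_integer_, other = NA_integer_,
             pct_A = NA_real_, pct_C = NA_real_, pct_G = NA_real_,
             pct_T = NA_real_, at_content = NA_real_,
             at_skew = NA_real_, gc_skew = NA_real_,
             stringsAsFactors = FALSE)
}
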