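# MitoRecord: one annotated circular mitogenome. Coordinates are 1-based
# inclusive throughout (GenBank convention); a feature may wrap the origin
# (start > end) only on a circular record.

#' Construct a gene feature table
#'
#' @param name canonical gene symbols (see [gene_classes()]).
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"J"` (majority/heavy) or `"N"` (minority/light); mapped to
#'   GenBank +/- on write.
#' @param codon_start reading-frame offset 1-3 (PCGs only; `NA` otherwise).
#' @return data.frame with columns name, ftype, start, end, strand,
#'   codon_start.
#' @export
gene_features <- function(name = character(), start = integer(),
                          end = integer(), strand = character(),
                          codon_start = NA_integer_) {
  n <- length(name)
  if (length(codon_start) == 1L) codon_start <- rep(codon_start, n)
  ftype <- gene_class_of(name)
  if (n > 0 && anyNA(ftype))
    stop("unknown gene name(s): ", paste(name[is.na(ftype)], collapse = ", "))
  if (n > 0 && !all(strand %in% c("J", "N")))
    stop("strand must be 'J' or 'N'")
  data.frame(name = as.character(name), ftype = ftype,
             start = as.integer(start), end = as.integer(end),
             strand = as.character(strand),
             codon_start = as.integer(codon_start),
             stringsAsFactors = FALSE)
}

#' Construct an annotated mitogenome record
#'
#' @param record_id accession-like identifier.
#' @param species binomial species name.
#' @param sequence DNA string over the IUPAC alphabet (uppercased on input).
#' @param is_circular logical; origin-wrapping features are only legal on
#'   circular records.
#' @param features a data.frame as returned by [gene_features()].
#' @param warnings character vector of annotation warnings (e.g. unmappable
#'   features kept by the GenBank reader).
#' @return An object of class `MitoRecord`.
#' @examples
#' rec <- mito_record("X1", "Toy species", "ACGTACGTAC",
#'                    features = gene_features("trnF", 1, 4, "J"))
#' rec$length_bp
#' @export
mito_record <- function(record_id, species, sequence, is_circular = TRUE,
                        features = gene_features(), warnings = character()) {
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("empty sequence")
  if (grepl("[^ACGTRYSWKMBDHVN]", sequence))
    stop("sequence contains non-IUPAC characters")
  rec <- structure(list(record_id = as.character(record_id),
                        species = as.character(species),
                        sequence = sequence,
                        length_bp = nchar(sequence),
                        is_circular = isTRUE(is_circular),
                        features = features,
                        warnings = as.character(warnings)),
                   class = "MitoRecord")
  validate_mito_record(rec)
  rec
}

validate_mito_record <- function(rec) {
  stopifnot(inherits(rec, "MitoRecord"))
  if (rec$length_bp != nchar(rec$sequence))
    stop("length_bp does not match sequence length")
  ft <- rec$features
  if (nrow(ft) > 0) {
    if (any(ft$start < 1L | ft$start > rec$length_bp |
            ft$end < 1L | ft$end > rec$length_bp))
      stop("feature coordinates outside [1, length_bp]")
    wraps <- ft$start > ft$end
    if (any(wraps) && !rec$is_circular)
      stop("origin-wrapping feature on a non-circular record")
  }
  invisible(rec)
}

#' @export
print.MitoRecord <- function(x, ...) {
  cat(sprintf("MitoRecord %s (%s): %d bp, %s, %d features\n",
              x$record_id, x$species, x$length_bp,
              if (x$is_circular) "circular" else "linear",
              nrow(x$features)))
  if (length(x$warnings))
    cat(sprintf("  %d annotation warning(s)\n", length(x$warnings)))
  invisible(x)
}

feature_length <- function(rec, i) {
  ft <- rec$features[i, ]
  if (ft$start <= ft$end) ft$end - ft$start + 1L
  else rec$length_bp - ft$start + 1L + ft$end
}

#' Extract a region from a (possibly circular) record
#'
#' `start > end` wraps through the origin and is only allowed on circular
#' records. Strand `"N"` returns the reverse complement of the J-strand
#' interval.
#'
#' @param rec a [mito_record()].
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"J"` or `"N"`.
#' @return DNA string of length `end - start + 1` (mod genome length for
#'   wrapping extractions).
#' @examples
#' rec <- mito_record("X1", "Toy", "ACGTACGTAC")
#' extract_region(rec, 9, 2)        # wraps: "ACAC"
#' extract_region(rec, 1, 4, "N")   # revcomp of "ACGT"
#' @export
extract_region <- function(rec, start, end, strand = "J") {
  stopifnot(inherits(rec, "MitoRecord"))
  L <- rec$length_bp
  if (start < 1 || start > L || end < 1 || end > L)
    stop(sprintf("coordinates (%d..%d) out of range for %d bp record",
                 start, end, L))
  if (!strand %in% c("J", "N")) stop("strand must be 'J' or 'N'")
  if (start <= end) {
    s <- substr(rec$sequence, start, end)
  } else {
    if (!rec$is_circular)
      stop("start > end requires a circular record")
    s <- paste0(substr(rec$sequence, start, L), substr(rec$sequence, 1, end))
  }
  if (strand == "N") s <- revcomp(s)
  s
}

#' Extract the sequence of an annotated feature in coding/gene orientation
#'
#' @param rec a [mito_record()].
#' @param gene canonical gene symbol present in `rec$features`.
#' @return DNA string (reverse-complemented for N-strand features).
#' @export
extract_feature <- function(rec, gene) {
  ft <- rec$features[rec$features$name == gene, , drop = FALSE]
  if (nrow(ft) == 0) stop("feature not annotated: ", gene)
  if (nrow(ft) > 1) stop("feature annotated more than once: ", gene)
  extract_region(rec, ft$start, ft$end, ft$strand)
}

#' Reverse complement of a DNA string
#'
#' IUPAC ambiguity codes are complemented correctly (via Biostrings).
#' @param x DNA string.
#' @return The reverse complement as a plain character string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
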