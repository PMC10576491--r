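# Codon usage under the vertebrate mitochondrial code (translation
# table 2): CDS assembly with incomplete-stop padding, start/stop
# inventory, and relative synonymous codon usage (RSCU).
#
# In table 2 AGA/AGG are stops (reported as terminators for cox1/cox3 and
# nad5 in passerines), ATA is Met and TGA is Trp, so Met and Trp are
# two-codon families. The duplicated Leu/Ser families carry the
# conventional split labels: L1 = UUR-Leu, L2 = CUN-Leu, S1 = AGY-Ser,
# S2 = UCN-Ser.

MITO_STOPS <- c("TAA", "TAG", "AGA", "AGG")

# codon -> family label (stop codons excluded)
mito_codon_families <- function() {
  gc2 <- Biostrings::getGeneticCode("2")
  codons <- names(gc2)
  aa <- unname(gc2)
  fam <- aa
  fam[codons %in% c("TTA", "TTG")] <- "L1"
  fam[startsWith(codons, "CT")] <- "L2"
  fam[codons %in% c("AGT", "AGC")] <- "S1"
  fam[startsWith(codons, "TC")] <- "S2"
  keep <- aa != "*"
  setNames(fam[keep], codons[keep])
}

#' Assemble the in-frame coding-sense CDS of a protein-coding gene
#'
#' N-strand genes are reverse-complemented, the `codon_start` offset is
#' honored, and 1-2 nt incomplete stops (completed in vivo by
#' post-transcriptional polyadenylation) are padded with A to `TAA`.
#'
#' @param rec a [mito_record()].
#' @param gene canonical PCG name.
#' @return List with `sequence` (padded, in frame), and `profile`: list
#'   (gene, start_codon, stop_codon as read pre-padding, padded flag).
#' @export
assemble_cds <- function(rec, gene) {
  ft <- rec$features[rec$features$name == gene, , drop = FALSE]
  if (nrow(ft) != 1 || ft$ftype != "PCG")
    stop("not an annotated PCG feature: ", gene)
  s <- extract_region(rec, ft$start, ft$end, ft$strand)
  cs <- ft$codon_start
  if (!is.na(cs) && cs > 1L) s <- substr(s, cs, nchar(s))
  if (nchar(s) < 6) stop("domain error: CDS too short for ", gene)
  r <- nchar(s) %% 3L
  stop_codon <- if (r == 0L) substr(s, nchar(s) - 2, nchar(s))
                else substr(s, nchar(s) - r + 1, nchar(s))
  padded <- r != 0L
  seq <- if (padded) paste0(s, strrep("A", 3L - r)) else s
  codons <- codon_split(seq)
  internal <- codons[-length(codons)]
  if (any(internal %in% MITO_STOPS))
    stop("frame error: internal stop codon in ", gene)
  list(sequence = seq,
       profile = list(gene = gene, start_codon = codons[1],
                      stop_codon = stop_codon, padded = padded))
}

codon_split <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

#' Relative synonymous codon usage
#'
#' RSCU of a codon is its observed count times the size of its synonymous
#' family, divided by the family's total count (so a uniformly used family
#' has RSCU 1 for every member, and family RSCU values sum to the family
#' size). The terminal (possibly padded) codon of each CDS is dropped
#' before counting; codons containing non-ACGT characters are skipped and
#' tallied in the `skipped` attribute.
#'
#' @param cds_set list/vector of padded in-frame CDS strings.
#' @return Object of class `RSCUTable`: data.frame (codon, family,
#'   amino_acid, count, rscu) covering the 60 sense codons of the
#'   vertebrate mitochondrial code.
#' @examples
#' rscu("ATGCTACTACTGTAA")   # Leu: CTA x2, CTG x1
#' @export
rscu <- function(cds_set) {
  cds_set <- unlist(cds_set)
  if (any(nchar(cds_set) %% 3 != 0))
    stop("frame error: CDS length not divisible by 3")
  codons <- unlist(lapply(cds_set, function(s) {
    cc <- codon_split(s)
    cc[-length(cc)]
  }))
  fam <- mito_codon_families()
  valid <- codons %in% names(fam)
  # stop codons are excluded from counting; anything with non-ACGT
  # characters is skipped and tallied
  skipped <- sum(grepl("[^ACGT]", codons[!valid]))
  counts <- table(factor(codons[valid], levels = names(fam)))
  tab <- data.frame(codon = names(fam), family = unname(fam),
                    amino_acid = unname(Biostrings::getGeneticCode("2")[names(fam)]),
                    count = as.integer(counts), stringsAsFactors = FALSE)
  # the synonymous family is the amino acid (Leu and Ser span 6 codons
  # across their L1/L2 and S1/S2 sub-family labels)
  fam_tot <- tapply(tab$count, tab$amino_acid, sum)
  fam_size <- tapply(tab$count, tab$amino_acid, length)
  tab$rscu <- as.numeric(ifelse(fam_tot[tab$amino_acid] > 0,
                                tab$count * fam_size[tab$amino_acid] /
                                  fam_tot[tab$amino_acid],
                                NA_real_))
  tab <- tab[order(tab$family, tab$codon), ]
  rownames(tab) <- NULL
  structure(tab, class = c("RSCUTable", "data.frame"), skipped = skipped)
}

#' Per-gene start/stop codon inventory
#'
#' Start and stop codons are reported verbatim as read (pre-padding); an
#' incomplete stop shows as `"T"` or `"TA"` with `padded = TRUE`. Missing
#' PCGs yield a completeness warning per gene, not an error.
#'
#' @param recs a `MitoRecord` or list of them.
#' @return data.frame (record_id, gene, start_codon, stop_codon, padded).
#' @export
codon_inventory <- function(recs) {
  if (inherits(recs, "MitoRecord")) recs <- list(recs)
  rows <- list()
  for (rec in recs) {
    for (g in PCG_NAMES) {
      if (!g %in% rec$features$name) {
        warning("completeness: ", rec$record_id, " lacks PCG ", g,
                call. = FALSE)
        next
      }
      p <- assemble_cds(rec, g)$profile
      rows[[length(rows) + 1L]] <-
        data.frame(record_id = rec$record_id, gene = g,
                   start_codon = p$start_codon, stop_codon = p$stop_codon,
                   padded = p$padded, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(record_id = character(), gene = character(),
                      start_codon = character(), stop_codon = character(),
                      padded = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
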