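# Controlled vocabulary for the standard avian mitochondrial gene complement.
# Canonical symbols follow the lowercase convention common in mitogenomics
# papers: nad1-6/nad4L, cox1-3, atp6/atp8, cytb, trnX (with anticodon class
# for the duplicated Leu/Ser tRNAs), rrnS/rrnL, plus CR1/CR2 for the
# control region(s).

PCG_NAMES <- c("nad1", "nad2", "cox1", "cox2", "atp8", "atp6", "cox3",
               "nad3", "nad4L", "nad4", "nad5", "cytb", "nad6")

TRNA_NAMES <- c("trnF", "trnV", "trnL(UUR)", "trnI", "trnQ", "trnM",
                "trnW", "trnA", "trnN", "trnC", "trnY", "trnS(UCN)",
                "trnD", "trnK", "trnG", "trnR", "trnH", "trnS(AGY)",
                "trnL(CUN)", "trnE", "trnT", "trnP")

RRNA_NAMES <- c("rrnS", "rrnL")
CR_NAMES <- c("CR1", "CR2", "CR")

#' Canonical gene vocabulary
#'
#' The 37-gene avian mitochondrial complement plus control-region labels,
#' with the feature class of each symbol.
#'
#' @return Named character vector mapping each canonical gene symbol to its
#'   feature class (`"PCG"`, `"tRNA"`, `"rRNA"` or `"CR"`).
#' @examples
#' gene_classes()[["nad2"]]
#' @export
gene_classes <- function() {
  c(setNames(rep("PCG", length(PCG_NAMES)), PCG_NAMES),
    setNames(rep("tRNA", length(TRNA_NAMES)), TRNA_NAMES),
    setNames(rep("rRNA", length(RRNA_NAMES)), RRNA_NAMES),
    setNames(rep("CR", length(CR_NAMES)), CR_NAMES))
}

#' The 37 canonical gene symbols (control regions excluded)
#' @return Character vector of length 37.
#' @export
standard_gene_complement <- function() {
  c(PCG_NAMES, TRNA_NAMES, RRNA_NAMES)
}

gene_class_of <- function(name) {
  cls <- gene_classes()
  unname(cls[name])
}

# Synonym table: common GenBank qualifier spellings -> canonical symbols.
# Loaded from YAML so users can extend it; keys are matched case-insensitively.
synonym_table_path <- function() {
  system.file("extdata", "gene_synonyms.yaml", package = "mitochar")
}

#' Resolve a GenBank gene/product label to a canonical symbol
#'
#' @param label character vector of labels as they appear in `/gene`,
#'   `/product` or `/note` qualifiers (e.g. `"ND2"`, `"COI"`, `"tRNA-Phe"`,
#'   `"D-loop"`).
#' @param synonyms optional named character vector (synonym -> canonical);
#'   defaults to the shipped table.
#' @return Character vector of canonical symbols, `NA` where unresolvable.
#' @examples
#' resolve_gene_name(c("ND2", "COX1", "tRNA-Phe", "nonsense"))
#' @export
resolve_gene_name <- function(label, synonyms = NULL) {
  if (is.null(synonyms)) synonyms <- load_gene_synonyms()
  key <- tolower(trimws(label))
  canon <- tolower(names(gene_classes()))
  out <- character(length(label))
  for (i in seq_along(label)) {
    if (is.na(key[i]) || !nzchar(key[i])) { out[i] <- NA_character_; next }
    hit <- match(key[i], canon)
    if (!is.na(hit)) { out[i] <- names(gene_classes())[hit]; next }
    hit <- match(key[i], tolower(names(synonyms)))
    out[i] <- if (is.na(hit)) NA_character_ else unname(synonyms[hit])
  }
  out
}

load_gene_synonyms <- function(path = synonym_table_path()) {
  tab <- yaml::read_yaml(path)
  unlist(tab)
}
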