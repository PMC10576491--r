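# Orchestration: run every characterization stage over a set of records
# and assemble a report mirroring the usual mitogenome-paper structure
# (structure/organization, PCGs, RNA genes, control region, distances).
# The reporter only collects module outputs; it never recomputes.

#' Run the full characterization pipeline
#'
#' @param inputs list of GenBank file paths, or a list of
#'   [mito_record()] objects.
#' @param config optional list: `domain_spec` (a [cr_domain_spec()], used
#'   for CR1 domain labels), `motif_library`, `trna_specs` (named list of
#'   [cloverleaf_spec()]), `deletion_mode` for distances.
#' @param alignment optional [alignment_matrix()]; adds a p-distance
#'   matrix and NJ tree to the cross-record section.
#' @param output_dir optional directory; writes `report.json` plus TSV
#'   tables.
#' @return List of class `CharacterizationReport` with `records` (per
#'   record: structure, composition, codon inventory, RSCU,
#'   control-region annotations, warnings) and `cross` (averaged
#'   composition, optional distances/tree).
#' @export
run_pipeline <- function(inputs, config = list(), alignment = NULL,
                         output_dir = NULL) {
  if (inherits(inputs, "MitoRecord")) inputs <- list(inputs)
  if (!length(inputs)) stop("input error: no records supplied")
  recs <- list()
  for (x in inputs) {
    if (inherits(x, "MitoRecord")) {
      recs[[length(recs) + 1L]] <- x
    } else {
      got <- tryCatch(read_genbank(x), error = function(e) {
        warning("skipping unreadable input ", x, ": ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
      recs <- c(recs, got)
    }
  }
  if (!length(recs)) stop("input error: no readable records")

  spec <- config$domain_spec
  if (is.null(spec) && !is.null(config$use_default_domains) &&
      isTRUE(config$use_default_domains))
    spec <- cr_domain_spec(c(1, 424), c(425, 859), c(860, 1104))
  lib <- if (is.null(config$motif_library)) motif_library()
         else config$motif_library

  per_record <- lapply(recs, function(rec) {
    characterize_record(rec, spec, lib, config$trna_specs)
  })
  names(per_record) <- vapply(recs, `[[`, "", "record_id")

  comp_rows <- lapply(per_record, function(r)
    r$composition[r$composition$region == "whole_genome", ])
  comp <- do.call(rbind, comp_rows)
  cross <- list(
    n_records = length(recs),
    mean_pct = c(A = mean(comp$pct_A), C = mean(comp$pct_C),
                 G = mean(comp$pct_G), T = mean(comp$pct_T)),
    mean_at_content = mean(comp$at_content))
  if (!is.null(alignment)) {
    mode <- if (is.null(config$deletion_mode)) "complete"
            else config$deletion_mode
    dm <- p_distance(alignment, mode)
    cross$p_distance <- dm
    cross$nj_newick <- neighbor_joining(dm)
  }
  report <- structure(list(records = per_record, cross = cross),
                      class = "CharacterizationReport")
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

characterize_record <- function(rec, spec, lib, trna_specs) {
  out <- list(record_id = rec$record_id, species = rec$species,
              length_bp = rec$length_bp, warnings = rec$warnings)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      out$warnings <<- c(out$warnings,
                         sprintf("stage %s failed: %s", name,
                                 conditionMessage(e)))
      NULL
    })
  }
  out$gene_counts <- stage("gene_counts", {
    ft <- rec$features
    counts <- table(factor(ft$ftype, levels = c("PCG", "tRNA", "rRNA", "CR")))
    as.list(counts)
  })
  out$strand_census <- stage("strand_census", {
    as.list(strand_census(extract_arrangement(rec)))
  })
  out$composition <- stage("composition", per_region_report(rec))
  out$codon_inventory <- stage("codon_inventory",
                               suppressWarnings(codon_inventory(rec)))
  out$rscu <- stage("rscu", {
    genes <- intersect(PCG_NAMES, rec$features$name)
    if (!length(genes)) stop("no PCGs annotated")
    rscu(lapply(genes, function(g) assemble_cds(rec, g)$sequence))
  })
  out$control_region <- stage("control_region", {
    cr <- list()
    for (g in c("CR1", "CR2")) {
      if (!g %in% rec$features$name) {
        cr[[g]] <- list(present = FALSE)
        next
      }
      s <- extract_feature(rec, g)
      cr[[g]] <- list(
        present = TRUE, length = nchar(s),
        motifs = scan_motifs(s, lib, if (g == "CR1") spec else NULL),
        cstrings = find_cstring(s),
        repeats = find_tandem_repeats(s))
    }
    cr
  })
  if (!is.null(trna_specs)) {
    out$trna_pairs <- stage("trna_pairs", {
      hits <- list()
      for (nm in names(trna_specs)) {
        if (!nm %in% rec$features$name) next
        hits[[nm]] <- classify_pairs(extract_feature(rec, nm),
                                     trna_specs[[nm]])
      }
      hits
    })
  }
  out
}

#' Write a characterization report as JSON and TSV tables
#' @param report a `CharacterizationReport`.
#' @param output_dir directory (created if needed).
#' @return `output_dir`, invisibly.
#' @export
write_report <- function(report, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  json <- report_to_json(report)
  writeLines(json, file.path(output_dir, "report.json"))
  comp <- do.call(rbind, lapply(report$records, function(r) {
    df <- r$composition
    if (is.null(df)) return(NULL)
    cbind(record_id = r$record_id, df)
  }))
  if (!is.null(comp))
    utils::write.table(round_report_df(comp),
                       file.path(output_dir, "composition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  inv <- do.call(rbind, lapply(report$records, `[[`, "codon_inventory"))
  if (!is.null(inv))
    utils::write.table(inv, file.path(output_dir, "codon_inventory.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(output_dir)
}

round_report_df <- function(df) {
  for (nm in names(df)) {
    if (grepl("^pct_|at_content", nm)) df[[nm]] <- round(df[[nm]], 2)
    if (grepl("skew", nm)) df[[nm]] <- round(df[[nm]], 4)
    if (grepl("copy_number", nm)) df[[nm]] <- round(df[[nm]], 1)
  }
  df
}

# deterministic JSON: sorted keys via stable list construction, rounding
# at serialization only
report_to_json <- function(report) {
  simplify <- function(x) {
    if (inherits(x, "PDistanceMatrix"))
      return(list(taxa = x$taxa, d = round(unclass(x$d), 4),
                  deletion_mode = x$deletion_mode))
    if (is.data.frame(x)) {
      x <- round_report_df(x)
      class(x) <- "data.frame"  # drop subclass so serialization is uniform
      return(x)
    }
    if (is.list(x)) {
      x <- lapply(x, simplify)
      if (!is.null(names(x))) x <- x[order(names(x))]
      return(x)
    }
    x
  }
  jsonlite::toJSON(simplify(unclass(report)), auto_unbox = TRUE,
                   digits = NA, pretty = TRUE, na = "null")
}
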