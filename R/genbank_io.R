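# GenBank flat-file reader/writer, limited to the fields a MitoRecord
# carries. No pre-installed R package parses feature tables from local
# GenBank files, so this is a purpose-built parser for the subset used by
# annotated mitogenomes (CDS/tRNA/rRNA/D-loop/misc_feature, simple and
# complement()/join() locations).

GB_SEQ_WIDTH <- 60L

#' Read annotated mitogenomes from a GenBank flat file
#'
#' CDS, tRNA, rRNA, D-loop and misc_feature entries are mapped to canonical
#' gene symbols via the synonym table (`/gene`, then `/product`, then
#' `/note` qualifiers). Unmappable features are collected in the record's
#' `warnings` field rather than dropped silently.
#'
#' @param path path to a GenBank flat file (one or more records).
#' @param synonyms optional synonym table, see [resolve_gene_name()].
#' @return List of [mito_record()] objects.
#' @export
read_genbank <- function(path, synonyms = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(grepl("^LOCUS", lines)))
    stop("not a GenBank flat file: ", path)
  ends <- grep("^//\\s*$", lines)
  if (!length(ends)) stop("GenBank format error: missing // terminator")
  starts <- c(1L, head(ends, -1L) + 1L)
  recs <- vector("list", length(ends))
  for (k in seq_along(ends)) {
    chunk <- lines[starts[k]:ends[k]]
    recs[[k]] <- parse_genbank_record(chunk, synonyms)
  }
  recs
}

parse_genbank_record <- function(lines, synonyms = NULL) {
  locus <- grep("^LOCUS", lines, value = TRUE)[1]
  if (is.na(locus)) stop("GenBank format error: no LOCUS line")
  toks <- strsplit(trimws(locus), "\\s+")[[1]]
  record_id <- toks[2]
  is_circular <- any(tolower(toks) == "circular")
  acc <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc)) {
    a <- strsplit(trimws(acc[1]), "\\s+")[[1]]
    if (length(a) >= 2) record_id <- a[2]
  }
  species <- NA_character_
  org <- grep("^\\s{2}ORGANISM", lines, value = TRUE)
  if (length(org)) species <- trimws(sub("^\\s*ORGANISM\\s*", "", org[1]))

  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("GenBank format error: no ORIGIN section")
  seq_lines <- lines[(ori[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("GenBank format error: empty sequence")

  fstart <- grep("^FEATURES", lines)
  feats <- list()
  warnings <- character()
  if (length(fstart)) {
    ftl <- lines[(fstart[1] + 1L):(ori[1] - 1L)]
    feats_raw <- parse_feature_table(ftl)
    for (fr in feats_raw) {
      if (fr$key == "source") next
      mapped <- map_feature(fr, synonyms)
      if (is.null(mapped)) {
        warnings <- c(warnings,
                      sprintf("unmappable %s feature at %s", fr$key,
                              fr$location))
      } else {
        feats[[length(feats) + 1L]] <- mapped
      }
    }
  }
  if (!length(feats) && !length(warnings))
    stop("annotation error: record ", record_id, " has no features")
  ft <- if (length(feats)) do.call(rbind, feats) else gene_features()
  if (length(org)) {
    # ORGANISM often carries lineage continuation lines; keep first line only
    species <- strsplit(species, "\n")[[1]][1]
  }
  mito_record(record_id = record_id,
              species = if (is.na(species)) "" else species,
              sequence = sequence, is_circular = is_circular,
              features = ft, warnings = warnings)
}

# Split the FEATURES block into (key, location, qualifiers) entries.
parse_feature_table <- function(ftl) {
  # feature key lines start at column 6; qualifier/continuation lines at 22
  is_key <- grepl("^\\s{5}\\S", ftl)
  idx <- which(is_key)
  out <- list()
  for (i in seq_along(idx)) {
    from <- idx[i]
    to <- if (i < length(idx)) idx[i + 1L] - 1L else length(ftl)
    block <- ftl[from:to]
    head_toks <- strsplit(trimws(block[1]), "\\s+")[[1]]
    key <- head_toks[1]
    loc <- paste(head_toks[-1], collapse = "")
    quals <- character()
    qname <- character()
    rest <- trimws(block[-1])
    cur <- NULL
    for (ln in rest) {
      if (startsWith(ln, "/")) {
        if (!is.null(cur)) { quals <- c(quals, cur$v); qname <- c(qname, cur$n) }
        eq <- regexpr("=", ln, fixed = TRUE)
        if (eq > 0) {
          cur <- list(n = substr(ln, 2, eq - 1),
                      v = gsub('^"|"$', "", substr(ln, eq + 1, nchar(ln))))
        } else {
          cur <- list(n = substring(ln, 2), v = "")
        }
      } else if (!is.null(cur)) {
        cur$v <- paste0(cur$v, " ", gsub('"$', "", ln))
      } else {
        loc <- paste0(loc, ln)  # continued location
      }
    }
    if (!is.null(cur)) { quals <- c(quals, cur$v); qname <- c(qname, cur$n) }
    names(quals) <- qname
    out[[i]] <- list(key = key, location = loc, qualifiers = quals)
  }
  out
}

# Parse a location string into (start, end, strand). Supports n..m,
# complement(n..m), join(a..b,c..d) for origin wraps, and complement(join()).
parse_location <- function(loc) {
  strand <- "J"
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "N"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",")[[1]]
    rng <- lapply(parts, function(p) as.integer(strsplit(p, "\\.\\.")[[1]]))
    # origin-wrapping join: take start of first segment, end of last
    start <- rng[[1]][1]; end <- rng[[length(rng)]][2]
  } else {
    r <- as.integer(strsplit(gsub("[<>]", "", loc), "\\.\\.")[[1]])
    if (length(r) == 1L) r <- c(r, r)
    start <- r[1]; end <- r[2]
  }
  if (anyNA(c(start, end))) stop("GenBank format error: bad location ", loc)
  list(start = start, end = end, strand = strand)
}

map_feature <- function(fr, synonyms = NULL) {
  q <- fr$qualifiers
  cand <- c(q[names(q) == "gene"], q[names(q) == "product"],
            q[names(q) == "note"])
  canon <- NA_character_
  for (lab in cand) {
    canon <- resolve_gene_name(lab, synonyms)
    if (!is.na(canon)) break
  }
  if (fr$key %in% c("D-loop") && is.na(canon)) canon <- "CR1"
  if (is.na(canon)) return(NULL)
  expected <- switch(fr$key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                     "D-loop" = "CR", misc_feature = NA_character_,
                     gene = NA_character_, NA_character_)
  cls <- gene_class_of(canon)
  if (fr$key == "gene") return(NULL)  # gene lines duplicate typed features
  if (!is.na(expected) && expected != cls) return(NULL)
  loc <- parse_location(fr$location)
  cs <- NA_integer_
  if (cls == "PCG") {
    cs <- suppressWarnings(as.integer(q[["codon_start"]]))
    if (is.na(cs) || !length(cs)) cs <- 1L
  }
  gene_features(canon, loc$start, loc$end, loc$strand, cs)
}

#' Write mitogenome records as a GenBank flat file
#'
#' Output is re-readable by [read_genbank()] with no information loss for
#' the fields a [mito_record()] carries. J/N strands are written as plain /
#' `complement()` locations; origin-wrapping features are written as
#' `join()` spans.
#'
#' @param recs a `MitoRecord` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(recs, path) {
  if (inherits(recs, "MitoRecord")) recs <- list(recs)
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in recs) writeLines(format_genbank_record(rec), con)
  invisible(path)
}

format_genbank_record <- function(rec) {
  topo <- if (rec$is_circular) "circular" else "linear"
  out <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     %s VRT 01-JAN-2024",
            rec$record_id, rec$length_bp, topo),
    sprintf("DEFINITION  %s mitochondrion%s.", rec$species,
            if (rec$is_circular) ", complete genome" else ""),
    sprintf("ACCESSION   %s", rec$record_id),
    sprintf("SOURCE      mitochondrion %s", rec$species),
    sprintf("  ORGANISM  %s", rec$species),
    "FEATURES             Location/Qualifiers",
    gb_feature_lines("source", sprintf("1..%d", rec$length_bp),
                     c(organism = rec$species,
                       organelle = "mitochondrion"))
  )
  ft <- rec$features
  if (nrow(ft) > 0) {
    for (i in seq_len(nrow(ft))) {
      f <- ft[i, ]
      loc <- if (f$start <= f$end) sprintf("%d..%d", f$start, f$end)
             else sprintf("join(%d..%d,1..%d)", f$start, rec$length_bp, f$end)
      if (f$strand == "N") loc <- sprintf("complement(%s)", loc)
      key <- switch(f$ftype, PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                    CR = "misc_feature")
      quals <- c(gene = f$name)
      if (f$ftype == "PCG") {
        quals <- c(quals, codon_start = as.character(f$codon_start),
                   transl_table = "2")
      }
      if (f$ftype == "CR") quals <- c(quals, note = "control region")
      out <- c(out, gb_feature_lines(key, loc, quals))
    }
  }
  out <- c(out, "ORIGIN", gb_origin_lines(rec$sequence), "//")
  out
}

gb_feature_lines <- function(key, loc, quals) {
  lines <- sprintf("     %-16s%s", key, loc)
  for (nm in names(quals)) {
    val <- quals[[nm]]
    q <- if (nm %in% c("codon_start", "transl_table"))
      sprintf("/%s=%s", nm, val) else sprintf('/%s="%s"', nm, val)
    lines <- c(lines, paste0(strrep(" ", 21), q))
  }
  lines
}

gb_origin_lines <- function(sequence) {
  n <- nchar(sequence)
  starts <- seq(1L, n, by = GB_SEQ_WIDTH)
  vapply(starts, function(s) {
    block <- tolower(substr(sequence, s, min(s + GB_SEQ_WIDTH - 1L, n)))
    groups <- substring(block, seq(1, nchar(block), 10),
                        pmin(seq(10, nchar(block) + 9, 10), nchar(block)))
    sprintf("%9d %s", s, paste(groups, collapse = " "))
  }, character(1))
}

#' Read sequences from a FASTA file
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to a FASTA file
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
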