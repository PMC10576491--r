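# Synthetic annotated mitogenomes with full ground-truth bookkeeping, and
# a site-independent substitution simulator for aligned matrices. Every
# planted quantity (coordinates, codon profiles, motifs with edit counts,
# C-string, tandem repeat, composition targets) is recorded in a truth
# list so each pipeline stage can be tested by plant/recover.

# body codon counts (between the ATG start and the stop), chosen to give
# gene lengths typical of passerine mitogenomes
PCG_BODY_CODONS <- c(nad1 = 322, nad2 = 345, cox1 = 515, cox2 = 226,
                     atp8 = 54, atp6 = 226, cox3 = 260, nad3 = 115,
                     nad4L = 97, nad4 = 458, nad5 = 604, cytb = 379,
                     nad6 = 171)

DEFAULT_STOPS <- c(nad1 = "TAA", nad2 = "TA", cox1 = "AGG", cox2 = "TAA",
                   atp8 = "TAA", atp6 = "TAA", cox3 = "AGG", nad3 = "TAA",
                   nad4L = "TAA", nad4 = "T", nad5 = "AGA", cytb = "TAA",
                   nad6 = "TAA")

# default CR1 plants: CR1-local positions for the shipped element library
DEFAULT_MOTIF_POSITIONS <- c("C-string" = 40, F = 430, E = 470, D = 500,
                             C = 540, "bird-similarity" = 700, B = 760,
                             CSB1 = 900)

#' The tandem-repeat units observed in remnant CR2
#'
#' The 46-bp (P. fuscatus) and 45-bp (P. proregulus) repeat-unit consensus
#' sequences used as default planted repeats and in the acceptance
#' analysis.
#' @return Named character vector.
#' @export
cr2_repeat_units <- function() {
  c(fuscatus = "CATTTCATTAAACTCGCAAAGCCTACCAAACAACCGCATTCACACC",
    proregulus = "AACCAAACCTATCCCAAACCCCCCTCCCACTAAAAAACAAACAAA")
}

#' Synthetic-mitogenome configuration
#'
#' Defaults emulate the leaf-warbler study conditions: a ~16.95 kb
#' circular genome in the rearranged (duplicated-CR) order, base
#' frequencies A .30 / C .32 / G .15 / T .23 (the six-genome averages,
#' rounded), ATG starts for all 13 PCGs with AGG/AGA terminators for
#' cox1/cox3/nad5, incomplete stops TA (nad2) and T (nad4), the conserved
#' boxes planted in CR1 at fixed domain-consistent positions, and a
#' two-copy 46-bp tandem repeat planted in remnant CR2.
#'
#' @param seed integer RNG seed.
#' @param genome_length target circular genome length (bp).
#' @param arrangement gene-order template name (see
#'   [gene_order_template()]).
#' @param base_freqs named A/C/G/T frequencies summing to 1.
#' @param codon_bias optional named numeric vector of per-codon weights
#'   overriding the base-frequency codon model for PCG bodies.
#' @param stop_codons named per-gene terminator strings (3 nt, or "TA"/"T"
#'   for incomplete stops).
#' @param planted_motifs data.frame (box, position, n_edits) of CR1 plants;
#'   defaults to all phylloscopus_cr1 library elements with 0 edits.
#' @param planted_repeat list(unit =, copies =) planted in CR2.
#' @param cr1_length,cr2_length control-region lengths (CR1 default 1104,
#'   partitioned 1-424 / 425-859 / 860-1104).
#' @return List of class `SynthConfig`.
#' @export
synth_config <- function(seed = 1L, genome_length = 16950L,
                         arrangement = "phylloscopus",
                         base_freqs = c(A = 0.30, C = 0.32,
                                        G = 0.15, T = 0.23),
                         codon_bias = NULL,
                         stop_codons = DEFAULT_STOPS,
                         planted_motifs = NULL,
                         planted_repeat = list(
                           unit = unname(cr2_repeat_units()["fuscatus"]),
                           copies = 2.0),
                         cr1_length = 1104L, cr2_length = 220L) {
  if (abs(sum(base_freqs) - 1) > 1e-9)
    stop("base_freqs must sum to 1")
  if (!is.null(planted_repeat) && planted_repeat$copies < 1.0)
    stop("repeat copies must be >= 1")
  if (is.null(planted_motifs)) {
    lib <- motif_library()
    lib <- Filter(function(m) m$provenance == "phylloscopus_cr1", lib)
    planted_motifs <- data.frame(
      box = vapply(lib, `[[`, "", "box"),
      position = unname(DEFAULT_MOTIF_POSITIONS[
        vapply(lib, `[[`, "", "box")]),
      n_edits = 0L, stringsAsFactors = FALSE)
  }
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 arrangement = arrangement, base_freqs = base_freqs,
                 codon_bias = codon_bias, stop_codons = stop_codons,
                 planted_motifs = planted_motifs,
                 planted_repeat = planted_repeat,
                 cr1_length = as.integer(cr1_length),
                 cr2_length = as.integer(cr2_length)),
            class = "SynthConfig")
}

#' Random DNA with target base frequencies
#' @param n length.
#' @param freqs named A/C/G/T frequencies.
#' @return DNA string.
#' @export
random_dna <- function(n, freqs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs),
        collapse = "")
}

# codon sampler: probability proportional to product of base frequencies
# (or explicit codon_bias weights), stop codons excluded. Because removing
# the (A-rich) stop codons skews the base marginals, the default weights
# are rebalanced by iterative proportional fitting so the expected base
# composition of sampled codons matches the target frequencies.
sample_codons <- function(n, freqs, codon_bias = NULL) {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  base_count <- sapply(bases, function(b)
    lengths(regmatches(codons, gregexpr(b, codons))))
  if (!is.null(codon_bias)) {
    w <- rep(0, length(codons))
    names(w) <- codons
    w[names(codon_bias)] <- codon_bias
    w[codons %in% MITO_STOPS] <- 0
  } else {
    f <- freqs[bases]
    w <- exp(base_count %*% log(f))[, 1]
    w[codons %in% MITO_STOPS] <- 0
    for (it in 1:60) {
      w <- w / sum(w)
      marg <- colSums(w * base_count) / 3
      f <- f * (freqs[bases] / marg)
      w <- exp(base_count %*% log(f))[, 1]
      w[codons %in% MITO_STOPS] <- 0
    }
  }
  paste(sample(codons, n, replace = TRUE, prob = w), collapse = "")
}

complement_freqs <- function(freqs) {
  c(A = unname(freqs["T"]), C = unname(freqs["G"]),
    G = unname(freqs["C"]), T = unname(freqs["A"]))
}

apply_edits <- function(pattern, n_edits) {
  if (n_edits == 0) return(pattern)
  pc <- strsplit(pattern, "")[[1]]
  at <- sample(length(pc), n_edits)
  for (i in at) pc[i] <- sample(setdiff(c("A", "C", "G", "T"), pc[i]), 1)
  paste(pc, collapse = "")
}

#' Generate a synthetic annotated mitogenome with ground truth
#'
#' Genes are laid out in template order starting at the anchor (trnF).
#' PCGs are in frame with ATG starts, stop codons as configured (1-2 nt
#' incomplete stops supported), and no internal stops; N-strand genes are
#' stored reverse-complemented in the genome. CR1 carries the planted
#' conserved boxes and C-string at recorded positions; CR2 carries the
#' planted tandem repeat. Residual length is filled by an intergenic
#' spacer before the origin. Deterministic for a given config.
#'
#' @param cfg a [synth_config()].
#' @return List with `record` (a [mito_record()]) and `truth` (planted
#'   coordinates and values).
#' @export
generate_mitogenome <- function(cfg) {
  stopifnot(inherits(cfg, "SynthConfig"))
  set.seed(cfg$seed)
  arr <- gene_order_template(cfg$arrangement)
  freqs <- cfg$base_freqs
  truth <- list(arrangement = cfg$arrangement, base_freqs = freqs,
                seed = cfg$seed, cds = list(), motifs = NULL,
                repeat_ = NULL, cstring = NULL)
  trna_len <- setNames(sample(67:74, length(TRNA_NAMES), replace = TRUE),
                       TRNA_NAMES)
  trna_len["trnS(AGY)"] <- 66L
  trna_len["trnL(UUR)"] <- 75L
  rrn_len <- c(rrnS = sample(974:988, 1), rrnL = sample(1598:1602, 1))

  segments <- character(nrow(arr))
  seg_truth <- vector("list", nrow(arr))
  for (i in seq_len(nrow(arr))) {
    g <- arr$name[i]
    st <- arr$strand[i]
    cls <- gene_class_of(g)
    if (cls == "PCG") {
      stop_str <- cfg$stop_codons[[g]]
      body <- sample_codons(PCG_BODY_CODONS[[g]],
                            if (st == "J") freqs else complement_freqs(freqs),
                            cfg$codon_bias)
      cds <- paste0("ATG", body, stop_str)
      segments[i] <- if (st == "J") cds else revcomp(cds)
      truth$cds[[g]] <- list(sequence = cds, start_codon = "ATG",
                             stop_codon = stop_str,
                             padded = nchar(stop_str) < 3)
    } else if (cls == "tRNA") {
      segments[i] <- random_dna(trna_len[[g]], freqs)
    } else if (cls == "rRNA") {
      segments[i] <- random_dna(rrn_len[[g]], freqs)
    } else if (g == "CR1") {
      cr <- build_cr1(cfg, freqs)
      segments[i] <- cr$seq
      truth$motifs <- cr$motifs
      truth$cstring <- cr$cstring
    } else {  # CR2
      cr <- build_cr2(cfg, freqs)
      segments[i] <- cr$seq
      truth$repeat_ <- cr$repeat_
    }
  }
  total <- sum(nchar(segments))
  spacer <- cfg$genome_length - total
  if (spacer < 0)
    stop(sprintf("config error: gene layout (%d bp) exceeds genome_length (%d)",
                 total, cfg$genome_length))
  starts <- cumsum(c(1L, head(nchar(segments), -1L)))
  ends <- starts + nchar(segments) - 1L
  ft <- gene_features(arr$name, starts, ends, arr$strand,
                      ifelse(gene_class_of(arr$name) == "PCG", 1L,
                             NA_integer_))
  genome <- paste0(paste(segments, collapse = ""),
                   if (spacer > 0) random_dna(spacer, freqs) else "")
  rec <- mito_record(record_id = sprintf("SYN%06d", cfg$seed),
                     species = "Phylloscopus syntheticus",
                     sequence = genome, is_circular = TRUE, features = ft)
  truth$features <- ft
  truth$spacer <- spacer
  list(record = rec, truth = truth)
}

build_cr1 <- function(cfg, freqs) {
  seq <- strsplit(random_dna(cfg$cr1_length, freqs), "")[[1]]
  lib <- motif_library()
  pat <- setNames(vapply(lib, `[[`, "", "pattern"),
                  vapply(lib, `[[`, "", "box"))
  pm <- cfg$planted_motifs
  planted <- list()
  cstring <- NULL
  for (k in seq_len(nrow(pm))) {
    box <- pm$box[k]
    if (!box %in% names(pat)) stop("unknown motif box: ", box)
    motif <- apply_edits(pat[[box]], pm$n_edits[k])
    pos <- pm$position[k]
    if (pos + nchar(motif) - 1L > length(seq))
      stop("config error: motif ", box, " does not fit in CR1")
    seq[pos:(pos + nchar(motif) - 1L)] <- strsplit(motif, "")[[1]]
    entry <- data.frame(box = box, position = pos, n_edits = pm$n_edits[k],
                        planted_seq = motif, stringsAsFactors = FALSE)
    if (box == "C-string") {
      cstring <- list(start = pos, length = nchar(motif))
    }
    planted[[length(planted) + 1L]] <- entry
  }
  # guard the base after a planted C-string so the run cannot extend
  if (!is.null(cstring)) {
    after <- cstring$start + cstring$length
    if (after <= length(seq) && seq[after] == "C") seq[after] <- "A"
    if (cstring$start > 1L && seq[cstring$start - 1L] == "C")
      seq[cstring$start - 1L] <- "A"
  }
  list(seq = paste(seq, collapse = ""),
       motifs = do.call(rbind, planted), cstring = cstring)
}

build_cr2 <- function(cfg, freqs) {
  pr <- cfg$planted_repeat
  if (is.null(pr)) {
    return(list(seq = random_dna(cfg$cr2_length, freqs), repeat_ = NULL))
  }
  unit <- toupper(pr$unit)
  p <- nchar(unit)
  reg_len <- round(p * pr$copies)
  reps <- paste(rep(unit, ceiling(pr$copies)), collapse = "")
  reps <- substr(reps, 1, reg_len)
  flank_total <- max(cfg$cr2_length - reg_len, 20L)
  lf <- flank_total %/% 2L
  rf <- flank_total - lf
  left <- random_dna(lf, freqs)
  right <- random_dna(rf, freqs)
  # guard bases: the flank must not continue the periodicity, so the
  # planted copy number is the true maximal periodic extent
  uc <- strsplit(unit, "")[[1]]
  if (lf > 0 && substr(left, lf, lf) == uc[p])
    substr(left, lf, lf) <- sample(setdiff(c("A", "C", "G", "T"), uc[p]), 1)
  nxt <- uc[(reg_len %% p) + 1L]
  if (rf > 0 && substr(right, 1, 1) == nxt)
    substr(right, 1, 1) <- sample(setdiff(c("A", "C", "G", "T"), nxt), 1)
  seq <- paste0(left, reps, right)
  list(seq = seq,
       repeat_ = list(start = lf + 1L, end = lf + reg_len,
                      period = p, copies = reg_len / p, unit = unit))
}

#' Simulate an aligned matrix along a tree
#'
#' Site-independent substitutions: on every branch each site mutates with
#' probability `subst_prob` to one of the three other bases uniformly
#' (Jukes-Cantor-like, no rate heterogeneity, no indels). The expected
#' p-distance between sequences separated by `k` branches is
#' `expected_p_distance(subst_prob, k)`.
#'
#' @param tree an `ape` phylo object or Newick string.
#' @param root_len sequence length (sites).
#' @param subst_prob per-branch per-site substitution probability in
#'   `[0, 0.75)`.
#' @param seed RNG seed.
#' @return List with `alignment` (an [alignment_matrix()]) and `tree`
#'   (phylo).
#' @export
simulate_alignment <- function(tree, root_len, subst_prob, seed = 1L) {
  if (is.character(tree)) {
    tree <- tryCatch(ape::read.tree(text = tree),
                     error = function(e) NULL)
    if (is.null(tree)) stop("parse error: malformed Newick")
  }
  if (subst_prob < 0 || subst_prob >= 0.75)
    stop("subst_prob must be in [0, 0.75)")
  set.seed(seed)
  phy <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  bases <- c("A", "C", "G", "T")
  seqs <- vector("list", max(phy$edge))
  seqs[[root]] <- sample(bases, root_len, replace = TRUE)
  for (e in seq_len(nrow(phy$edge))) {
    par <- phy$edge[e, 1]
    child <- phy$edge[e, 2]
    s <- seqs[[par]]
    hit <- which(runif(root_len) < subst_prob)
    for (i in hit) s[i] <- sample(setdiff(bases, s[i]), 1)
    seqs[[child]] <- s
  }
  tips <- setNames(vapply(seq_len(ntip), function(i)
    paste(seqs[[i]], collapse = ""), character(1)), phy$tip.label)
  list(alignment = alignment_matrix(tips), tree = phy)
}

#' Expected p-distance under the per-branch substitution model
#' @param q per-branch per-site substitution probability.
#' @param k number of branches separating the two sequences.
#' @return Expected proportion of differing sites.
#' @export
expected_p_distance <- function(q, k) {
  0.75 * (1 - (1 - 4 * q / 3)^k)
}
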