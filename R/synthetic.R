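# Synthetic genomes with planted LTR-RT histories and full ground truth.
#
# The generator emulates the features the pipeline measures: a GC-matched
# random background; families of elements derived from a shared ancestral
# exemplar whose internal region encodes the bundled Gag-Pol exemplars in
# frame; per-element insertion ages drawn from a two-component mixture
# (ancient 2-10 Mya peak plus recent <1 Mya activity); K2P substitution
# accumulation on each LTR copy independently; TSDs for intact insertions
# and recombination-derived solos; and truncated remnants keeping one LTR
# plus a partial internal region. Coordinates, categories, mechanisms, ages
# and family labels are all recorded as ground truth.

#' Simulation configuration
#'
#' Defaults mirror the study conditions the pipeline targets: 35.8% GC,
#' 500-bp LTRs, ~5-kb internal regions, substitution rate 1.3e-8
#' substitutions/site/year with transition/transversion ratio kappa = 2,
#' 5-bp TSDs, an age mixture of 70% Uniform(2,10) Mya and 30% Uniform(0,1)
#' Mya, and per-family category counts whose planted S:I (14/6 = 2.33) and
#' T:I (0.33) sit at the genome-wide removal-rate ratios the analysis is
#' designed to measure, with recombination-derived solos a small minority of
#' all solos.
#'
#' @param genome_len Genome length in bp.
#' @param gc_content Background GC fraction.
#' @param n_families Number of element families (each from an independent
#'   random ancestral exemplar; clades cycle through the bundled library).
#' @param n_intact,n_solo_recomb,n_solo_fragment,n_truncated Planted loci
#'   per family by category/mechanism.
#' @param ltr_len,internal_len Ancestral LTR and internal-region lengths (bp).
#' @param age_model List with `weights` and `ranges` (list of `c(lo, hi)` in
#'   Mya) defining the insertion-age mixture.
#' @param kappa Transition/transversion rate ratio.
#' @param mu Substitution rate per site per year.
#' @param tsd_len TSD length in bp.
#' @param plant_genes Plant one gene near each intact element.
#' @param gene_distance_range Gap in bp between an intact element and its
#'   planted gene.
#' @param gene_len Planted gene length in bp.
#' @param min_spacing Minimum background gap between planted loci (bp). The
#'   default (16 kb) exceeds the maximum element span the detector accepts,
#'   so two distinct planted loci can never jointly masquerade as one
#'   element: every planted locus is independently resolvable (the
#'   no-overlapping-insertions regime).
#' @param seed RNG seed; identical configs give byte-identical output.
#' @return A list of class `ltr_sim_config`.
#' @export
sim_config <- function(genome_len = 1500000, gc_content = 0.358,
                       n_families = 2, n_intact = 6, n_solo_recomb = 1,
                       n_solo_fragment = 13, n_truncated = 2,
                       ltr_len = 500, internal_len = 5000,
                       age_model = list(weights = c(0.7, 0.3),
                                        ranges = list(c(2, 10), c(0, 1))),
                       kappa = 2.0, mu = 1.3e-8, tsd_len = 5,
                       plant_genes = TRUE,
                       gene_distance_range = c(3000, 5000), gene_len = 1500,
                       min_spacing = 16000, seed = 1L) {
  cfg <- as.list(environment())
  if (gc_content <= 0 || gc_content >= 1) stop("gc_content must be in (0,1)")
  if (any(c(n_intact, n_solo_recomb, n_solo_fragment, n_truncated) < 0))
    stop("category counts must be >= 0")
  if (abs(sum(age_model$weights) - 1) > 1e-8)
    stop("age_model weights must sum to 1")
  if (length(age_model$weights) != length(age_model$ranges))
    stop("age_model weights and ranges must have equal length")
  coding_len <- 3L * sum(.DOMAIN_LENGTHS)
  if (internal_len < coding_len + 200L)
    stop("internal_len must be at least ", coding_len + 200L,
         " bp to hold the Gag-Pol coding region plus UTRs")
  structure(cfg, class = "ltr_sim_config")
}

.random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# One deterministic codon per amino acid (lexicographically smallest).
.codon_table <- function() {
  if (is.null(.ltrdyn_cache$codons)) {
    gc <- Biostrings::GENETIC_CODE
    by_aa <- split(names(gc), unname(gc))
    .ltrdyn_cache$codons <- vapply(by_aa, function(x) sort(x)[1], "")
  }
  .ltrdyn_cache$codons
}

.encode_protein <- function(aa_seq) {
  tab <- .codon_table()
  paste(tab[strsplit(aa_seq, "")[[1]]], collapse = "")
}

# Evolve a sequence by `d` expected substitutions per site under K2P with
# transition/transversion rate ratio kappa. Analytic K2P transition
# probabilities, so realized divergence is unbiased for the dating model.
.evolve_seq <- function(seq_chr, d, kappa) {
  v <- .dna_int(seq_chr)
  n <- length(v)
  if (d == 0 || n == 0) return(seq_chr)
  beta <- d / (kappa + 2)
  alpha <- d * kappa / (kappa + 2)
  p_ts <- 0.25 + 0.25 * exp(-4 * beta) - 0.5 * exp(-2 * (alpha + beta))
  p_tv <- 0.5 - 0.5 * exp(-4 * beta)
  r <- stats::runif(n)
  ts <- r < p_ts
  tv <- !ts & r < p_ts + p_tv
  # transitions: A<->G (0<->2), C<->T (1<->3)
  ts_map <- c(2L, 3L, 0L, 1L)
  out <- v
  out[ts & v >= 0] <- ts_map[v[ts & v >= 0] + 1L]
  # transversions: pick one of the two non-partner bases uniformly
  tv1 <- c(1L, 0L, 1L, 0L)  # A->C, C->A, G->C, T->A
  tv2 <- c(3L, 2L, 3L, 2L)  # A->T, C->G, G->T, T->G
  pick <- stats::runif(n) < 0.5
  sel <- tv & v >= 0
  out[sel] <- ifelse(pick[sel], tv1[v[sel] + 1L], tv2[v[sel] + 1L])
  paste(c("A", "C", "G", "T", "N")[ifelse(out < 0, 5L, out + 1L)],
        collapse = "")
}

#' Evolve an ancestral LTR into a diverged 5'/3' pair
#'
#' Each copy independently accumulates an expected `mu * age` substitutions
#' per site (so the expected pairwise divergence is `2 * mu * age`), with
#' transitions favoured by `kappa`. No indels are introduced, keeping K2P
#' site counts exact.
#'
#' @param ancestral_ltr Ancestral LTR sequence (character).
#' @param age_mya Insertion age in Mya (>= 0).
#' @param mu Substitution rate per site per year.
#' @param kappa Transition/transversion rate ratio.
#' @param seed Optional seed set before drawing.
#' @return A list with `ltr5` and `ltr3`.
#' @export
evolve_ltr_pair <- function(ancestral_ltr, age_mya, mu = 1.3e-8, kappa = 2.0,
                            seed = NULL) {
  if (age_mya < 0) stop("age must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  d <- mu * age_mya * 1e6
  list(ltr5 = .evolve_seq(ancestral_ltr, d, kappa),
       ltr3 = .evolve_seq(ancestral_ltr, d, kappa))
}

.draw_age <- function(age_model) {
  k <- sample.int(length(age_model$weights), 1, prob = age_model$weights)
  r <- age_model$ranges[[k]]
  stats::runif(1, r[1], r[2])
}

#' Simulate a genome with planted LTR-RT loci and ground truth
#'
#' Builds the genome described by `config`: each family derives from a
#' random ancestral exemplar (LTR plus an internal region carrying a 150-bp
#' leader, the clade's GAG-PR-RT-RH-INT coding block in frame, and a
#' trailer); intact loci are TSD + 5'LTR + internal + 3'LTR + TSD;
#' recombination solos keep a single LTR between the original TSD copies;
#' fragmentation solos are a bare LTR; truncated loci keep one LTR plus a
#' random 20-80% prefix or suffix of the internal region. Loci are placed in
#' shuffled order with at least `min_spacing` bp of background between them,
#' and a gene is planted 3-5 kb from each intact element when
#' `plant_genes` is set.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes `genome.fasta`,
#'   `truth.tsv`, `truth.gff3`, `genes.gff3`, `domains.faa` and
#'   `config.yaml`.
#' @return A list: `genome` (named `DNAStringSet`), `truth` (data.frame, one
#'   row per planted locus), `genes` (data.frame), `library`
#'   (`domain_library`), `config`.
#' @export
simulate_genome <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "ltr_sim_config"))
  set.seed(config$seed)
  lib <- synthetic_domain_library()
  gc <- config$gc_content
  leader_len <- 150L
  coding_len <- 3L * sum(.DOMAIN_LENGTHS)
  trailer_len <- config$internal_len - leader_len - coding_len

  # family ancestors
  fams <- lapply(seq_len(config$n_families), function(f) {
    clade <- .CLADES$clade[(f - 1L) %% nrow(.CLADES) + 1L]
    prot <- lib$seqs[lib$info$clade == clade]
    ord <- match(.DOMAIN_NAMES, lib$info$domain[lib$info$clade == clade])
    coding <- paste(vapply(ord, function(i)
      .encode_protein(as.character(prot[[i]])), ""), collapse = "")
    list(label = sprintf("FAM%02d", f), clade = clade,
         ltr = .random_dna(config$ltr_len, gc),
         internal = paste0(.random_dna(leader_len, gc), coding,
                           .random_dna(trailer_len, gc)))
  })

  # locus descriptors
  loci <- list()
  for (fam in fams) {
    cats <- c(rep("INTACT", config$n_intact),
              rep("SOLO_RECOMB", config$n_solo_recomb),
              rep("SOLO_FRAG", config$n_solo_fragment),
              rep("TRUNCATED", config$n_truncated))
    for (cat in cats) {
      age <- .draw_age(config$age_model)
      d <- config$mu * age * 1e6
      l <- list(family = fam$label, clade = fam$clade, cat = cat, age = age)
      if (cat == "INTACT") {
        pair <- evolve_ltr_pair(fam$ltr, age, config$mu, config$kappa)
        l$ltr5 <- pair$ltr5
        l$ltr3 <- pair$ltr3
        l$internal <- .evolve_seq(fam$internal, d, config$kappa)
        l$tsd <- .random_dna(config$tsd_len, gc)
      } else {
        l$ltr <- .evolve_seq(fam$ltr, d, config$kappa)
        if (cat == "SOLO_RECOMB") l$tsd <- .random_dna(config$tsd_len, gc)
        if (cat == "TRUNCATED") {
          l$side <- sample(c("5p", "3p"), 1)
          l$frac <- stats::runif(1, 0.2, 0.8)
          int_e <- .evolve_seq(fam$internal, d, config$kappa)
          keep <- round(l$frac * nchar(int_e))
          l$internal <- if (l$side == "5p") substr(int_e, 1, keep) else
            substr(int_e, nchar(int_e) - keep + 1, nchar(int_e))
        }
      }
      loci[[length(loci) + 1L]] <- l
    }
  }
  loci <- loci[sample.int(length(loci))]

  locus_seq <- function(l) {
    switch(l$cat,
      INTACT = paste0(l$tsd, l$ltr5, l$internal, l$ltr3, l$tsd),
      SOLO_RECOMB = paste0(l$tsd, l$ltr, l$tsd),
      SOLO_FRAG = l$ltr,
      TRUNCATED = if (l$side == "5p") paste0(l$ltr, l$internal) else
        paste0(l$internal, l$ltr))
  }
  widths <- vapply(loci, function(l) nchar(locus_seq(l)), numeric(1))
  has_gene <- config$plant_genes &
    vapply(loci, function(l) l$cat == "INTACT", logical(1))
  gene_gap <- ifelse(has_gene,
                     round(stats::runif(length(loci),
                                        config$gene_distance_range[1],
                                        config$gene_distance_range[2])), 0)
  gene_alloc <- ifelse(has_gene, gene_gap + config$gene_len, 0)
  n <- length(loci)
  material <- sum(widths) + sum(gene_alloc) +
    (n + 1L) * config$min_spacing
  leftover <- config$genome_len - material
  if (leftover < 0)
    stop("planted material (", material, " bp) exceeds genome_len (",
         config$genome_len, " bp)")
  extras <- as.vector(stats::rmultinom(1, leftover, rep(1, n + 1L)))

  chunks <- character(0)
  truth <- list()
  genes <- list()
  cursor <- 1L
  append_bg <- function(len) {
    if (len > 0) chunks[[length(chunks) + 1L]] <<- .random_dna(len, gc)
    cursor <<- cursor + as.integer(len)
  }
  tsd_len <- config$tsd_len
  for (i in seq_len(n)) {
    append_bg(config$min_spacing + extras[i])
    l <- loci[[i]]
    sq <- locus_seq(l)
    w <- nchar(sq)
    locus_start <- cursor
    chunks[[length(chunks) + 1L]] <- sq
    cursor <- cursor + w
    locus_end <- cursor - 1L
    ltrL <- nchar(if (l$cat == "INTACT") l$ltr5 else l$ltr)
    row <- data.frame(
      truth_id = sprintf("P%03d", i), family = l$family, clade = l$clade,
      category = switch(l$cat, INTACT = "INTACT", TRUNCATED = "TRUNCATED",
                        "SOLO"),
      mechanism = switch(l$cat, INTACT = "insertion",
                         SOLO_RECOMB = "unequal_recombination",
                         SOLO_FRAG = "fragmentation",
                         TRUNCATED = "fragmentation"),
      seq_id = "chr1", start = NA_integer_, end = NA_integer_,
      ltr5_start = NA_integer_, ltr5_end = NA_integer_,
      ltr3_start = NA_integer_, ltr3_end = NA_integer_,
      age_mya = l$age, tsd = if (is.null(l$tsd)) NA_character_ else l$tsd,
      trunc_side = if (is.null(l$side)) NA_character_ else l$side,
      trunc_frac = if (is.null(l$frac)) NA_real_ else l$frac,
      stringsAsFactors = FALSE)
    if (l$cat == "INTACT") {
      row$start <- locus_start + tsd_len
      row$end <- locus_end - tsd_len
      row$ltr5_start <- row$start
      row$ltr5_end <- row$start + ltrL - 1L
      row$ltr3_start <- row$end - ltrL + 1L
      row$ltr3_end <- row$end
    } else if (l$cat == "SOLO_RECOMB") {
      row$start <- locus_start + tsd_len
      row$end <- locus_end - tsd_len
      row$ltr5_start <- row$start; row$ltr5_end <- row$end
    } else if (l$cat == "SOLO_FRAG") {
      row$start <- locus_start; row$end <- locus_end
      row$ltr5_start <- row$start; row$ltr5_end <- row$end
    } else {
      row$start <- locus_start; row$end <- locus_end
      if (l$side == "5p") {
        row$ltr5_start <- locus_start
        row$ltr5_end <- locus_start + ltrL - 1L
      } else {
        row$ltr5_start <- locus_end - ltrL + 1L
        row$ltr5_end <- locus_end
      }
    }
    truth[[length(truth) + 1L]] <- row
    if (has_gene[i]) {
      g_start <- row$end + gene_gap[i] + 1L
      g_end <- g_start + config$gene_len - 1L
      append_bg((g_end) - (locus_end + 1L) + 1L)
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = sprintf("G%03d", length(genes) + 1L), seq_id = "chr1",
        start = g_start, end = g_end, strand = "+",
        near_truth_id = row$truth_id, planted_distance = gene_gap[i],
        stringsAsFactors = FALSE)
    }
  }
  append_bg(config$min_spacing + extras[n + 1L])
  genome_str <- paste(unlist(chunks), collapse = "")
  stopifnot(nchar(genome_str) == cursor - 1L,
            nchar(genome_str) <= config$genome_len)
  # pad to exact genome length
  if (nchar(genome_str) < config$genome_len)
    genome_str <- paste0(genome_str,
                         .random_dna(config$genome_len - nchar(genome_str), gc))
  genome <- Biostrings::DNAStringSet(stats::setNames(genome_str, "chr1"))
  truth <- do.call(rbind, truth)
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(gene_id = character(), seq_id = character(),
               start = integer(), end = integer(), strand = character(),
               near_truth_id = character(), planted_distance = numeric(),
               stringsAsFactors = FALSE)
  res <- list(genome = genome, truth = truth, genes = genes, library = lib,
              config = config)
  if (!is.null(out_dir)) .write_sim(res, out_dir)
  res
}

.write_sim <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_genome_fasta(res$genome, file.path(out_dir, "genome.fasta"))
  utils::write.table(res$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_domain_library(res$library, file.path(out_dir, "domains.faa"))
  # truth GFF3: one row per planted locus
  con <- file(file.path(out_dir, "truth.gff3"), "w")
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(res$truth))) {
    t <- res$truth[i, ]
    type <- switch(t$category, INTACT = "LTR_retrotransposon",
                   SOLO = "solo_LTR", TRUNCATED = "truncated_LTR_retrotransposon")
    writeLines(paste(t$seq_id, "ltrdyn_sim", type, t$start, t$end, ".", "+",
                     ".", sprintf("ID=%s;family=%s;age_mya=%s", t$truth_id,
                                  t$family, format(t$age_mya, digits = 6)),
                     sep = "\t"), con)
  }
  close(con)
  con <- file(file.path(out_dir, "genes.gff3"), "w")
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(res$genes))) {
    g <- res$genes[i, ]
    writeLines(paste(g$seq_id, "ltrdyn_sim", "gene", g$start, g$end, ".",
                     g$strand, ".", paste0("ID=", g$gene_id), sep = "\t"), con)
  }
  close(con)
  cfg <- unclass(res$config)
  cfg$age_model$ranges <- lapply(cfg$age_model$ranges, as.numeric)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}
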