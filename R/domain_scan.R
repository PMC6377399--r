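# Gag-Pol protein domain scanning of candidate internal regions.
#
# The internal region (or any DNA) is translated in all six frames and each
# frame is locally aligned (BLOSUM62, affine gaps 11/1) against every protein
# in a GyDB-style domain library. Hits must cover >=50% of the library
# protein, exceed 30% identity, and reach an E-value of at most 1e-8; an
# element whose internal region carries qualifying hits for all five domains
# GAG, PR, RT, RH and INT is called intact.

.DOMAIN_NAMES <- c("GAG", "PR", "RT", "RH", "INT")

# Domain lengths (aa) used by the bundled synthetic exemplars; chosen inside
# the ranges seen for plant Ty1/Ty3 polyproteins.
.DOMAIN_LENGTHS <- c(GAG = 500L, PR = 120L, RT = 380L, RH = 160L, INT = 406L)

.CLADES <- data.frame(
  clade = c("Del", "Tat", "Galadriel", "Reina",
            "Sire", "Tork", "Oryco", "Retrofit"),
  superfamily = rep(c("Gypsy", "Copia"), each = 4),
  stringsAsFactors = FALSE)

#' Construct a domain library from protein sequences
#'
#' @param seqs A named [Biostrings::AAStringSet]; names must follow
#'   `NAME|CLADE|SUPERFAMILY` with NAME one of GAG, PR, RT, RH, INT.
#' @return A list of class `domain_library` with elements `seqs` and `info`
#'   (data.frame of `domain`, `clade`, `superfamily`).
#' @export
domain_library <- function(seqs) {
  if (length(seqs) == 0) stop("domain library must be nonempty")
  if (!is(seqs, "AAStringSet")) seqs <- Biostrings::AAStringSet(seqs)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(parts) != 3))
    stop("domain library headers must be NAME|CLADE|SUPERFAMILY")
  info <- data.frame(domain = vapply(parts, `[`, "", 1),
                     clade = vapply(parts, `[`, "", 2),
                     superfamily = vapply(parts, `[`, "", 3),
                     stringsAsFactors = FALSE)
  bad <- setdiff(unique(info$domain), .DOMAIN_NAMES)
  if (length(bad) > 0)
    stop("unknown domain name in library: ", bad[1])
  if (any(grepl("[^ACDEFGHIKLMNPQRSTVWYX]", as.character(seqs))))
    stop("library proteins must use the 20-letter amino-acid alphabet plus X")
  structure(list(seqs = seqs, info = info), class = "domain_library")
}

#' Read a GyDB-style Gag-Pol protein FASTA
#'
#' @param path Protein FASTA with `>NAME|CLADE|SUPERFAMILY` headers.
#' @return A `domain_library`.
#' @export
read_domain_library <- function(path) {
  if (!file.exists(path)) stop("domain library FASTA not found: ", path)
  domain_library(Biostrings::readAAStringSet(path))
}

#' Write a domain library as protein FASTA
#' @param library A `domain_library`.
#' @param path Output path.
#' @export
write_domain_library <- function(library, path) {
  Biostrings::writeXStringSet(library$seqs, path, width = 70L)
  invisible(path)
}

#' Bundled synthetic Gag-Pol exemplar library
#'
#' A deterministic set of synthetic exemplar proteins: one GAG, PR, RT, RH
#' and INT sequence for each of eight clades (Del, Tat, Galadriel, Reina of
#' Gypsy; Sire, Tork, Oryco, Retrofit of Copia). The sequences are randomly
#' generated (fixed internal seed), not real GyDB entries: they carry no
#' biological signal and exist so the scanner, the intactness rule and the
#' simulator share a consistent, redistributable reference set. Supply a real
#' GyDB-style FASTA via [read_domain_library()] for production use.
#'
#' @return A `domain_library` with 40 entries.
#' @export
synthetic_domain_library <- function() {
  if (!is.null(.ltrdyn_cache$synthetic_library))
    return(.ltrdyn_cache$synthetic_library)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(20260901L)
  seqs <- character(0)
  for (ci in seq_len(nrow(.CLADES))) {
    for (dn in .DOMAIN_NAMES) {
      p <- paste(sample(aa, .DOMAIN_LENGTHS[[dn]], replace = TRUE),
                 collapse = "")
      seqs[sprintf("%s|%s|%s", dn, .CLADES$clade[ci], .CLADES$superfamily[ci])] <- p
    }
  }
  lib <- domain_library(Biostrings::AAStringSet(seqs))
  .ltrdyn_cache$synthetic_library <- lib
  lib
}

# Translate one frame; f in 1..3 on the given strand sequence.
.translate_frame <- function(dna, f) {
  n <- Biostrings::nchar(dna)
  len <- 3L * ((n - f + 1L) %/% 3L)
  if (len < 3L) return(NULL)
  sub <- Biostrings::subseq(dna, f, f + len - 1L)
  suppressWarnings(Biostrings::translate(sub, if.fuzzy.codon = "X"))
}

#' Scan DNA for Gag-Pol protein domain hits
#'
#' Six-frame translated search of `dna` against every protein in `library`
#' using local alignment with BLOSUM62 scoring. E-values follow
#' Karlin-Altschul statistics over a search space of (translated length x
#' total library length). Hits failing the coverage, identity or E-value
#' thresholds are dropped; survivors are returned sorted by ascending
#' E-value.
#'
#' @param dna Nucleotide sequence (character or `DNAString`), length >= 3.
#' @param library A `domain_library`.
#' @param min_coverage Minimum fraction of the library protein covered.
#' @param min_identity Minimum percent identity (strict inequality).
#' @param max_evalue Maximum E-value.
#' @return A data.frame of hits: `domain`, `clade`, `superfamily`,
#'   `coverage`, `identity`, `score`, `bits`, `e_value`, `frame` (+1..+3
#'   forward, -1..-3 reverse), `start`, `end` (coordinates on the forward
#'   strand of `dna`).
#' @export
scan_gag_pol <- function(dna, library, min_coverage = 0.5, min_identity = 30,
                         max_evalue = 1e-8) {
  if (!inherits(library, "domain_library") || length(library$seqs) == 0)
    stop("library must be a nonempty domain_library")
  dna <- .as_dna_string(dna)
  n <- Biostrings::nchar(dna)
  if (n < 3) stop("dna shorter than one codon")
  m_space <- n %/% 3L
  n_space <- sum(Biostrings::width(library$seqs))
  strands <- list(fwd = dna, rev = Biostrings::reverseComplement(dna))
  hits <- list()
  for (st in names(strands)) {
    for (f in 1:3) {
      aa <- .translate_frame(strands[[st]], f)
      if (is.null(aa) || Biostrings::nchar(aa) < 1) next
      # score-only prescreen: the E-value gate depends only on the score,
      # so the (more expensive) traceback runs just for passing patterns
      sc_all <- Biostrings::pairwiseAlignment(
        library$seqs, aa, type = "local", substitutionMatrix = "BLOSUM62",
        gapOpening = .AA_GAP_OPEN, gapExtension = .AA_GAP_EXT,
        scoreOnly = TRUE)
      cand <- which(.evalue_aa(sc_all, m_space, n_space) <= max_evalue)
      if (length(cand) == 0) next
      aln <- Biostrings::pairwiseAlignment(
        library$seqs[cand], aa, type = "local",
        substitutionMatrix = "BLOSUM62",
        gapOpening = .AA_GAP_OPEN, gapExtension = .AA_GAP_EXT)
      sc <- Biostrings::score(aln)
      ev <- .evalue_aa(sc, m_space, n_space)
      nm <- Biostrings::nmatch(aln)
      cols <- Biostrings::nchar(aln)
      ident <- nm / cols * 100
      pw <- IRanges::width(Biostrings::pattern(aln))
      cov <- pw / Biostrings::width(library$seqs)[cand]
      s_start <- IRanges::start(Biostrings::subject(aln))
      s_end <- IRanges::end(Biostrings::subject(aln))
      keep <- cov >= min_coverage & ident > min_identity & ev <= max_evalue
      if (!any(keep)) next
      idx <- cand[keep]
      aa_s <- s_start[keep]; aa_e <- s_end[keep]
      nt_s <- f + (aa_s - 1L) * 3L
      nt_e <- f + aa_e * 3L - 1L
      if (st == "rev") {
        tmp_s <- n - nt_e + 1L
        nt_e <- n - nt_s + 1L
        nt_s <- tmp_s
      }
      hits[[length(hits) + 1L]] <- data.frame(
        domain = library$info$domain[idx],
        clade = library$info$clade[idx],
        superfamily = library$info$superfamily[idx],
        coverage = cov[keep], identity = ident[keep],
        score = sc[keep], bits = .bits_aa(sc[keep]), e_value = ev[keep],
        frame = if (st == "fwd") f else -f,
        start = nt_s, end = nt_e, stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0) return(.empty_domain_hits())
  out <- do.call(rbind, hits)
  out <- out[order(out$e_value, -out$bits, out$domain, out$clade), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_domain_hits <- function() {
  data.frame(domain = character(), clade = character(),
             superfamily = character(), coverage = numeric(),
             identity = numeric(), score = numeric(), bits = numeric(),
             e_value = numeric(), frame = integer(), start = integer(),
             end = integer(), stringsAsFactors = FALSE)
}

#' Call element intactness from domain hits
#'
#' An element is intact when its internal region carries at least one
#' qualifying hit for every required domain (the complete Gag-Pol
#' complement GAG, PR, RT, RH, INT by default). The clade label is the modal
#' clade among the hits, ties broken lexicographically; the strand is
#' inferred from the majority hit frame sign.
#'
#' @param candidate One-row candidate data.frame (needs `element_id`,
#'   `internal_start`, `internal_end`).
#' @param hits Hit table from [scan_gag_pol()] in genomic coordinates.
#' @param required_domains Character vector of domains that define
#'   completeness.
#' @return A one-row data.frame: `element_id`, `is_intact`, `domains_found`
#'   (sorted, `+`-collapsed), `best_clade`, `superfamily`, `strand`.
#' @export
call_intact <- function(candidate, hits,
                        required_domains = c("GAG", "PR", "RT", "RH", "INT")) {
  if (nrow(hits) > 0) {
    outside <- hits$start < candidate$internal_start |
      hits$end > candidate$internal_end
    if (any(outside))
      stop("domain hit outside internal region of ", candidate$element_id)
  }
  found <- sort(unique(hits$domain))
  is_intact <- all(required_domains %in% found)
  best_clade <- NA_character_
  superfamily <- NA_character_
  strand <- "."
  if (nrow(hits) > 0) {
    tab <- table(hits$clade)
    best_clade <- sort(names(tab)[tab == max(tab)])[1]
    superfamily <- hits$superfamily[hits$clade == best_clade][1]
    strand <- if (sum(hits$frame > 0) >= sum(hits$frame < 0)) "+" else "-"
  }
  data.frame(element_id = candidate$element_id, is_intact = is_intact,
             domains_found = paste(found, collapse = "+"),
             best_clade = best_clade, superfamily = superfamily,
             strand = strand, stringsAsFactors = FALSE)
}

#' Scan all candidates and call intactness
#'
#' Convenience wrapper: extracts each candidate's internal region, runs
#' [scan_gag_pol()], shifts hit coordinates to genomic positions and applies
#' [call_intact()].
#'
#' @param genome Named `DNAStringSet`.
#' @param candidates Candidate table from [find_ltr_candidates()].
#' @param library A `domain_library`.
#' @param scan [scan_params()].
#' @param required_domains Domains defining completeness.
#' @return A list with `calls` (one row per candidate) and `hits` (all
#'   qualifying hits, genomic coordinates, with `element_id`).
#' @export
scan_candidates <- function(genome, candidates, library,
                            scan = scan_params(),
                            required_domains = c("GAG", "PR", "RT", "RH", "INT")) {
  calls <- list(); all_hits <- list()
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    s <- Biostrings::subseq(genome[[cand$seq_id]],
                            cand$internal_start, cand$internal_end)
    h <- scan_gag_pol(s, library, scan$min_coverage, scan$min_identity,
                      scan$max_evalue)
    if (nrow(h) > 0) {
      h$start <- h$start + cand$internal_start - 1L
      h$end <- h$end + cand$internal_start - 1L
      h <- cbind(element_id = cand$element_id, h, stringsAsFactors = FALSE)
      all_hits[[length(all_hits) + 1L]] <- h
    }
    h_call <- h
    h_call$element_id <- NULL
    calls[[i]] <- call_intact(cand, h_call, required_domains)
  }
  list(calls = do.call(rbind, calls),
       hits = if (length(all_hits)) do.call(rbind, all_hits) else NULL)
}
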