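# Genome-wide homologs of intact elements' 5' LTRs, classified into
# solo-LTRs and truncated elements.
#
# Each intact element's 5' LTR is searched against the genome (intact loci
# masked) with BLASTN-like thresholds: E-value <= 1e-10, >= 90% of the query
# length aligned, >= 90% identity. For every retained homolog, 3 kb of
# sequence on each side is scanned for Gag-Pol protein homology: no evidence
# on either side = solo-LTR, evidence on exactly one side = truncated
# element; both sides (an unannotated intact-like locus) is reported as
# AMBIGUOUS and kept out of the S/T tallies.

.HOMOLOG_SEED_K <- 16L

#' Find genome-wide homologs of intact elements' LTRs
#'
#' Seed-and-extend search of every intact element's 5' LTR against the
#' genome. Exact 16-mer seeds define candidate windows, each window is
#' aligned locally against the query for scoring and thresholding, and a
#' query-global alignment fixes the homolog boundaries (so terminal
#' substitutions do not erode them). Hits overlapping any intact element are
#' discarded (masking); overlapping hits from different queries are merged
#' and assigned to the best-scoring source element (ties: higher identity,
#' then longer alignment, then lowest source id).
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param intact_elements Candidate rows with `is_intact` calls applied, i.e.
#'   the intact subset of [find_ltr_candidates()] output.
#' @param params [homology_params()].
#' @return A data.frame: `homolog_id`, `seq_id`, `start`, `end`,
#'   `source_element`, `identity`, `overlap`, `e_value`.
#' @export
find_ltr_homologs <- function(genome, intact_elements,
                              params = homology_params()) {
  if (is.null(intact_elements) || nrow(intact_elements) == 0)
    stop("no intact elements: remnant classification is undefined")
  genome_len <- sum(as.numeric(Biostrings::width(genome)))
  hits <- list()
  for (sq in names(genome)) {
    s <- as.character(genome[[sq]])
    v <- .dna_int(s)
    codes <- .kmer_codes(v, .HOMOLOG_SEED_K)
    mask <- intact_elements[intact_elements$seq_id == sq, , drop = FALSE]
    for (qi in seq_len(nrow(intact_elements))) {
      q <- intact_elements[qi, ]
      qseq <- Biostrings::subseq(genome[[q$seq_id]], q$ltr5_start, q$ltr5_end)
      h <- .search_query_windows(s, codes, as.character(qseq), genome_len,
                                 params)
      if (is.null(h) || nrow(h) == 0) next
      h$seq_id <- sq
      h$source_element <- q$element_id
      # masking: drop hits overlapping any intact element locus
      if (nrow(mask) > 0) {
        ov <- vapply(seq_len(nrow(h)), function(i) {
          any(h$start[i] <= mask$end & h$end[i] >= mask$start)
        }, logical(1))
        h <- h[!ov, , drop = FALSE]
      }
      if (nrow(h) > 0) hits[[length(hits) + 1L]] <- h
    }
  }
  if (length(hits) == 0) return(.empty_homologs())
  all <- do.call(rbind, hits)
  # merge overlapping hits: best source wins
  out <- list()
  for (sq in unique(all$seq_id)) {
    a <- all[all$seq_id == sq, , drop = FALSE]
    ir <- IRanges::IRanges(a$start, a$end)
    grp <- S4Vectors::subjectHits(
      IRanges::findOverlaps(ir, IRanges::reduce(ir)))
    for (g in unique(grp)) {
      b <- a[grp == g, , drop = FALSE]
      b <- b[order(-b$score, -b$identity, -(b$end - b$start), b$source_element), ,
             drop = FALSE]
      out[[length(out) + 1L]] <- b[1, , drop = FALSE]
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$seq_id, res$start), , drop = FALSE]
  res$homolog_id <- sprintf("H%04d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res[, c("homolog_id", "seq_id", "start", "end", "source_element",
          "identity", "overlap", "e_value", "score")]
}

.empty_homologs <- function() {
  data.frame(homolog_id = character(), seq_id = character(),
             start = integer(), end = integer(),
             source_element = character(), identity = numeric(),
             overlap = numeric(), e_value = numeric(), score = numeric(),
             stringsAsFactors = FALSE)
}

# Seed-driven window search of one query against one coded sequence.
.search_query_windows <- function(s, codes, qseq, genome_len, params) {
  n <- nchar(s)
  qlen <- nchar(qseq)
  qv <- .dna_int(qseq)
  qcodes <- .kmer_codes(qv, .HOMOLOG_SEED_K)
  qok <- which(!is.na(qcodes))
  if (length(qok) == 0) return(NULL)
  uq <- unique(qcodes[qok])
  gpos <- which(codes %in% uq)
  if (length(gpos) == 0) return(NULL)
  # implied query-start position for each seed match
  qpos_by_code <- split(qok, qcodes[qok])
  mm <- match(codes[gpos], as.numeric(names(qpos_by_code)))
  starts <- integer(0)
  for (i in seq_along(gpos)) {
    qp <- qpos_by_code[[mm[i]]]
    starts <- c(starts, gpos[i] - qp + 1L)
  }
  starts <- sort(unique(starts))
  # windows around implied query placements, merged when overlapping
  margin <- 100L
  win <- IRanges::reduce(IRanges::IRanges(
    pmax(1L, starts - margin), pmin(n, starts + qlen - 1L + margin)))
  res <- list()
  qds <- Biostrings::DNAString(qseq)
  for (i in seq_along(win)) {
    ws <- IRanges::start(win)[i]; we <- IRanges::end(win)[i]
    wseq <- Biostrings::DNAString(substr(s, ws, we))
    aln <- .align_nt(qds, wseq, type = "local")
    sc <- Biostrings::score(aln)
    if (sc <= 0) next
    ident <- .aln_identity(aln)
    overlap <- IRanges::width(Biostrings::pattern(aln)) / qlen
    ev <- .evalue_nt(sc, qlen, genome_len)
    if (ev > params$max_evalue || overlap < params$min_overlap ||
        ident < params$min_identity) next
    # query-global alignment pins the full homolog extent
    gl <- .align_nt(qds, wseq, type = "global-local")
    hs <- ws + IRanges::start(Biostrings::subject(gl)) - 1L
    he <- ws + IRanges::end(Biostrings::subject(gl)) - 1L
    res[[length(res) + 1L]] <- data.frame(
      start = hs, end = he, identity = ident, overlap = overlap,
      e_value = ev, score = sc, stringsAsFactors = FALSE)
  }
  if (length(res) == 0) return(NULL)
  do.call(rbind, res)
}

#' Classify one LTR homolog as solo or truncated
#'
#' Extracts up to `params$flank_len` bp upstream and downstream of the
#' homolog (clipped at sequence ends), scans each flank for Gag-Pol domain
#' hits, and applies the two-sided rule: no hit on either side = `SOLO`, a
#' hit on exactly one side = `TRUNCATED`, hits on both sides = `AMBIGUOUS`.
#' A TSD is searched around the homolog boundaries with the same anchored
#' semantics as [detect_tsd()]; solo-LTRs born by unequal recombination
#' between the two LTRs of one element retain their TSD, deletion-derived
#' remnants generally do not.
#'
#' @param genome Named `DNAStringSet`.
#' @param homolog One row of [find_ltr_homologs()] output.
#' @param library A `domain_library`.
#' @param params [homology_params()] (for `flank_len`).
#' @param scan [scan_params()] thresholds for the flank scan.
#' @param detection [detection_params()] (for the TSD length range).
#' @return One-row data.frame: `homolog_id`, `category`, `upstream_gagpol`,
#'   `downstream_gagpol`, `tsd`.
#' @export
classify_remnant <- function(genome, homolog, library,
                             params = homology_params(),
                             scan = scan_params(),
                             detection = detection_params()) {
  s <- genome[[homolog$seq_id]]
  n <- Biostrings::nchar(s)
  up_s <- max(1L, homolog$start - params$flank_len)
  up_e <- homolog$start - 1L
  dn_s <- homolog$end + 1L
  dn_e <- min(n, homolog$end + params$flank_len)
  if (up_e < up_s && dn_s > dn_e)
    stop("homolog ", homolog$homolog_id, " spans the whole sequence: no flanks")
  flank_hit <- function(a, b) {
    if (b < a || b - a + 1L < 3L) return(FALSE)
    h <- scan_gag_pol(Biostrings::subseq(s, a, b), library,
                      scan$min_coverage, scan$min_identity, scan$max_evalue)
    nrow(h) > 0
  }
  up <- flank_hit(up_s, up_e)
  dn <- flank_hit(dn_s, dn_e)
  category <- if (!up && !dn) "SOLO" else if (xor(up, dn)) "TRUNCATED" else "AMBIGUOUS"
  t <- .detect_tsd_at(as.character(s), homolog$start, homolog$end,
                      detection$tsd_min, detection$tsd_max)
  data.frame(homolog_id = homolog$homolog_id, category = category,
             upstream_gagpol = up, downstream_gagpol = dn,
             tsd = if (is.null(t)) NA_character_ else t$tsd,
             stringsAsFactors = FALSE)
}

#' Classify all homologs
#'
#' @param genome Named `DNAStringSet`.
#' @param homologs Output of [find_ltr_homologs()].
#' @param library A `domain_library`.
#' @param params,scan,detection See [classify_remnant()].
#' @return The homolog table with `category`, `upstream_gagpol`,
#'   `downstream_gagpol` and `tsd` columns appended.
#' @export
classify_remnants <- function(genome, homologs, library,
                              params = homology_params(),
                              scan = scan_params(),
                              detection = detection_params()) {
  if (nrow(homologs) == 0) {
    out <- homologs
    out$category <- character(0); out$upstream_gagpol <- logical(0)
    out$downstream_gagpol <- logical(0); out$tsd <- character(0)
    return(out)
  }
  calls <- do.call(rbind, lapply(seq_len(nrow(homologs)), function(i) {
    classify_remnant(genome, homologs[i, ], library, params, scan, detection)
  }))
  cbind(homologs, calls[, c("category", "upstream_gagpol",
                            "downstream_gagpol", "tsd")])
}
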