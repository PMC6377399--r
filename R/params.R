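#' Structural detection parameters
#'
#' Constraints a candidate LTR retrotransposon must satisfy: the two LTRs are
#' 100-3,000 bp long, at least 80% identical to each other, and the whole
#' element spans 1-15 kb. Target site duplications (TSDs) are searched as
#' exact direct repeats of 4-6 bp anchored at the element boundaries.
#'
#' @param min_ltr_len,max_ltr_len Allowed LTR length range in bp.
#' @param min_element_span,max_element_span Allowed span in bp from the start
#'   of the 5' LTR to the end of the 3' LTR.
#' @param min_ltr_identity Minimum global-alignment identity (percent) between
#'   the two LTRs of one element.
#' @param tsd_min,tsd_max TSD length range in bp.
#' @param tsd_search_window Window in bp examined around element boundaries.
#' @param seed_len Exact-match seed length (bp) used by the candidate search.
#' @return A list of class `ltr_detection_params`.
#' @export
detection_params <- function(min_ltr_len = 100, max_ltr_len = 3000,
                             min_element_span = 1000, max_element_span = 15000,
                             min_ltr_identity = 80,
                             tsd_min = 4, tsd_max = 6, tsd_search_window = 20,
                             seed_len = 20) {
  p <- list(min_ltr_len = min_ltr_len, max_ltr_len = max_ltr_len,
            min_element_span = min_element_span,
            max_element_span = max_element_span,
            min_ltr_identity = min_ltr_identity,
            tsd_min = tsd_min, tsd_max = tsd_max,
            tsd_search_window = tsd_search_window, seed_len = seed_len)
  if (p$min_ltr_len >= p$max_ltr_len)
    stop("min_ltr_len must be < max_ltr_len")
  if (p$min_element_span >= p$max_element_span)
    stop("min_element_span must be < max_element_span")
  if (p$tsd_min > p$tsd_max) stop("tsd_min must be <= tsd_max")
  if (p$min_ltr_identity <= 0 || p$min_ltr_identity > 100)
    stop("min_ltr_identity must be in (0, 100]")
  if (p$seed_len < 8 || p$seed_len > 24)
    stop("seed_len must be in [8, 24]")
  structure(p, class = "ltr_detection_params")
}

#' LTR homology search parameters
#'
#' Thresholds for recovering genome-wide homologs of intact elements' LTRs
#' (the solo/truncated remnant search): E-value cutoff 1e-10, at least 90% of
#' the query LTR length aligned, at least 90% identity, and 3 kb of flanking
#' sequence on each side scanned for Gag-Pol homology.
#'
#' @param max_evalue Maximum alignment E-value.
#' @param min_overlap Minimum aligned fraction of the query LTR length.
#' @param min_identity Minimum alignment identity in percent.
#' @param flank_len Flank length in bp scanned for Gag-Pol evidence.
#' @return A list of class `ltr_homology_params`.
#' @export
homology_params <- function(max_evalue = 1e-10, min_overlap = 0.90,
                            min_identity = 90, flank_len = 3000) {
  if (min_overlap <= 0 || min_overlap > 1)
    stop("min_overlap must be in (0, 1]")
  if (min_identity <= 0 || min_identity > 100)
    stop("min_identity must be in (0, 100]")
  if (max_evalue <= 0) stop("max_evalue must be positive")
  if (flank_len < 1) stop("flank_len must be >= 1")
  structure(list(max_evalue = max_evalue, min_overlap = min_overlap,
                 min_identity = min_identity, flank_len = flank_len),
            class = "ltr_homology_params")
}

#' Family clustering parameters
#'
#' Two LTR sequences are joined when their best local alignment mutually
#' covers at least `min_mutual_coverage` of both lengths at
#' `min_identity` percent identity or better. 60% identity defines the
#' superfamily level, 80% the family level.
#'
#' @param min_mutual_coverage Minimum aligned fraction of both sequences.
#' @param min_identity Minimum alignment identity in percent.
#' @param level_label Free-text label for the clustering level.
#' @return A list of class `ltr_cluster_params`.
#' @export
cluster_params <- function(min_mutual_coverage = 0.70, min_identity = 60,
                           level_label = "superfamily") {
  if (min_mutual_coverage <= 0 || min_mutual_coverage > 1)
    stop("min_mutual_coverage must be in (0, 1]")
  if (min_identity <= 0 || min_identity > 100)
    stop("min_identity must be in (0, 100]")
  structure(list(min_mutual_coverage = min_mutual_coverage,
                 min_identity = min_identity, level_label = level_label),
            class = "ltr_cluster_params")
}

#' Gag-Pol domain scan thresholds
#'
#' A translated-nucleotide hit against a library protein qualifies when it
#' covers at least half of that protein, exceeds 30% identity and has an
#' E-value of at most 1e-8.
#'
#' @param min_coverage Minimum covered fraction of the library protein.
#' @param min_identity Minimum percent identity (strict: hits at exactly this
#'   value are rejected).
#' @param max_evalue Maximum E-value.
#' @return A list of class `gagpol_scan_params`.
#' @export
scan_params <- function(min_coverage = 0.5, min_identity = 30,
                        max_evalue = 1e-8) {
  if (min_coverage <= 0 || min_coverage > 1)
    stop("min_coverage must be in (0, 1]")
  if (min_identity < 0 || min_identity >= 100)
    stop("min_identity must be in [0, 100)")
  if (max_evalue <= 0) stop("max_evalue must be positive")
  structure(list(min_coverage = min_coverage, min_identity = min_identity,
                 max_evalue = max_evalue), class = "gagpol_scan_params")
}
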