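# Insertion-age dating from LTR-LTR divergence.
#
# At integration the two LTRs of an element are identical; each then
# accumulates substitutions independently at rate mu per site per year, so
# the K2P distance K between them estimates 2*mu*T and the insertion time is
# T = K / (2*mu). The default rate is mu = 1.3e-8 substitutions/site/year.

#' Align the two LTRs of one element and count substitution classes
#'
#' Global alignment under the package's fixed nucleotide scoring. Columns
#' containing a gap or an N are excluded from the site count; among the
#' remaining columns, transitions are A<->G and C<->T, everything else that
#' differs is a transversion.
#'
#' @param ltr5,ltr3 The two LTR sequences (character or `DNAString`).
#' @param element_id Optional id carried through to the result.
#' @return A list of class `ltr_pair_alignment`: `element_id`, `aligned_len`
#'   (alignment columns), `n_sites` (ungapped unambiguous columns), `P`
#'   (transition proportion), `Q` (transversion proportion).
#' @export
align_ltr_pair <- function(ltr5, ltr3, element_id = NA_character_) {
  ltr5 <- as.character(ltr5); ltr3 <- as.character(ltr3)
  if (nchar(ltr5) == 0 || nchar(ltr3) == 0)
    stop("LTR sequences must be nonempty")
  aln <- .align_nt(Biostrings::DNAString(ltr5), Biostrings::DNAString(ltr3))
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  keep <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[keep]; b <- b[keep]
  n_sites <- length(a)
  diff <- a != b
  purine <- c("A", "G")
  is_ts <- diff & ((a %in% purine) == (b %in% purine))
  structure(list(element_id = element_id, aligned_len = Biostrings::nchar(aln),
                 n_sites = n_sites,
                 P = if (n_sites > 0) sum(is_ts) / n_sites else NA_real_,
                 Q = if (n_sites > 0) sum(diff & !is_ts) / n_sites else NA_real_),
            class = "ltr_pair_alignment")
}

#' Kimura two-parameter distance
#'
#' `K = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` with `P` the transition and
#' `Q` the transversion proportion. When `1 - 2P - Q <= 0` or `1 - 2Q <= 0`
#' the distance is saturated: no finite estimate exists and `K` is `NA` with
#' `saturated = TRUE`.
#'
#' @param P Transition proportion, or an `ltr_pair_alignment` object.
#' @param Q Transversion proportion (ignored when `P` is an alignment).
#' @return A list: `K` (substitutions/site, `NA` when saturated),
#'   `saturated` (logical).
#' @export
k2p_distance <- function(P, Q = NULL) {
  if (inherits(P, "ltr_pair_alignment")) {
    if (P$n_sites == 0) stop("no informative sites in alignment")
    Q <- P$Q; P <- P$P
  }
  stopifnot(is.numeric(P), is.numeric(Q))
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(list(K = NA_real_, saturated = TRUE))
  list(K = -0.5 * log(w1) - 0.25 * log(w2), saturated = FALSE)
}

#' Insertion time from a K2P distance
#'
#' `T = K / (2 mu)` years: both LTRs diverge independently, so the pairwise
#' distance grows at twice the per-lineage rate.
#'
#' @param K K2P distance in substitutions per site (`NA` when saturated).
#' @param mu Substitution rate per site per year.
#' @param saturated Logical; a saturated input yields `NA` ages, never a
#'   number.
#' @return A list: `K`, `mu`, `saturated`, `T_years`, `T_mya`.
#' @export
insertion_time <- function(K, mu = 1.3e-8, saturated = FALSE) {
  if (mu <= 0) stop("mu must be positive")
  if (saturated || is.na(K)) {
    return(list(K = NA_real_, mu = mu, saturated = TRUE,
                T_years = NA_real_, T_mya = NA_real_))
  }
  if (K < 0) stop("K must be >= 0")
  T_years <- K / (2 * mu)
  list(K = K, mu = mu, saturated = FALSE, T_years = T_years,
       T_mya = T_years / 1e6)
}

#' Date all intact elements of a candidate table
#'
#' @param genome Named `DNAStringSet`.
#' @param elements Candidate rows to date (normally the intact subset).
#' @param mu Substitution rate per site per year.
#' @return A data.frame: `element_id`, `aligned_len`, `n_sites`, `P`, `Q`,
#'   `K`, `saturated`, `T_years`, `T_mya`.
#' @export
date_elements <- function(genome, elements, mu = 1.3e-8) {
  rows <- lapply(seq_len(nrow(elements)), function(i) {
    e <- elements[i, ]
    s <- genome[[e$seq_id]]
    aln <- align_ltr_pair(Biostrings::subseq(s, e$ltr5_start, e$ltr5_end),
                          Biostrings::subseq(s, e$ltr3_start, e$ltr3_end),
                          element_id = e$element_id)
    k <- k2p_distance(aln)
    t <- insertion_time(k$K, mu, k$saturated)
    data.frame(element_id = e$element_id, aligned_len = aln$aligned_len,
               n_sites = aln$n_sites, P = aln$P, Q = aln$Q, K = t$K,
               saturated = t$saturated, T_years = t$T_years, T_mya = t$T_mya,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(element_id = character(), aligned_len = integer(),
                      n_sites = integer(), P = numeric(), Q = numeric(),
                      K = numeric(), saturated = logical(),
                      T_years = numeric(), T_mya = numeric(),
                      stringsAsFactors = FALSE)
  out
}
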