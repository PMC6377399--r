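# Shared alignment plumbing: fixed scoring schemes, identity/coverage
# extraction and Karlin-Altschul E-values. All pairwise alignments in the
# package run through Biostrings::pairwiseAlignment with the schemes below so
# every identity threshold is reproducible.

.ltrdyn_cache <- new.env(parent = emptyenv())

# Nucleotide scoring: match +2 / mismatch -3, affine gaps open 5 / extend 2.
.nt_submat <- function() {
  if (is.null(.ltrdyn_cache$nt_submat)) {
    .ltrdyn_cache$nt_submat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = FALSE, type = "DNA")
  }
  .ltrdyn_cache$nt_submat
}

.NT_GAP_OPEN <- 5
.NT_GAP_EXT <- 2
.AA_GAP_OPEN <- 11
.AA_GAP_EXT <- 1

# Karlin-Altschul lambda for the ungapped +2/-3 scheme with uniform base
# composition: solves (1/4) e^{2L} + (3/4) e^{-3L} = 1. K is kept as a fixed
# documented constant; with 1e-10 cutoffs against alignments hundreds of bp
# long the E-value decision is insensitive to K to many orders of magnitude.
.nt_lambda <- function() {
  if (is.null(.ltrdyn_cache$nt_lambda)) {
    f <- function(l) 0.25 * exp(2 * l) + 0.75 * exp(-3 * l) - 1
    .ltrdyn_cache$nt_lambda <- stats::uniroot(f, c(1e-6, 2), tol = 1e-12)$root
  }
  .ltrdyn_cache$nt_lambda
}
.NT_KA_K <- 0.3

# Gapped BLOSUM62 (open 11 / extend 1) Karlin-Altschul constants.
.AA_LAMBDA <- 0.267
.AA_KA_K <- 0.041

.as_dna_string <- function(x) {
  if (is(x, "DNAString")) x else Biostrings::DNAString(as.character(x))
}

#' @noRd
.align_nt <- function(pattern, subject, type = "global") {
  Biostrings::pairwiseAlignment(
    pattern, subject, type = type,
    substitutionMatrix = .nt_submat(),
    gapOpening = .NT_GAP_OPEN, gapExtension = .NT_GAP_EXT)
}

# Percent identity over all alignment columns (matches / columns * 100).
.aln_identity <- function(aln) {
  Biostrings::nmatch(aln) / Biostrings::nchar(aln) * 100
}

# E-value of a nucleotide alignment score over search space m x n.
.evalue_nt <- function(score, m, n) {
  .NT_KA_K * as.numeric(m) * as.numeric(n) * exp(-.nt_lambda() * score)
}

# Bit score and E-value for protein alignments.
.bits_aa <- function(score) (.AA_LAMBDA * score - log(.AA_KA_K)) / log(2)
.evalue_aa <- function(score, m, n) {
  as.numeric(m) * as.numeric(n) * 2^(-.bits_aa(score))
}

#' Global alignment identity between two nucleotide sequences
#'
#' Needleman-Wunsch alignment under the package's fixed nucleotide scoring
#' (match +2, mismatch -3, gap open 5, gap extend 2); identity is
#' matches / alignment columns x 100.
#'
#' @param a,b Nucleotide sequences (character or `DNAString`).
#' @return Percent identity (numeric scalar).
#' @export
ltr_identity <- function(a, b) {
  .aln_identity(.align_nt(.as_dna_string(a), .as_dna_string(b)))
}
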