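# De novo structural detection of LTR retrotransposon candidates.
#
# Search strategy: exact k-mer seeds shared between two positions of the same
# sequence define diagonals (candidate LTR-LTR offsets); seeds on one
# diagonal are clustered and extended outward by an ungapped X-drop scan,
# giving the maximal repeat extent; the two repeat copies are then aligned
# globally to score LTR identity, and structural constraints (LTR length,
# element span, identity, low-complexity guard) are applied. With the
# substitution-dominated divergence typical of young LTR pairs the two copies
# stay on one diagonal, so ungapped extension recovers boundaries to within a
# few bp.

.DNA_CODE <- {
  m <- rep(-1L, 256)
  m[utf8ToInt("A") + 1L] <- 0L
  m[utf8ToInt("C") + 1L] <- 1L
  m[utf8ToInt("G") + 1L] <- 2L
  m[utf8ToInt("T") + 1L] <- 3L
  m
}

# Integer encoding A=0 C=1 G=2 T=3, anything else -1.
.dna_int <- function(seq_chr) {
  .DNA_CODE[utf8ToInt(seq_chr) + 1L]
}

# k-mer codes as doubles (exact up to k = 24); positions containing N get NA.
.kmer_codes <- function(v, k) {
  n <- length(v) - k + 1L
  if (n < 1) return(numeric(0))
  code <- numeric(n)
  for (j in 0:(k - 1L)) {
    code <- code + pmax(v[(1L + j):(n + j)], 0L) * 4^(k - 1L - j)
  }
  bad <- cumsum(v < 0L)
  nbad <- bad[k:length(v)] - c(0, bad[seq_len(n - 1L)])
  code[nbad > 0] <- NA_real_
  code
}

# Ungapped X-drop extension along one diagonal. v: integer-coded sequence,
# idx: candidate positions of the first copy in extension order, d: offset to
# the second copy. Returns how many steps extend (0 if none).
.xdrop_extend <- function(v, idx, d, match_score = 1, mismatch_score = -3,
                          xdrop = 24) {
  if (length(idx) == 0) return(0L)
  a <- v[idx]
  b <- v[idx + d]
  m <- (a == b) & (a >= 0L)
  sc <- cumsum(ifelse(m, match_score, mismatch_score))
  drop <- cummax(sc) - sc
  stop_i <- which(drop > xdrop)[1]
  lim <- if (is.na(stop_i)) length(sc) else stop_i
  top <- max(sc[seq_len(lim)])
  if (top <= 0) return(0L)
  which.max(sc[seq_len(lim)])
}

#' Find candidate LTR retrotransposons in a genome sequence
#'
#' Detects pairs of direct repeats (putative 5' and 3' LTRs) that satisfy the
#' structural constraints in `params`: LTR length 100-3,000 bp, element span
#' 1-15 kb, and >80% LTR-LTR global identity by default. Overlapping
#' candidates are resolved in favour of higher identity, then longer span,
#' then leftmost position, so no reported candidate is contained in another.
#' TSDs are searched for every accepted candidate but never used as an
#' acceptance filter. Deterministic for fixed input and parameters.
#'
#' @param genome A named [Biostrings::DNAStringSet] (all sequences are
#'   scanned), or a single sequence (character or `DNAString`) together with
#'   `seq_id`.
#' @param params [detection_params()].
#' @param seq_id Sequence name used when `genome` is a bare sequence.
#' @return A data.frame with one row per candidate: `element_id`, `seq_id`,
#'   `start`, `end`, LTR and internal-region coordinates, `ltr_identity`,
#'   `strand` (reported as `.` until domain evidence orients the element),
#'   and TSD columns (`tsd` is `NA` when no anchored direct repeat of
#'   qualifying length exists).
#' @export
find_ltr_candidates <- function(genome, params = detection_params(),
                                seq_id = "seq") {
  if (is(genome, "DNAStringSet")) {
    res <- lapply(seq_along(genome), function(i) {
      .find_ltr_candidates_one(as.character(genome[[i]]), params,
                               names(genome)[i])
    })
    out <- do.call(rbind, res)
  } else {
    out <- .find_ltr_candidates_one(as.character(genome), params, seq_id)
  }
  if (is.null(out) || nrow(out) == 0) return(.empty_candidates())
  out$element_id <- sprintf("%s_RT%04d", out$seq_id,
                            stats::ave(seq_len(nrow(out)), out$seq_id,
                                       FUN = seq_along))
  rownames(out) <- NULL
  out
}

.empty_candidates <- function() {
  data.frame(element_id = character(), seq_id = character(),
             start = integer(), end = integer(),
             ltr5_start = integer(), ltr5_end = integer(),
             ltr3_start = integer(), ltr3_end = integer(),
             internal_start = integer(), internal_end = integer(),
             ltr_identity = numeric(), strand = character(),
             tsd = character(), tsd5_start = integer(), tsd5_end = integer(),
             tsd3_start = integer(), tsd3_end = integer(),
             stringsAsFactors = FALSE)
}

.find_ltr_candidates_one <- function(s, params, seq_id) {
  n <- nchar(s)
  if (n <= params$min_element_span) return(NULL)
  v <- .dna_int(s)
  k <- params$seed_len
  codes <- .kmer_codes(v, k)
  ok <- which(!is.na(codes))
  if (length(ok) < 2) return(NULL)
  cd <- codes[ok]
  ord <- order(cd, ok)
  cd_s <- cd[ord]
  pos_s <- ok[ord]
  new_grp <- c(TRUE, diff(cd_s) != 0)
  grp <- cumsum(new_grp)
  sizes <- tabulate(grp)
  multi <- which(sizes >= 2L & sizes <= 200L)
  if (length(multi) == 0) return(NULL)
  d_min <- params$min_ltr_len
  d_max <- params$max_element_span - params$min_ltr_len
  pair_a <- vector("list", length(multi))
  pair_d <- vector("list", length(multi))
  for (gi in seq_along(multi)) {
    p <- pos_s[grp == multi[gi]]
    m <- length(p)
    a <- rep(p, times = m)
    b <- rep(p, each = m)
    sel <- (b - a) >= d_min & (b - a) <= d_max
    pair_a[[gi]] <- a[sel]
    pair_d[[gi]] <- (b - a)[sel]
  }
  pa <- unlist(pair_a)
  pd <- unlist(pair_d)
  if (length(pa) == 0) return(NULL)
  dup <- duplicated(pd * (n + 1) + pa)
  pa <- pa[!dup]; pd <- pd[!dup]

  cands <- list()
  join_gap <- 150L
  for (d in sort(unique(pd))) {
    aa <- sort(pa[pd == d])
    cl <- cumsum(c(TRUE, diff(aa) > join_gap))
    for (ci in unique(cl)) {
      p <- aa[cl == ci]
      a_seed <- p[1]
      b_seed <- p[length(p)] + k - 1L
      # extend left from a_seed-1 and right from b_seed+1 on diagonal d
      lo <- max(1L, b_seed - params$max_ltr_len + 1L, a_seed - params$max_ltr_len)
      left_idx <- if (a_seed > lo) seq(a_seed - 1L, lo) else integer(0)
      nl <- .xdrop_extend(v, left_idx, d)
      hi <- min(n - d, a_seed + params$max_ltr_len - 1L)
      right_idx <- if (b_seed < hi) seq(b_seed + 1L, hi) else integer(0)
      nr <- .xdrop_extend(v, right_idx, d)
      a0 <- a_seed - nl
      b0 <- b_seed + nr
      L <- b0 - a0 + 1L
      if (L < params$min_ltr_len || L > params$max_ltr_len) next
      if (L > d) next  # copies overlap
      span <- d + L
      if (span < params$min_element_span || span > params$max_element_span) next
      # TSD-guided boundary refinement: chance matches just outside the true
      # element let the ungapped extension overrun by a base or two, and a
      # mismatch cluster at an LTR edge can make the stiff extension stop
      # short by tens of bp. A lenient re-extension (rescue) proposes an
      # alternative boundary pair, and anchored TSD parses are searched at
      # both, canonical 5-bp TSDs before other lengths.
      lo2 <- max(1L, a0 - 40L)
      lidx <- if (a0 > lo2) seq(a0 - 1L, lo2) else integer(0)
      n1 <- .xdrop_extend(v, lidx, d, mismatch_score = -1, xdrop = 12)
      hi2 <- min(n - d, b0 + 40L)
      ridx <- if (b0 < hi2) seq(b0 + 1L, hi2) else integer(0)
      n2 <- .xdrop_extend(v, ridx, d, mismatch_score = -1, xdrop = 12)
      rescued <- if (n1 > 0L || n2 > 0L) c(a0 - n1, b0 + n2 + d) else NULL
      lens <- seq(params$tsd_min, params$tsd_max)
      canon <- lens[lens == 5L]
      other <- lens[lens != 5L]
      other <- other[order(abs(other - 5L), -other)]
      ref <- NULL
      for (lset in list(canon, other)) {
        if (length(lset) == 0) next
        ref <- .refine_by_tsd(s, a0, b0 + d, params, lens = lset)
        if (is.null(ref) && !is.null(rescued))
          ref <- .refine_by_tsd(s, rescued[1], rescued[2], params,
                                lens = lset)
        if (!is.null(ref)) break
      }
      if (!is.null(ref)) {
        a0 <- ref$start
        b0 <- ref$end - d
        L <- b0 - a0 + 1L
        if (L < params$min_ltr_len || L > params$max_ltr_len || L > d) next
      }
      ltr5 <- substr(s, a0, b0)
      if (length(unique(strsplit(ltr5, "")[[1]])) < 3) next  # low complexity
      ltr3 <- substr(s, a0 + d, b0 + d)
      ident <- ltr_identity(ltr5, ltr3)
      if (ident < params$min_ltr_identity) next
      cands[[length(cands) + 1L]] <- list(a0 = a0, b0 = b0, d = d,
                                          L = L, span = span, ident = ident)
    }
  }
  if (length(cands) == 0) return(NULL)
  cdf <- do.call(rbind, lapply(cands, as.data.frame))
  cdf <- cdf[!duplicated(cdf[, c("a0", "b0", "d")]), , drop = FALSE]
  # overlap resolution: higher identity, then longer, then leftmost
  cdf <- cdf[order(-cdf$ident, -cdf$span, cdf$a0), , drop = FALSE]
  kept <- logical(0)
  kstart <- integer(0); kend <- integer(0)
  keep_rows <- integer(0)
  for (i in seq_len(nrow(cdf))) {
    st <- cdf$a0[i]; en <- cdf$b0[i] + cdf$d[i]
    if (!any(st <= kend & en >= kstart)) {
      keep_rows <- c(keep_rows, i)
      kstart <- c(kstart, st); kend <- c(kend, en)
    }
  }
  cdf <- cdf[keep_rows, , drop = FALSE]
  cdf <- cdf[order(cdf$a0), , drop = FALSE]

  out <- data.frame(
    element_id = NA_character_, seq_id = seq_id,
    start = cdf$a0, end = cdf$b0 + cdf$d,
    ltr5_start = cdf$a0, ltr5_end = cdf$b0,
    ltr3_start = cdf$a0 + cdf$d, ltr3_end = cdf$b0 + cdf$d,
    internal_start = cdf$b0 + 1L, internal_end = cdf$a0 + cdf$d - 1L,
    ltr_identity = cdf$ident, strand = ".",
    tsd = NA_character_, tsd5_start = NA_integer_, tsd5_end = NA_integer_,
    tsd3_start = NA_integer_, tsd3_end = NA_integer_,
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    t <- .detect_tsd_at(s, out$start[i], out$end[i],
                        params$tsd_min, params$tsd_max)
    if (!is.null(t)) {
      out$tsd[i] <- t$tsd
      out$tsd5_start[i] <- t$tsd5[1]; out$tsd5_end[i] <- t$tsd5[2]
      out$tsd3_start[i] <- t$tsd3[1]; out$tsd3_end[i] <- t$tsd3[2]
    }
  }
  out
}

# Search small boundary shifts for a pair of anchored TSD copies of the
# given lengths. The parse is intrinsically ambiguous near the boundaries: a
# one-base extension overshoot always leaves a truncated 4-mer of the real
# TSD anchored at the overshot boundary, and a chance flank base next to a
# real 5-mer creates a 6-mer anchor one base over. LTR-RT TSDs are
# canonically 5 bp, so the caller asks for length 5 before the others;
# within a length set the smallest total boundary displacement wins.
.refine_by_tsd <- function(s, start, end, params, max_shift = 4L,
                           lens = seq(params$tsd_min, params$tsd_max)) {
  shifts <- expand.grid(ds = -max_shift:max_shift, de = -max_shift:max_shift)
  shifts <- shifts[order(abs(shifts$ds) + abs(shifts$de), abs(shifts$ds)), ]
  n <- nchar(s)
  for (len in lens) {
    for (i in seq_len(nrow(shifts))) {
      a <- start + shifts$ds[i]
      b <- end + shifts$de[i]
      if (a - len < 1 || b + len > n || a >= b) next
      left <- substr(s, a - len, a - 1)
      if (left == substr(s, b + 1, b + len) &&
          !grepl("N", left, fixed = TRUE))
        return(list(start = a, end = b))
    }
  }
  NULL
}

# Longest exact direct repeat of length in [tsd_min, tsd_max] whose copies
# end at position a-1 and start at position b+1 (anchored at the element
# boundaries). NULL when absent.
.detect_tsd_at <- function(s, a, b, tsd_min, tsd_max) {
  n <- nchar(s)
  for (len in seq(tsd_max, tsd_min)) {
    if (a - len < 1 || b + len > n) next
    left <- substr(s, a - len, a - 1)
    right <- substr(s, b + 1, b + len)
    if (left == right && !grepl("N", left, fixed = TRUE)) {
      return(list(tsd = left, tsd5 = c(a - len, a - 1), tsd3 = c(b + 1, b + len)))
    }
  }
  NULL
}

#' Detect the target site duplication of a candidate element
#'
#' Returns the longest exact direct repeat of 4-6 bp whose copies are
#' anchored exactly at the element's boundaries (ending at the base before
#' the 5' LTR and starting at the base after the 3' LTR). TSDs arise from the
#' staggered cut at integration, so intact insertions carry them while
#' deletion-derived remnants generally do not.
#'
#' @param genome The sequence the candidate lies on (character, `DNAString`,
#'   or a named `DNAStringSet` containing `candidate$seq_id`).
#' @param candidate A one-row element data.frame (or list) with `start` and
#'   `end` (and `seq_id` when `genome` is a set).
#' @param params [detection_params()] supplying `tsd_min` / `tsd_max`.
#' @return `NULL` when no anchored repeat qualifies, else a list with `tsd`
#'   (the repeat string) and the two interval vectors `tsd5`, `tsd3`.
#' @export
detect_tsd <- function(genome, candidate, params = detection_params()) {
  if (is(genome, "DNAStringSet")) {
    s <- as.character(genome[[candidate$seq_id]])
  } else {
    s <- as.character(genome)
  }
  a <- candidate$start
  b <- candidate$end
  if (is.na(a) || is.na(b) || a < 1 || b > nchar(s) || a > b)
    stop("candidate out of genome bounds")
  .detect_tsd_at(s, a, b, params$tsd_min, params$tsd_max)
}
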