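# Removal-rate ratios, TSD rates, age distributions and gene-proximity
# statistics: the summary layer over the annotated element sets.

#' Solo:intact and truncated:intact ratios per cluster and genome-wide
#'
#' Genome-wide ratios are quotients of summed counts (never means of
#' per-cluster ratios). Clusters without intact members are reported but
#' excluded both from per-cluster ratios and from the denominator of the
#' proportion of clusters with S:I > 3 (the removal-rate indicator).
#'
#' @param clusters Cluster table with columns `cluster_id`, `member_id`,
#'   `category` (I/S/T).
#' @return A list: `per_cluster` (cluster_id, I, S, T, SI, TI, STI),
#'   `genome_totals` (one row: I, S, T, SI, TI, STI), and
#'   `prop_clusters_SI_gt3`.
#' @export
compute_dynamics_ratios <- function(clusters) {
  if (nrow(clusters) == 0) stop("need at least one cluster")
  cl <- unique(clusters$cluster_id)
  per <- do.call(rbind, lapply(cl, function(cid) {
    m <- clusters[clusters$cluster_id == cid, ]
    I <- sum(m$category == "I"); S <- sum(m$category == "S")
    T_ <- sum(m$category == "T")
    data.frame(cluster_id = cid, I = I, S = S, T = T_,
               SI = if (I > 0) S / I else NA_real_,
               TI = if (I > 0) T_ / I else NA_real_,
               STI = if (I > 0) (S + T_) / I else NA_real_,
               stringsAsFactors = FALSE)
  }))
  per <- per[order(per$cluster_id), , drop = FALSE]
  rownames(per) <- NULL
  I <- sum(per$I); S <- sum(per$S); T_ <- sum(per$T)
  if (I == 0) {
    warning("no intact elements: genome-wide ratios are undefined")
    totals <- data.frame(I = I, S = S, T = T_, SI = NA_real_, TI = NA_real_,
                         STI = NA_real_)
  } else {
    totals <- data.frame(I = I, S = S, T = T_, SI = S / I, TI = T_ / I,
                         STI = (S + T_) / I)
  }
  with_i <- per[per$I > 0, , drop = FALSE]
  prop <- if (nrow(with_i) > 0) mean(with_i$SI > 3) else NA_real_
  list(per_cluster = per, genome_totals = totals,
       prop_clusters_SI_gt3 = prop)
}

#' Histogram of insertion ages
#'
#' Half-open 1-Mya bins `[k*w, (k+1)*w)` by default; ages at or beyond
#' `max_age` are pooled in an overflow bin. Saturated elements (no finite
#' K2P distance) are excluded from `ages` and counted separately via
#' `n_saturated`, so bin counts + overflow + saturated equals the number of
#' elements submitted for dating.
#'
#' @param ages Numeric vector of ages in Mya (non-saturated elements only).
#' @param bin_width Bin width in Mya.
#' @param max_age Pooling threshold in Mya.
#' @param n_saturated Count of saturated elements.
#' @return A list: `bins` (data.frame `bin_lo`, `bin_hi`, `count`),
#'   `overflow`, `n_saturated`, `n_total`.
#' @export
age_histogram <- function(ages, bin_width = 1.0, max_age = 20,
                          n_saturated = 0L) {
  if (bin_width <= 0) stop("bin_width must be positive")
  if (any(ages < 0)) stop("ages must be >= 0")
  nb <- ceiling(max_age / bin_width)
  lo <- (seq_len(nb) - 1) * bin_width
  hi <- lo + bin_width
  idx <- floor(ages / bin_width) + 1
  counts <- tabulate(idx[ages < max_age], nbins = nb)
  list(bins = data.frame(bin_lo = lo, bin_hi = hi, count = counts),
       overflow = sum(ages >= max_age),
       n_saturated = as.integer(n_saturated),
       n_total = length(ages) + as.integer(n_saturated))
}

#' Distance from each element to its nearest gene
#'
#' The distance is the number of bp strictly between the element and the
#' nearest gene on the same sequence (0 with `overlapping = TRUE` when they
#' intersect). Ties go to the gene with the lower start coordinate. Elements
#' on sequences without genes get `NA` distance.
#'
#' @param elements Data.frame with `element_id`, `seq_id`, `start`, `end`.
#' @param genes Data.frame from [read_gff3_genes()].
#' @return A data.frame: `element_id`, `nearest_gene_id`, `distance`,
#'   `overlapping`.
#' @export
gene_proximity <- function(elements, genes) {
  rows <- lapply(seq_len(nrow(elements)), function(i) {
    e <- elements[i, ]
    g <- genes[genes$seq_id == e$seq_id, , drop = FALSE]
    if (nrow(g) == 0) {
      return(data.frame(element_id = e$element_id,
                        nearest_gene_id = NA_character_,
                        distance = NA_real_, overlapping = NA,
                        stringsAsFactors = FALSE))
    }
    ov <- e$start <= g$end & e$end >= g$start
    d <- ifelse(ov, 0, pmax(g$start - e$end, e$start - g$end) - 1)
    best <- which(d == min(d))
    best <- best[which.min(g$start[best])]
    data.frame(element_id = e$element_id, nearest_gene_id = g$gene_id[best],
               distance = d[best], overlapping = ov[best],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(element_id = character(),
                      nearest_gene_id = character(), distance = numeric(),
                      overlapping = logical(), stringsAsFactors = FALSE)
  out
}

#' Bin gene-proximity distances into a summary table
#'
#' Default bins express the observation that most non-overlapping elements
#' sit 3-5 kb from the nearest gene: overlap, 0-1, 1-3, 3-5, 5-10, >10 kb.
#'
#' @param prox Output of [gene_proximity()].
#' @param breaks_kb Interior bin edges in kb.
#' @return A data.frame with `bin` and `count`.
#' @export
summarize_gene_proximity <- function(prox, breaks_kb = c(0, 1, 3, 5, 10)) {
  p <- prox[!is.na(prox$distance), , drop = FALSE]
  n_ov <- sum(p$overlapping)
  d <- p$distance[!p$overlapping] / 1000
  edges <- c(breaks_kb, Inf)
  labs <- c(paste0(utils::head(edges, -1), "-", utils::tail(edges, -1), " kb"))
  labs[length(labs)] <- paste0(">", breaks_kb[length(breaks_kb)], " kb")
  cnt <- as.integer(table(cut(d, breaks = edges, right = FALSE,
                              labels = labs)))
  data.frame(bin = c("overlap", labs), count = c(n_ov, cnt),
             stringsAsFactors = FALSE)
}

#' Assemble the dynamics report
#'
#' Cross-checks that every id referenced in one stage exists in the others,
#' then bundles removal-rate ratios, TSD rates per category, the age
#' histogram and the gene-proximity table.
#'
#' @param candidates Full candidate table (with `tsd` column).
#' @param intact_calls Calls from [scan_candidates()] (needs `element_id`,
#'   `is_intact`).
#' @param remnants Classified homolog table from [classify_remnants()].
#' @param ages Dating table from [date_elements()].
#' @param clusters Cluster table with I/S/T categories.
#' @param prox Optional [gene_proximity()] table.
#' @param bin_width,max_age Age-histogram controls (Mya).
#' @return A list of class `dynamics_report`.
#' @export
build_report <- function(candidates, intact_calls, remnants, ages, clusters,
                         prox = NULL, bin_width = 1.0, max_age = 20) {
  intact_ids <- intact_calls$element_id[intact_calls$is_intact]
  bad <- setdiff(ages$element_id, intact_ids)
  if (length(bad) > 0)
    stop("dated element not in intact set: ", bad[1])
  known <- c(intact_ids, remnants$homolog_id)
  bad <- setdiff(clusters$member_id, known)
  if (length(bad) > 0)
    stop("cluster member with no upstream record: ", bad[1])
  ratios <- compute_dynamics_ratios(clusters)
  cand_int <- candidates[candidates$element_id %in% intact_ids, , drop = FALSE]
  st <- remnants[remnants$category %in% c("SOLO", "TRUNCATED"), , drop = FALSE]
  tsd_rates <- c(
    I = if (nrow(cand_int) > 0) mean(!is.na(cand_int$tsd)) else NA_real_,
    S = if (any(st$category == "SOLO"))
      mean(!is.na(st$tsd[st$category == "SOLO"])) else NA_real_,
    T = if (any(st$category == "TRUNCATED"))
      mean(!is.na(st$tsd[st$category == "TRUNCATED"])) else NA_real_)
  hist <- age_histogram(ages$T_mya[!ages$saturated], bin_width, max_age,
                        n_saturated = sum(ages$saturated))
  structure(list(
    per_cluster = ratios$per_cluster,
    genome_totals = ratios$genome_totals,
    prop_clusters_SI_gt3 = ratios$prop_clusters_SI_gt3,
    n_ambiguous = sum(remnants$category == "AMBIGUOUS"),
    tsd_rates = tsd_rates,
    age_histogram = hist,
    gene_proximity = prox), class = "dynamics_report")
}

#' Serialize a dynamics report to JSON
#' @param report A `dynamics_report`.
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Re-read a JSON dynamics report
#' @param path Path written by [write_report_json()].
#' @return A `dynamics_report`.
#' @export
read_report_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$tsd_rates <- unlist(x$tsd_rates)
  structure(x, class = "dynamics_report")
}
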