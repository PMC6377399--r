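# Silix-style single-linkage clustering of 5' LTR sequences.
#
# Two LTRs are connected when their best local alignment mutually covers at
# least 70% of both lengths with at least 60% identity (superfamily level;
# 80% for the family level). Families are the connected components of that
# graph, so any chain of qualifying matches merges clusters. Solo and
# truncated remnants are then attached to the cluster of their most similar
# intact 5' LTR.

#' Build the thresholded LTR similarity graph
#'
#' All-against-all local alignment of the supplied LTR sequences under the
#' package's fixed nucleotide scoring. An undirected edge is emitted iff the
#' best local alignment covers at least `min_mutual_coverage` of BOTH
#' sequence lengths and reaches `min_identity` percent identity.
#'
#' @param ltr_seqs Named character vector or `DNAStringSet` of 5' LTR
#'   sequences (names are element ids).
#' @param params [cluster_params()].
#' @return A data.frame of edges: `a`, `b`, `identity`, `coverage_a`,
#'   `coverage_b`, `score`.
#' @export
build_similarity_edges <- function(ltr_seqs, params = cluster_params()) {
  if (length(ltr_seqs) == 0) stop("need at least one sequence")
  if (!is(ltr_seqs, "DNAStringSet"))
    ltr_seqs <- Biostrings::DNAStringSet(ltr_seqs)
  ids <- names(ltr_seqs)
  n <- length(ltr_seqs)
  edges <- list()
  if (n >= 2) {
    for (j in 2:n) {
      pats <- ltr_seqs[1:(j - 1)]
      aln <- Biostrings::pairwiseAlignment(
        pats, ltr_seqs[[j]], type = "local",
        substitutionMatrix = .nt_submat(),
        gapOpening = .NT_GAP_OPEN, gapExtension = .NT_GAP_EXT)
      ident <- Biostrings::nmatch(aln) / Biostrings::nchar(aln) * 100
      cov_a <- IRanges::width(Biostrings::pattern(aln)) /
        Biostrings::width(pats)
      cov_b <- IRanges::width(Biostrings::subject(aln)) /
        Biostrings::width(ltr_seqs)[j]
      keep <- which(cov_a >= params$min_mutual_coverage &
                    cov_b >= params$min_mutual_coverage &
                    ident >= params$min_identity)
      if (length(keep) > 0) {
        edges[[length(edges) + 1L]] <- data.frame(
          a = ids[keep], b = ids[j], identity = ident[keep],
          coverage_a = cov_a[keep], coverage_b = cov_b[keep],
          score = Biostrings::score(aln)[keep], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(edges) == 0)
    return(data.frame(a = character(), b = character(), identity = numeric(),
                      coverage_a = numeric(), coverage_b = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, edges)
  rownames(out) <- NULL
  out
}

#' Single-linkage clusters as connected components
#'
#' Union-find over the qualifying-edge graph. The cluster id is the
#' lexicographically smallest member id; output is sorted by cluster id then
#' member id, so the result is deterministic.
#'
#' @param nodes Character vector of all ids (isolated ids become singleton
#'   clusters).
#' @param edges Edge data.frame from [build_similarity_edges()] (only `a`
#'   and `b` are used).
#' @return A data.frame: `cluster_id`, `member_id`.
#' @export
single_linkage_clusters <- function(nodes, edges) {
  nodes <- as.character(nodes)
  if (!all(c(edges$a, edges$b) %in% nodes))
    stop("edges reference ids missing from nodes")
  parent <- seq_along(nodes)
  names(parent) <- nodes
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ia <- match(edges$a, nodes)
  ib <- match(edges$b, nodes)
  for (e in seq_along(ia)) {
    ra <- find(ia[e]); rb <- find(ib[e])
    if (ra != rb) parent[rb] <- ra
  }
  root <- vapply(seq_along(nodes), find, integer(1))
  comp <- split(nodes, root)
  out <- do.call(rbind, lapply(comp, function(m) {
    m <- sort(m)
    data.frame(cluster_id = m[1], member_id = m, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$cluster_id, out$member_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach solo/truncated remnants to intact-element clusters
#'
#' Each remnant joins the cluster containing its most similar intact 5' LTR:
#' the best-scoring local alignment that also satisfies the clustering
#' thresholds (mutual coverage and identity). Ties go to higher identity,
#' then to the lexicographically lowest intact id. Remnants with no
#' qualifying alignment are reported unassigned and excluded from ratio
#' statistics.
#'
#' @param remnant_seqs Named character vector / `DNAStringSet` of remnant
#'   (homolog) sequences.
#' @param remnant_categories Named character vector mapping remnant id to
#'   `"SOLO"` or `"TRUNCATED"`.
#' @param clusters Cluster table from [single_linkage_clusters()] over the
#'   intact ids.
#' @param intact_ltrs Named character vector / `DNAStringSet` of intact 5'
#'   LTR sequences.
#' @param params [cluster_params()].
#' @return A list: `clusters` (data.frame `cluster_id`, `member_id`,
#'   `category` with I/S/T codes) and `unassigned` (character ids).
#' @export
assign_remnants_to_clusters <- function(remnant_seqs, remnant_categories,
                                        clusters, intact_ltrs,
                                        params = cluster_params()) {
  if (!is(intact_ltrs, "DNAStringSet"))
    intact_ltrs <- Biostrings::DNAStringSet(intact_ltrs)
  if (!is(remnant_seqs, "DNAStringSet") && length(remnant_seqs) > 0)
    remnant_seqs <- Biostrings::DNAStringSet(remnant_seqs)
  base <- data.frame(cluster_id = clusters$cluster_id,
                     member_id = clusters$member_id,
                     category = "I", stringsAsFactors = FALSE)
  unassigned <- character(0)
  extra <- list()
  iids <- names(intact_ltrs)
  cluster_of <- stats::setNames(clusters$cluster_id, clusters$member_id)
  for (rid in names(remnant_seqs)) {
    aln <- Biostrings::pairwiseAlignment(
      intact_ltrs, remnant_seqs[[rid]], type = "local",
      substitutionMatrix = .nt_submat(),
      gapOpening = .NT_GAP_OPEN, gapExtension = .NT_GAP_EXT)
    ident <- Biostrings::nmatch(aln) / Biostrings::nchar(aln) * 100
    cov_a <- IRanges::width(Biostrings::pattern(aln)) /
      Biostrings::width(intact_ltrs)
    cov_b <- IRanges::width(Biostrings::subject(aln)) /
      Biostrings::nchar(remnant_seqs[[rid]])
    sc <- Biostrings::score(aln)
    ok <- which(cov_a >= params$min_mutual_coverage &
                cov_b >= params$min_mutual_coverage &
                ident >= params$min_identity)
    if (length(ok) == 0) {
      unassigned <- c(unassigned, rid)
      next
    }
    ord <- ok[order(-sc[ok], -ident[ok], iids[ok])]
    best <- iids[ord[1]]
    cat <- remnant_categories[[rid]]
    extra[[length(extra) + 1L]] <- data.frame(
      cluster_id = unname(cluster_of[best]), member_id = rid,
      category = if (cat == "SOLO") "S" else "T", stringsAsFactors = FALSE)
  }
  out <- rbind(base, if (length(extra)) do.call(rbind, extra))
  out <- out[order(out$cluster_id, out$category, out$member_id), , drop = FALSE]
  rownames(out) <- NULL
  list(clusters = out, unassigned = unassigned)
}
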