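test_that("similarity edges require identity and mutual coverage", {
  s <- random_dna_str(800, seed = 41)
  seqs <- c(A = s, B = s)
  e <- build_similarity_edges(seqs)
  expect_equal(nrow(e), 1L)
  expect_equal(e$identity, 100)
  expect_equal(e$coverage_a, 1)
  expect_equal(e$coverage_b, 1)

  # a sequence vs its exact half: identity 100 but the longer sequence is
  # only half covered, so no edge
  seqs <- c(A = s, B = substr(s, 1, 400))
  e <- build_similarity_edges(seqs)
  expect_equal(nrow(e), 0L)
})

test_that("chained similarity links A-B and B-C without A-C", {
  set.seed(42)
  b <- random_dna_str(600)
  a <- mutate_k(b, 30)   # ~95% identical to B
  c0 <- mutate_k(b, 30)  # ~95% identical to B, ~90% to A
  # push A vs C below 60% while keeping both near B is not possible with
  # substitutions alone; instead plant C as B-like only in its second half
  c1 <- paste0(random_dna_str(300), substr(c0, 301, 600))
  seqs <- c(A = a, B = b, C = c1)
  e <- build_similarity_edges(seqs, cluster_params(min_identity = 90))
  pairs <- paste(e$a, e$b)
  expect_true("A B" %in% pairs)
  expect_false("A C" %in% pairs)
  # C covers only half of B, so mutual coverage also blocks B-C at 0.7
  expect_false("B C" %in% pairs)
})

test_that("single linkage equals connected components from an independent oracle", {
  skip_if_not_installed("igraph")
  set.seed(7)
  for (rep in 1:5) {
    n <- 60
    nodes <- sprintf("n%03d", seq_len(n))
    m <- matrix(runif(n * n) < 0.02, n, n)
    idx <- which(m & upper.tri(m), arr.ind = TRUE)
    edges <- data.frame(a = nodes[idx[, 1]], b = nodes[idx[, 2]],
                        stringsAsFactors = FALSE)
    got <- single_linkage_clusters(nodes, edges)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = nodes)
    comp <- igraph::components(g)$membership
    oracle <- vapply(nodes, function(x)
      min(nodes[comp == comp[[x]]]), "")
    expect_equal(stats::setNames(got$cluster_id, got$member_id),
                 oracle[got$member_id])
  }
})

test_that("cluster ids are the smallest member and singletons stay alone", {
  cl <- single_linkage_clusters(c("C", "A", "B"),
                                data.frame(a = "C", b = "B"))
  expect_equal(unique(cl$cluster_id), c("A", "B"))
  expect_equal(cl$member_id[cl$cluster_id == "B"], c("B", "C"))
  # transitivity
  cl <- single_linkage_clusters(c("A", "B", "C"),
                                data.frame(a = c("A", "B"), b = c("B", "C")))
  expect_equal(unique(cl$cluster_id), "A")
  expect_error(single_linkage_clusters(c("A"), data.frame(a = "A", b = "Z")),
               "missing")
})

test_that("raising the identity threshold refines the partition", {
  set.seed(91)
  anc1 <- random_dna_str(500)
  anc2 <- random_dna_str(500)
  seqs <- c(
    a1 = mutate_k(anc1, 10), a2 = mutate_k(anc1, 10),  # ~96% to each other
    a3 = mutate_k(anc1, 140),                          # ~72% to family 1
    b1 = mutate_k(anc2, 10), b2 = mutate_k(anc2, 10))
  e60 <- build_similarity_edges(seqs, cluster_params(min_identity = 60))
  e80 <- build_similarity_edges(seqs, cluster_params(min_identity = 80,
                                                     level_label = "family"))
  cl60 <- single_linkage_clusters(names(seqs), e60)
  cl80 <- single_linkage_clusters(names(seqs), e80)
  expect_gte(length(unique(cl80$cluster_id)),
             length(unique(cl60$cluster_id)))
  # every family-level cluster is inside one superfamily-level cluster
  sup_of <- stats::setNames(cl60$cluster_id, cl60$member_id)
  for (cid in unique(cl80$cluster_id)) {
    members <- cl80$member_id[cl80$cluster_id == cid]
    expect_equal(length(unique(sup_of[members])), 1L)
  }
  # separate ancestors never co-cluster at 60%
  expect_false(sup_of[["a1"]] == sup_of[["b1"]])
})

test_that("remnants join the cluster of their most similar intact LTR", {
  set.seed(52)
  anc1 <- random_dna_str(500)
  anc2 <- random_dna_str(500)
  intact <- c(E1 = mutate_k(anc1, 5), E2 = mutate_k(anc2, 5))
  clusters <- single_linkage_clusters(names(intact),
                                      build_similarity_edges(intact))
  remn <- c(R1 = mutate_k(anc1, 8), R2 = mutate_k(anc2, 8),
            R3 = random_dna_str(500))
  cats <- c(R1 = "SOLO", R2 = "TRUNCATED", R3 = "SOLO")
  res <- assign_remnants_to_clusters(remn, cats, clusters, intact)
  cl <- res$clusters
  expect_equal(cl$cluster_id[cl$member_id == "R1"], "E1")
  expect_equal(cl$cluster_id[cl$member_id == "R2"], "E2")
  expect_equal(cl$category[cl$member_id == "R2"], "T")
  # diverged remnant is unassigned and absent from the cluster table
  expect_equal(res$unassigned, "R3")
  expect_false("R3" %in% cl$member_id)

  # tie on score goes to the lowest intact id
  intact2 <- c(E2 = anc1, E1 = anc1)
  cl2 <- single_linkage_clusters(names(intact2),
                                 build_similarity_edges(intact2))
  res2 <- assign_remnants_to_clusters(c(R = anc1), c(R = "SOLO"),
                                      cl2, intact2)
  expect_equal(res2$clusters$cluster_id[res2$clusters$member_id == "R"], "E1")
})
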