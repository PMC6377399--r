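make_clusters <- function(spec) {
  # spec: named list cluster_id -> c(I, S, T)
  do.call(rbind, lapply(names(spec), function(cid) {
    n <- spec[[cid]]
    data.frame(cluster_id = cid,
               member_id = paste0(cid, "_", seq_len(sum(n))),
               category = rep(c("I", "S", "T"), n),
               stringsAsFactors = FALSE)
  }))
}

test_that("per-cluster and genome-wide ratios are count quotients", {
  cl <- make_clusters(list(c1 = c(2, 5, 1)))
  r <- compute_dynamics_ratios(cl)
  expect_equal(r$per_cluster$SI, 2.5)
  expect_equal(r$per_cluster$TI, 0.5)
  expect_equal(r$per_cluster$STI, 3.0)

  # genome totals are quotients of sums, not means of per-cluster ratios
  cl <- make_clusters(list(c1 = c(100, 228, 33)))
  r <- compute_dynamics_ratios(cl)
  expect_equal(r$genome_totals$SI, 2.28)
  expect_equal(r$genome_totals$STI, 2.61)
})

test_that("clusters without intact members are excluded from the S:I>3 proportion", {
  cl <- make_clusters(list(c1 = c(2, 5, 0), c2 = c(1, 4, 0),
                           c3 = c(2, 1, 0), c4 = c(0, 6, 1)))
  r <- compute_dynamics_ratios(cl)
  expect_equal(r$prop_clusters_SI_gt3, 1 / 3)
  expect_true(is.na(r$per_cluster$SI[r$per_cluster$cluster_id == "c4"]))
  # but remnant-only clusters still count in genome totals
  expect_equal(r$genome_totals$S, 16)
})

test_that("genome ratios with zero intact elements warn instead of dividing", {
  cl <- make_clusters(list(c1 = c(0, 3, 1)))
  expect_warning(r <- compute_dynamics_ratios(cl), "undefined")
  expect_true(is.na(r$genome_totals$SI))
})

test_that("ratio totals are invariant to splitting clusters", {
  cl1 <- make_clusters(list(c1 = c(4, 8, 2)))
  cl2 <- make_clusters(list(c1 = c(2, 3, 1), c2 = c(2, 5, 1)))
  r1 <- compute_dynamics_ratios(cl1)
  r2 <- compute_dynamics_ratios(cl2)
  expect_equal(r1$genome_totals, r2$genome_totals)
})

test_that("age histogram uses half-open bins with overflow pooling", {
  h <- age_histogram(c(0.2, 0.4, 1.5), bin_width = 1)
  expect_equal(h$bins$count[1:2], c(2L, 1L))
  # boundary age falls in the upper bin (half-open contract)
  h <- age_histogram(1.0, bin_width = 1)
  expect_equal(h$bins$count[1:2], c(0L, 1L))
  h <- age_histogram(c(0.5, 25), max_age = 20, n_saturated = 2)
  expect_equal(h$overflow, 1L)
  expect_equal(h$n_total, 4L)
  expect_equal(sum(h$bins$count) + h$overflow + h$n_saturated, h$n_total)
  expect_error(age_histogram(1, bin_width = 0), "positive")
})

test_that("a simulated two-component age mixture lands in the expected bins", {
  set.seed(5)
  comp <- runif(1000) < 0.7
  ages <- ifelse(comp, runif(1000, 2, 10), runif(1000, 0, 1))
  h <- age_histogram(ages)
  # the ancient component spreads its mass over [2,10); the recent
  # component concentrates in [0,1); the trough [1,2) is nearly empty
  in_ancient <- h$bins$bin_lo >= 2 & h$bins$bin_hi <= 10
  expect_equal(sum(h$bins$count[in_ancient]), sum(comp))
  expect_equal(h$bins$count[1], sum(ages < 1))
  expect_equal(h$bins$count[2], 0L)
  expect_equal(sum(h$bins$count), 1000L)
})

test_that("gene proximity reports gap distances, overlaps and tie-breaks", {
  genes <- data.frame(gene_id = c("g1", "g2"), seq_id = "chr1",
                      start = c(10001L, 15001L), end = c(12000L, 16000L),
                      strand = "+", stringsAsFactors = FALSE)
  el <- data.frame(element_id = c("e1", "e2", "e3"), seq_id = "chr1",
                   start = c(12501L, 11001L, 13001L),
                   end = c(13000L, 11500L, 14000L), stringsAsFactors = FALSE)
  p <- gene_proximity(el, genes)
  expect_equal(p$distance[1], 500)
  expect_false(p$overlapping[1])
  expect_equal(p$distance[2], 0)
  expect_true(p$overlapping[2])
  # e3 is equidistant (1000 bp) to g1 and g2: lower-coordinate gene wins
  expect_equal(p$distance[3], 1000)
  expect_equal(p$nearest_gene_id[3], "g1")

  # element on a sequence without genes
  el2 <- data.frame(element_id = "e4", seq_id = "chr9",
                    start = 1L, end = 100L, stringsAsFactors = FALSE)
  p2 <- gene_proximity(el2, genes)
  expect_true(is.na(p2$distance))
})

test_that("gene proximity summary bins express the 3-5 kb observation", {
  prox <- data.frame(element_id = paste0("e", 1:4),
                     nearest_gene_id = "g", distance = c(0, 500, 4000, 12000),
                     overlapping = c(TRUE, FALSE, FALSE, FALSE))
  s <- summarize_gene_proximity(prox)
  expect_equal(s$count[s$bin == "overlap"], 1L)
  expect_equal(s$count[s$bin == "3-5 kb"], 1L)
  expect_equal(s$count[s$bin == ">10 kb"], 1L)
  expect_equal(sum(s$count), 4L)
})

test_that("report assembly validates ids and round-trips through JSON", {
  cand <- data.frame(element_id = c("e1", "e2"), seq_id = "chr1",
                     start = c(1000L, 20000L), end = c(7000L, 26000L),
                     tsd = c("ACGTA", NA), stringsAsFactors = FALSE)
  calls <- data.frame(element_id = c("e1", "e2"),
                      is_intact = c(TRUE, TRUE), stringsAsFactors = FALSE)
  remn <- data.frame(homolog_id = c("h1", "h2"), category = c("SOLO", "TRUNCATED"),
                     tsd = c("GGCCA", NA), stringsAsFactors = FALSE)
  ages <- data.frame(element_id = c("e1", "e2"), T_mya = c(0.5, 3.2),
                     saturated = c(FALSE, FALSE), stringsAsFactors = FALSE)
  cl <- data.frame(cluster_id = "e1", member_id = c("e1", "e2", "h1", "h2"),
                   category = c("I", "I", "S", "T"), stringsAsFactors = FALSE)
  rep <- build_report(cand, calls, remn, ages, cl)
  expect_equal(rep$genome_totals$I, 2)
  expect_equal(rep$genome_totals$SI, 0.5)
  expect_equal(unname(rep$tsd_rates["I"]), 0.5)
  expect_equal(rep$age_histogram$n_total, 2L)

  p <- tempfile(fileext = ".json")
  write_report_json(rep, p)
  back <- read_report_json(p)
  expect_equal(back$genome_totals$SI, rep$genome_totals$SI)
  expect_equal(back$prop_clusters_SI_gt3, rep$prop_clusters_SI_gt3)
  expect_equal(unname(back$tsd_rates), unname(rep$tsd_rates))

  # id referenced in one stage but missing in another is an error
  bad_ages <- rbind(ages, data.frame(element_id = "ghost", T_mya = 1,
                                     saturated = FALSE))
  expect_error(build_report(cand, calls, remn, bad_ages, cl), "ghost")
})

test_that("empty remnant set gives zero ratios, not errors", {
  cand <- data.frame(element_id = "e1", seq_id = "chr1", start = 1L,
                     end = 10L, tsd = "AACGT", stringsAsFactors = FALSE)
  calls <- data.frame(element_id = "e1", is_intact = TRUE)
  remn <- data.frame(homolog_id = character(), category = character(),
                     tsd = character(), stringsAsFactors = FALSE)
  ages <- data.frame(element_id = "e1", T_mya = 1.0, saturated = FALSE)
  cl <- data.frame(cluster_id = "e1", member_id = "e1", category = "I")
  rep <- build_report(cand, calls, remn, ages, cl)
  expect_equal(rep$genome_totals$SI, 0)
  expect_equal(rep$genome_totals$TI, 0)
})
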