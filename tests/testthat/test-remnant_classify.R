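# A compact hand-built genome for homolog search and classification tests:
# one intact element plus planted remnant loci derived from its LTR.
build_remnant_genome <- function(seed = 81, solo_mut = 0, extra = list()) {
  set.seed(seed)
  lib <- synthetic_domain_library()
  ltr <- random_dna_str(500)
  prot <- lib$seqs[lib$info$clade == "Del"]
  ord <- match(c("GAG", "PR", "RT", "RH", "INT"),
               lib$info$domain[lib$info$clade == "Del"])
  coding <- paste(vapply(ord, function(i)
    ltrdyn:::.encode_protein(as.character(prot[[i]])), ""), collapse = "")
  internal <- paste0(random_dna_str(150), coding, random_dna_str(152))
  tsd <- random_dna_str(5)
  parts <- list(bg0 = random_dna_str(17000),
                intact = paste0(tsd, ltr, internal, ltr, tsd))
  for (nm in names(extra)) {
    parts[[paste0("gap_", nm)]] <- random_dna_str(17000)
    parts[[nm]] <- extra[[nm]](ltr = if (solo_mut > 0)
      mutate_k(ltr, solo_mut) else ltr, internal = internal,
      tsd = random_dna_str(5))
  }
  parts$bg_end <- random_dna_str(17000)
  g <- paste(unlist(parts), collapse = "")
  offs <- cumsum(c(1, nchar(unlist(parts))))
  starts <- stats::setNames(offs[-length(offs)], names(parts))
  genome <- Biostrings::DNAStringSet(c(chr1 = g))
  el_start <- unname(starts["intact"]) + 5L
  intact_el <- data.frame(
    element_id = "E1", seq_id = "chr1",
    start = el_start, end = el_start + 500L + nchar(internal) + 500L - 1L,
    ltr5_start = el_start, ltr5_end = el_start + 499L,
    ltr3_start = el_start + 500L + nchar(internal),
    ltr3_end = el_start + 500L + nchar(internal) + 499L,
    internal_start = el_start + 500L,
    internal_end = el_start + 499L + nchar(internal),
    stringsAsFactors = FALSE)
  list(genome = genome, intact = intact_el, starts = starts, ltr = ltr,
       internal = internal, lib = lib)
}

test_that("homolog search masks intact loci and recovers an exact solo copy", {
  gm <- build_remnant_genome(extra = list(
    solo = function(ltr, internal, tsd) ltr))
  h <- find_ltr_homologs(gm$genome, gm$intact)
  expect_equal(nrow(h), 1L)
  expect_equal(h$identity, 100)
  expect_equal(h$overlap, 1.0)
  expect_equal(h$source_element, "E1")
  expect_equal(unname(h$start), unname(gm$starts["solo"]))
  expect_equal(unname(h$end), unname(gm$starts["solo"]) + 499L)
  # the intact element's own two LTRs yield no homolog (masking)
  expect_false(any(h$start >= gm$intact$start & h$end <= gm$intact$end))
  expect_error(find_ltr_homologs(gm$genome, gm$intact[0, ]), "no intact")
})

test_that("identity and overlap thresholds gate diverged and truncated copies", {
  # 13% of positions mutated: realized identity < 90, rejected
  gm <- build_remnant_genome(seed = 82, solo_mut = 65, extra = list(
    solo = function(ltr, internal, tsd) ltr))
  h <- find_ltr_homologs(gm$genome, gm$intact)
  expect_equal(nrow(h), 0L)
  # 4% mutated: accepted, identity close to 96
  gm <- build_remnant_genome(seed = 83, solo_mut = 20, extra = list(
    solo = function(ltr, internal, tsd) ltr))
  h <- find_ltr_homologs(gm$genome, gm$intact)
  expect_equal(nrow(h), 1L)
  expect_gte(h$identity, 90)
  # copy truncated to 80% of the LTR: overlap 0.8 < 0.9, rejected
  gm <- build_remnant_genome(seed = 84, extra = list(
    part = function(ltr, internal, tsd) substr(ltr, 1, 400)))
  h <- find_ltr_homologs(gm$genome, gm$intact)
  expect_equal(nrow(h), 0L)
})

test_that("remnants are classified by flanking Gag-Pol evidence", {
  gm <- build_remnant_genome(seed = 85, extra = list(
    solo_bare = function(ltr, internal, tsd) ltr,
    solo_rec = function(ltr, internal, tsd) paste0(tsd, ltr, tsd),
    trunc5 = function(ltr, internal, tsd)
      paste0(ltr, substr(internal, 1, 2500)),
    trunc3 = function(ltr, internal, tsd)
      paste0(substr(internal, nchar(internal) - 2499, nchar(internal)), ltr)))
  h <- find_ltr_homologs(gm$genome, gm$intact)
  expect_equal(nrow(h), 4L)
  r <- classify_remnants(gm$genome, h, gm$lib)
  by_start <- r[order(r$start), ]
  expect_equal(by_start$category,
               c("SOLO", "SOLO", "TRUNCATED", "TRUNCATED"))
  # 5'-truncated: Gag-Pol downstream of the LTR; 3'-truncated: upstream
  expect_true(by_start$downstream_gagpol[3])
  expect_false(by_start$upstream_gagpol[3])
  expect_true(by_start$upstream_gagpol[4])
  expect_false(by_start$downstream_gagpol[4])
  # recombination solo keeps its TSD; bare solo and truncations do not
  expect_false(is.na(by_start$tsd[2]))
  expect_equal(nchar(by_start$tsd[2]), 5L)
  expect_true(is.na(by_start$tsd[1]))
  expect_true(all(is.na(by_start$tsd[3:4])))
  # category partition: every homolog in exactly one category
  expect_true(all(table(r$homolog_id) == 1))
  expect_setequal(r$category, c("SOLO", "TRUNCATED"))
})

test_that("classification flags honour the SOLO/TRUNCATED/AMBIGUOUS rule", {
  gm <- build_remnant_genome(seed = 86, extra = list(
    both = function(ltr, internal, tsd)
      paste0(substr(internal, nchar(internal) - 2499, nchar(internal)),
             ltr, substr(internal, 1, 2500))))
  h <- find_ltr_homologs(gm$genome, gm$intact)
  r <- classify_remnants(gm$genome, h, gm$lib)
  expect_equal(r$category, "AMBIGUOUS")
  expect_true(r$upstream_gagpol && r$downstream_gagpol)
})

test_that("overlapping hits from different sources merge to the best source", {
  # two identical intact elements (same family): the solo matches both, but
  # must be reported once, assigned to the lexicographically first source
  set.seed(87)
  gm <- build_remnant_genome(seed = 87, extra = list(
    solo = function(ltr, internal, tsd) ltr))
  second <- gm$intact
  second$element_id <- "E2"
  # pretend a second source with the same LTR coordinates (same sequence)
  both <- rbind(gm$intact, second)
  h <- find_ltr_homologs(gm$genome, both)
  expect_equal(nrow(h), 1L)
  expect_equal(h$source_element, "E1")
})
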