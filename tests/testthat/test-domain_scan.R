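# Encode a protein with the same deterministic codon table the simulator
# uses (exposed here through the internal helper).
encode_protein <- function(aa) ltrdyn:::.encode_protein(aa)

test_that("the bundled synthetic library is deterministic and complete", {
  lib <- synthetic_domain_library()
  expect_s3_class(lib, "domain_library")
  expect_equal(length(lib$seqs), 40L)
  expect_setequal(unique(lib$info$domain), c("GAG", "PR", "RT", "RH", "INT"))
  expect_setequal(unique(lib$info$superfamily), c("Gypsy", "Copia"))
  lib2 <- synthetic_domain_library()
  expect_identical(as.character(lib$seqs), as.character(lib2$seqs))
})

test_that("domain library FASTA round-trips with structured headers", {
  lib <- synthetic_domain_library()
  p <- tempfile(fileext = ".faa")
  write_domain_library(lib, p)
  back <- read_domain_library(p)
  expect_equal(as.character(back$seqs), as.character(lib$seqs))
  expect_equal(back$info, lib$info)
  expect_error(domain_library(Biostrings::AAStringSet(c("XX|Del|Gypsy" = "MA"))),
               "unknown domain")
})

test_that("an exact in-frame planted domain is found with full coverage", {
  lib <- synthetic_domain_library()
  rt <- as.character(lib$seqs[[which(lib$info$domain == "RT" &
                                     lib$info$clade == "Del")]])
  set.seed(61)
  dna <- paste0(random_dna_str(301), encode_protein(rt), random_dna_str(300))
  hits <- scan_gag_pol(dna, lib)
  expect_gte(nrow(hits), 1L)
  top <- hits[1, ]
  expect_equal(top$domain, "RT")
  expect_equal(top$clade, "Del")
  expect_equal(top$identity, 100)
  expect_equal(top$coverage, 1.0)
  expect_equal(top$frame, 2L)  # planted after 301 bases
  expect_equal(top$start, 302L)
  expect_equal(top$end, 301L + 3L * nchar(rt))
})

test_that("random DNA yields no qualifying hits at default thresholds", {
  lib <- synthetic_domain_library()
  set.seed(62)
  dna <- random_dna_str(5000)
  expect_equal(nrow(scan_gag_pol(dna, lib)), 0L)
})

test_that("the coverage threshold gates partial domains", {
  lib <- synthetic_domain_library()
  pr <- as.character(lib$seqs[[which(lib$info$domain == "PR" &
                                     lib$info$clade == "Sire")]])
  part <- substr(pr, 1, round(0.4 * nchar(pr)))
  set.seed(63)
  dna <- paste0(random_dna_str(300), encode_protein(part), random_dna_str(300))
  expect_equal(nrow(scan_gag_pol(dna, lib)), 0L)
  hits <- scan_gag_pol(dna, lib, min_coverage = 0.3)
  expect_equal(hits$domain[1], "PR")
  expect_lt(hits$coverage[1], 0.5)
})

test_that("reverse-strand domains are found with negated frames and mirrored locations", {
  lib <- synthetic_domain_library()
  rh <- as.character(lib$seqs[[which(lib$info$domain == "RH" &
                                     lib$info$clade == "Tork")]])
  set.seed(64)
  fwd <- paste0(random_dna_str(200), encode_protein(rh), random_dna_str(250))
  hf <- scan_gag_pol(fwd, lib)
  rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  hr <- scan_gag_pol(rev, lib)
  expect_equal(nrow(hf), nrow(hr))
  expect_equal(hf$frame[1], -hr$frame[1])
  n <- nchar(fwd)
  expect_equal(hr$start[1], n - hf$end[1] + 1L)
  expect_equal(hr$end[1], n - hf$start[1] + 1L)
  expect_equal(hf$score[1], hr$score[1])
})

test_that("scan input contracts are enforced", {
  lib <- synthetic_domain_library()
  expect_error(scan_gag_pol("AC", lib), "codon")
  expect_error(scan_gag_pol("ACGTACGT", list()), "domain_library")
})

test_that("intactness requires the full required domain set", {
  cand <- data.frame(element_id = "e1", internal_start = 1000L,
                     internal_end = 6000L, stringsAsFactors = FALSE)
  mk_hits <- function(domains) {
    data.frame(domain = domains, clade = "Del", superfamily = "Gypsy",
               coverage = 0.9, identity = 80, score = 500, bits = 200,
               e_value = 1e-50, frame = 1L,
               start = 1100L + seq_along(domains) * 100L,
               end = 1150L + seq_along(domains) * 100L,
               stringsAsFactors = FALSE)
  }
  all5 <- call_intact(cand, mk_hits(c("GAG", "PR", "RT", "RH", "INT")))
  expect_true(all5$is_intact)
  expect_equal(all5$best_clade, "Del")
  two <- call_intact(cand, mk_hits(c("RT", "INT")))
  expect_false(two$is_intact)
  # completeness is configurable
  rt_only <- call_intact(cand, mk_hits("RT"), required_domains = "RT")
  expect_true(rt_only$is_intact)
  # clade ties break lexicographically
  h <- rbind(mk_hits("RT"), mk_hits("INT"))
  h$clade <- c("Tat", "Del")
  expect_equal(call_intact(cand, h, required_domains = "RT")$best_clade, "Del")
  # hits outside the internal region are a contract violation
  bad <- mk_hits("RT"); bad$start <- 100L; bad$end <- 400L
  expect_error(call_intact(cand, bad), "outside internal region")
})

test_that("planted internal regions are recovered as intact with the right clade", {
  sim <- small_sim(seed = 66)
  cand <- find_ltr_candidates(sim$genome)
  sc <- scan_candidates(sim$genome, cand, sim$library)
  expect_true(all(sc$calls$is_intact))
  expect_equal(unique(sc$calls$best_clade),
               unique(sim$truth$clade))
  # all five domains recovered for every intact element
  expect_true(all(sc$calls$domains_found == "GAG+INT+PR+RH+RT"))
  expect_true(all(sc$calls$strand == "+"))
})
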