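# Shared fixture builders. Everything is generated in code; no stored data.

random_dna_str <- function(n, gc = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Write a FASTA file from a named character vector; returns the path.
write_fasta_tmp <- function(seqs, path = tempfile(fileext = ".fa")) {
  con <- file(path, "w")
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    writeLines(seqs[[nm]], con)
  }
  close(con)
  path
}

# Mutate exactly k positions of a DNA string (substitutions only, distinct
# sites, never to the original base).
mutate_k <- function(s, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- strsplit(s, "")[[1]]
  pos <- sample(length(v), k)
  for (p in pos) {
    v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  }
  paste(v, collapse = "")
}

# A genome string with a planted two-LTR construct: returns list with the
# genome string and 1-based coordinates of the parts. Homopolymer guards
# around the insert make chance TSD-like anchored repeats at the element
# boundaries impossible, so boundary assertions can be exact.
plant_ltr_construct <- function(bg_len = 50000, ltr = NULL, ltr_len = 500,
                                internal_len = 5000, at = 20000,
                                ltr3 = NULL, tsd = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(ltr)) ltr <- random_dna_str(ltr_len)
  if (is.null(ltr3)) ltr3 <- ltr
  internal <- random_dna_str(internal_len)
  guard_l <- strrep("A", 12)
  guard_r <- strrep("C", 12)
  insert <- paste0(guard_l, if (!is.null(tsd)) tsd, ltr, internal, ltr3,
                   if (!is.null(tsd)) tsd, guard_r)
  bg <- random_dna_str(bg_len)
  g <- paste0(substr(bg, 1, at - 1), insert, substr(bg, at, bg_len))
  el_start <- at + 12L + if (!is.null(tsd)) nchar(tsd) else 0L
  list(genome = g,
       ltr5_start = el_start, ltr5_end = el_start + nchar(ltr) - 1L,
       ltr3_start = el_start + nchar(ltr) + internal_len,
       ltr3_end = el_start + nchar(ltr) + internal_len + nchar(ltr3) - 1L,
       start = el_start,
       end = el_start + nchar(ltr) + internal_len + nchar(ltr3) - 1L)
}

# Small simulation shared by several tests (cheap: one family, few loci).
small_sim <- function(seed = 11, ...) {
  cfg <- sim_config(genome_len = 600000, n_families = 1, n_intact = 3,
                    n_solo_recomb = 2, n_solo_fragment = 2, n_truncated = 2,
                    age_model = list(weights = 1, ranges = list(c(0.1, 1.9))),
                    seed = seed, ...)
  simulate_genome(cfg)
}
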