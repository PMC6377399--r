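# Genome and annotation I/O. One coordinate convention everywhere: 1-based,
# closed intervals on the forward strand (the IRanges/GFF3 convention), so
# coordinates written to GFF3 are the internal coordinates unchanged.

#' Read a genome FASTA with residue normalization
#'
#' Residues are uppercased, `U` is mapped to `T`, and every other IUPAC
#' ambiguity code is collapsed to `N` so that downstream divergence counts
#' only ever see A, C, G, T or N.
#'
#' @param path Path to a (multi-)FASTA file.
#' @return A named [Biostrings::DNAStringSet]; names are the first
#'   whitespace-delimited token of each header.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0) stop("FASTA file is empty: ", path)
  ids <- sub("\\s.*$", "", names(x))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("duplicate sequence id in FASTA: ", dup[1])
  res <- toupper(as.character(x))
  res <- chartr("U", "T", res)
  res <- gsub("[^ACGT]", "N", res)
  out <- Biostrings::DNAStringSet(res)
  names(out) <- ids
  out
}

#' Write sequences as FASTA
#'
#' @param seqs A named [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output path.
#' @export
write_genome_fasta <- function(seqs, path) {
  if (!is(seqs, "XStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Extract gene annotations from a GFF3 file
#'
#' Only features of type `gene` are kept. Coordinates are GFF3 1-based
#' closed, which is also the package's internal convention.
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with columns `gene_id`, `seq_id`, `start`, `end`,
#'   `strand`.
#' @export
read_gff3_genes <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  out <- list()
  n_auto <- 0L
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9)
      stop("malformed GFF3 record (", length(f), " columns) at line ", i)
    if (f[3] != "gene") next
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end))
      stop("non-numeric coordinates in GFF3 at line ", i)
    if (end < start)
      stop("end < start in GFF3 record at line ", i)
    id <- .gff3_attr(f[9], "ID")
    if (is.na(id)) {
      n_auto <- n_auto + 1L
      id <- sprintf("gene_%04d", n_auto)
    }
    out[[length(out) + 1L]] <- data.frame(
      gene_id = id, seq_id = f[1], start = start, end = end,
      strand = if (f[7] %in% c("+", "-")) f[7] else ".",
      stringsAsFactors = FALSE)
  }
  genes <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(), seq_id = character(),
               start = integer(), end = integer(), strand = character(),
               stringsAsFactors = FALSE)
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0) stop("duplicate gene_id in GFF3: ", dup[1])
  genes
}

.gff3_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0("(?:^|;)\\s*", key, "=([^;]+)"),
                                 attrs))[[1]]
  if (length(m) < 2) NA_character_ else m[2]
}

#' Write annotated LTR-RT elements as GFF3
#'
#' Emits Sequence Ontology feature types: one `LTR_retrotransposon` row per
#' element, two `long_terminal_repeat` child rows, and
#' `target_site_duplication` rows when a TSD was detected. Rows are ordered
#' by `seq_id`, then element start, regardless of input order.
#'
#' @param elements Element table as produced by [find_ltr_candidates()]
#'   (columns `element_id`, `seq_id`, `start`, `end`, `ltr5_start`,
#'   `ltr5_end`, `ltr3_start`, `ltr3_end`, `ltr_identity`, `strand`, `tsd`,
#'   TSD interval columns; optional `category` and `age_mya`).
#' @param path Output path.
#' @export
write_element_gff3 <- function(elements, path) {
  el <- elements[order(elements$seq_id, elements$start), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  fmt <- function(seq_id, type, start, end, attrs)
    paste(seq_id, "ltrdyn", type, start, end, ".",
          ".", ".", attrs, sep = "\t")
  for (i in seq_len(nrow(el))) {
    e <- el[i, ]
    strand <- if (!is.null(e$strand) && e$strand %in% c("+", "-")) e$strand else "."
    attrs <- sprintf("ID=%s;ltr_identity=%s", e$element_id,
                     format(e$ltr_identity, digits = 6))
    if (!is.null(e$category) && !is.na(e$category))
      attrs <- paste0(attrs, ";category=", e$category)
    if (!is.null(e$age_mya) && !is.na(e$age_mya))
      attrs <- paste0(attrs, ";age_mya=", format(e$age_mya, digits = 8))
    if (!is.na(e$tsd)) attrs <- paste0(attrs, ";tsd=", e$tsd)
    ln <- paste(e$seq_id, "ltrdyn", "LTR_retrotransposon", e$start, e$end,
                ".", strand, ".", attrs, sep = "\t")
    writeLines(ln, con)
    writeLines(fmt(e$seq_id, "long_terminal_repeat", e$ltr5_start, e$ltr5_end,
                   sprintf("ID=%s_LTR5;Parent=%s", e$element_id, e$element_id)),
               con)
    writeLines(fmt(e$seq_id, "long_terminal_repeat", e$ltr3_start, e$ltr3_end,
                   sprintf("ID=%s_LTR3;Parent=%s", e$element_id, e$element_id)),
               con)
    if (!is.na(e$tsd)) {
      writeLines(fmt(e$seq_id, "target_site_duplication",
                     e$tsd5_start, e$tsd5_end,
                     sprintf("ID=%s_TSD5;Parent=%s", e$element_id, e$element_id)),
                 con)
      writeLines(fmt(e$seq_id, "target_site_duplication",
                     e$tsd3_start, e$tsd3_end,
                     sprintf("ID=%s_TSD3;Parent=%s", e$element_id, e$element_id)),
                 con)
    }
  }
  invisible(path)
}

#' Re-read an element GFF3 written by [write_element_gff3()]
#'
#' @param path Path to the GFF3 file.
#' @return An element data.frame with the same columns and coordinates that
#'   were written (round-trip identity).
#' @export
read_element_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != 9)
  if (length(bad) > 0)
    stop("malformed GFF3 record at line ", which(keep)[bad[1]])
  df <- data.frame(
    seq_id = vapply(rows, `[`, "", 1), type = vapply(rows, `[`, "", 3),
    start = as.integer(vapply(rows, `[`, "", 4)),
    end = as.integer(vapply(rows, `[`, "", 5)),
    strand = vapply(rows, `[`, "", 7),
    attrs = vapply(rows, `[`, "", 9), stringsAsFactors = FALSE)
  parents <- df[df$type == "LTR_retrotransposon", , drop = FALSE]
  out <- lapply(seq_len(nrow(parents)), function(i) {
    p <- parents[i, ]
    id <- .gff3_attr(p$attrs, "ID")
    kids <- df[grepl(paste0("Parent=", id, "$"), df$attrs), , drop = FALSE]
    ltrs <- kids[kids$type == "long_terminal_repeat", , drop = FALSE]
    ltrs <- ltrs[order(ltrs$start), , drop = FALSE]
    tsds <- kids[kids$type == "target_site_duplication", , drop = FALSE]
    tsds <- tsds[order(tsds$start), , drop = FALSE]
    age <- .gff3_attr(p$attrs, "age_mya")
    cat <- .gff3_attr(p$attrs, "category")
    data.frame(
      element_id = id, seq_id = p$seq_id, start = p$start, end = p$end,
      ltr5_start = ltrs$start[1], ltr5_end = ltrs$end[1],
      ltr3_start = ltrs$start[2], ltr3_end = ltrs$end[2],
      ltr_identity = as.numeric(.gff3_attr(p$attrs, "ltr_identity")),
      strand = p$strand,
      tsd = .gff3_attr(p$attrs, "tsd"),
      tsd5_start = if (nrow(tsds) == 2) tsds$start[1] else NA_integer_,
      tsd5_end = if (nrow(tsds) == 2) tsds$end[1] else NA_integer_,
      tsd3_start = if (nrow(tsds) == 2) tsds$start[2] else NA_integer_,
      tsd3_end = if (nrow(tsds) == 2) tsds$end[2] else NA_integer_,
      category = cat, age_mya = as.numeric(age),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[order(res$seq_id, res$start), , drop = FALSE]
}
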