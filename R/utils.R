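#' @noRd
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. All stochastic entry points route
# through this so that library users' RNG is never clobbered.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic polynomial string hash into [1, 2^31-2]; used to derive
# per-branch RNG substreams from the master seed so that adding a species
# does not perturb the draws made on unrelated branches.
#' @noRd
str_hash <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483629
  as.integer(h + 1)
}

#' @noRd
substream_seed <- function(master, key) {
  as.integer((as.numeric(master) * 7919 + str_hash(key)) %% 2147483629 + 1)
}

#' Read a protein FASTA file into a named character vector
#' @param path file path
#' @return named character vector of sequences
#' @export
read_fasta_vec <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write named protein sequences to FASTA
#' @param seqs named character vector
#' @param path output path
#' @export
write_fasta_vec <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  invisible(path)
}

# Minimal GFF3 gene-feature table used throughout: one row per gene with
# scaffold, start, end (1-based inclusive), strand, gene_id, family.
#' @noRd
empty_features <- function() {
  data.frame(scaffold = character(), start = integer(), end = integer(),
             strand = character(), gene_id = character(),
             family = character(), stringsAsFactors = FALSE)
}

#' Write a gene feature table as GFF3
#' @param features data.frame with scaffold, start, end, strand, gene_id, family
#' @param path output path
#' @export
write_gff3 <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features)) {
    attrs <- paste0("ID=", features$gene_id, ";family=", features$family)
    lines <- paste(features$scaffold, "sim", "gene", features$start,
                   features$end, ".", features$strand, ".", attrs,
                   sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a GFF3 file into a gene feature table
#' @param path GFF3 path
#' @return data.frame with scaffold, start, end, strand, gene_id, family
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return(empty_features())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 0L) != 9L
  if (any(bad)) stop("malformed GFF3 line(s) in ", path)
  m <- do.call(rbind, parts)
  attr_field <- function(a, key) {
    kv <- strsplit(strsplit(a, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    for (p in kv) if (p[1] == key) return(p[2])
    NA_character_
  }
  data.frame(
    scaffold = m[, 1],
    start = as.integer(m[, 4]), end = as.integer(m[, 5]),
    strand = m[, 7],
    gene_id = vapply(m[, 9], attr_field, "", key = "ID"),
    family = vapply(m[, 9], attr_field, "", key = "family"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' @noRd
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Path to a packaged fixture file
#' @param name file name under the package's extdata directory
#' @return absolute path
#' @export
coralfp_extdata <- function(name) {
  p <- system.file("extdata", name, package = "coralfp", mustWork = TRUE)
  p
}

# gene leaf labels are "<species>|<gene id>"; split helpers
#' @noRd
species_of <- function(labels) sub("\\|.*$", "", labels)
#' @noRd
gene_of <- function(labels) sub("^[^|]*\\|", "", labels)
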