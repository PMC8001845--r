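# Candidate FP gene identification in a proteome: local-alignment search
# against the packaged 40-query panel, position-specific domain scan,
# multi-domain splitting (_A/_B/_C suffixes), completeness filtering and
# chromophore-tripeptide extraction.

# Karlin-Altschul parameters for gapped BLOSUM62 11/1 scoring; only the
# E-value cutoff is biologically meaningful here, the parameters are the
# common gapped defaults.
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' @noRd
bit_score <- function(raw) (KA_LAMBDA * raw - log(KA_K)) / log(2)

#' Search a proteome for FP candidates against a query panel
#'
#' For each protein, computes the best Smith-Waterman score over all panel
#' queries and converts it to an E-value via the Karlin-Altschul form
#' `E = m * n * 2^(-S')` with `S'` the bit score, `m` the query length and
#' `n` the subject length. Records containing characters outside the
#' amino-acid alphabet (plus X) are rejected with a warning.
#'
#' @param proteome named character vector of protein sequences (may be empty)
#' @param panel a query panel as returned by [load_query_panel()] (needs
#'   columns `accession` and `sequence`)
#' @param e_threshold E-value cutoff (default 1e-5)
#' @return data.frame with protein_id, evalue, best_query, score for
#'   proteins at or below the threshold
#' @export
search_candidates <- function(proteome, panel, e_threshold = 1e-5) {
  out <- data.frame(protein_id = character(), evalue = numeric(),
                    best_query = character(), score = numeric(),
                    stringsAsFactors = FALSE)
  if (!length(proteome)) return(out)
  ok <- grepl(paste0("^[", paste(c(AA20, "X"), collapse = ""), "]+$"),
              proteome)
  if (any(!ok)) {
    warning("rejecting ", sum(!ok), " record(s) with non-amino-acid ",
            "characters: ", paste(head(names(proteome)[!ok], 5),
                                  collapse = ", "))
    proteome <- proteome[ok]
  }
  sm <- blosum62()
  for (i in seq_along(proteome)) {
    subj <- proteome[[i]]
    best_e <- Inf; best_q <- NA_character_; best_s <- -Inf
    for (j in seq_len(nrow(panel))) {
      q <- panel$sequence[j]
      s <- .sw_score(q, subj, sm, 11, 1)
      e <- nchar(q) * nchar(subj) * 2^(-bit_score(s))
      if (e < best_e) { best_e <- e; best_q <- panel$accession[j]; best_s <- s }
    }
    if (best_e <= e_threshold)
      out <- rbind(out, data.frame(protein_id = names(proteome)[i],
                                   evalue = best_e, best_query = best_q,
                                   score = best_s, stringsAsFactors = FALSE))
  }
  out
}

#' Build a position-specific score model from a reference alignment
#'
#' Column scores are the mean, over non-gap rows, of the BLOSUM62 row of
#' the observed residue: a single-sequence alignment therefore reproduces
#' the substitution-matrix rows, and the consensus (column argmax) scores
#' at least as high as any reference row in every column. All-gap columns
#' are dropped.
#'
#' @param msa named character vector of equal-length gapped sequences, or
#'   a character matrix (rows = sequences)
#' @param chromophore_cols optional chromophore column indices (in input
#'   column coordinates) carried through column dropping
#' @return object of class `fp_profile`: score matrix (columns x residues),
#'   consensus string, max/min attainable scores, chromophore columns
#' @export
build_profile <- function(msa, chromophore_cols = NULL) {
  m <- if (is.matrix(msa)) msa else
    do.call(rbind, strsplit(unname(msa), ""))
  if (nrow(m) < 1) stop("empty alignment")
  sm <- blosum62()[c(AA20, "X"), AA20]
  keep <- colSums(m != "-") > 0
  m <- m[, keep, drop = FALSE]
  if (!is.null(chromophore_cols))
    chromophore_cols <- cumsum(keep)[chromophore_cols][keep[chromophore_cols]]
  L <- ncol(m)
  scores <- matrix(0, L, length(AA20), dimnames = list(NULL, AA20))
  for (j in seq_len(L)) {
    res <- m[, j]
    res <- res[res != "-"]
    res[!res %in% rownames(sm)] <- "X"
    scores[j, ] <- colMeans(sm[res, , drop = FALSE])
  }
  cons <- AA20[max.col(scores, ties.method = "first")]
  obj <- list(scores = scores, length = L,
              consensus = paste(cons, collapse = ""),
              max_score = sum(apply(scores, 1, max)),
              chromophore_cols = chromophore_cols)
  class(obj) <- "fp_profile"
  obj
}

#' Scan a protein for FP domain hits
#'
#' Slides the profile along the protein ungapped and reports windows whose
#' score exceeds `threshold_frac` of the profile's maximum attainable
#' score, greedily resolved to non-overlapping hits by descending score
#' (ties by leftmost start). Proteins shorter than the profile yield at
#' most one partial hit (flagged), scored against the best-covered profile
#' segment with a proportionally scaled threshold.
#'
#' @param protein protein sequence (string)
#' @param profile an `fp_profile`
#' @param threshold_frac fraction of the maximum attainable profile score
#'   required for a hit (default 0.25; calibrated so shuffled sequences
#'   essentially never hit)
#' @return data.frame of hits: start, end (1-based inclusive), score,
#'   partial flag
#' @export
scan_domains <- function(protein, profile, threshold_frac = 0.25) {
  s <- strsplit(protein, "")[[1]]
  s[!s %in% AA20] <- NA
  n <- length(s)
  L <- profile$length
  hits <- data.frame(start = integer(), end = integer(), score = numeric(),
                     partial = logical())
  if (n >= L) {
    idx <- match(s, colnames(profile$scores))
    persite <- matrix(NA_real_, n, 1)
    # window scores via per-position profile lookups and rolling sums
    starts <- seq_len(n - L + 1L)
    win_scores <- vapply(starts, function(st) {
      cols <- idx[st:(st + L - 1L)]
      v <- profile$scores[cbind(seq_len(L), cols)]
      v[is.na(v)] <- 0
      sum(v)
    }, 0)
    thr <- threshold_frac * profile$max_score
    cand <- data.frame(start = starts, end = starts + L - 1L,
                       score = win_scores, partial = FALSE)
    cand <- cand[cand$score > thr, , drop = FALSE]
    cand <- cand[order(-cand$score, cand$start), , drop = FALSE]
    while (nrow(cand)) {
      top <- cand[1, ]
      hits <- rbind(hits, top)
      cand <- cand[cand$end < top$start | cand$start > top$end, ,
                   drop = FALSE]
    }
    hits <- hits[order(hits$start), , drop = FALSE]
  } else {
    # partial: protein shorter than profile; best ungapped offset of the
    # protein within the profile
    idx <- match(s, colnames(profile$scores))
    offs <- 0:(L - n)
    sc <- vapply(offs, function(o) {
      v <- profile$scores[cbind(o + seq_len(n), idx)]
      v[is.na(v)] <- 0
      sum(v)
    }, 0)
    best <- which.max(sc)
    covmax <- sum(apply(profile$scores[offs[best] + seq_len(n), , drop = FALSE],
                        1, max))
    if (sc[best] > threshold_frac * covmax)
      hits <- data.frame(start = 1L, end = n, score = sc[best],
                         partial = TRUE)
  }
  rownames(hits) <- NULL
  hits
}

#' Split a multi-domain candidate into one candidate per domain
#'
#' Long predicted proteins carrying several FP domains (in-silico gene
#' fusion artifacts) are cut at the midpoints between adjacent domain
#' hits; pieces get `_A`, `_B`, `_C` ... suffixes in coordinate order
#' (more than three domains triggers a warning, continuing `_D` ...).
#'
#' @param id gene/protein identifier
#' @param protein protein sequence
#' @param hits domain-hit table from [scan_domains()]
#' @return data.frame with id (suffixed iff split), sequence, piece
#'   boundaries in parent coordinates
#' @export
split_multidomain <- function(id, protein, hits) {
  stopifnot(nrow(hits) >= 1)
  hits <- hits[order(hits$start), , drop = FALSE]
  n <- nchar(protein)
  if (nrow(hits) == 1L)
    return(data.frame(id = id, sequence = protein, from = 1L, to = n,
                      stringsAsFactors = FALSE))
  if (nrow(hits) > 3L)
    warning("more than 3 domains in ", id, "; continuing suffixes past _C")
  cuts <- floor((head(hits$end, -1) + tail(hits$start, -1)) / 2)
  from <- c(1L, cuts + 1L)
  to <- c(cuts, n)
  data.frame(id = paste0(id, "_", LETTERS[seq_len(nrow(hits))]),
             sequence = substring(protein, from, to),
             from = from, to = to, stringsAsFactors = FALSE)
}

# Global alignment of a candidate to the reference consensus; shared by
# the completeness filter and chromophore extraction.
#' @noRd
align_to_reference <- function(sequence, profile) {
  nw_align(sequence, profile$consensus)
}

#' Filter candidates to complete sequences
#'
#' A candidate is complete iff its global alignment to the reference
#' consensus covers at least `coverage_min` of the reference columns and
#' contains no internal candidate-side gap run longer than `max_gap_run`
#' (the operational surrogate for "incomplete sequences with large gaps").
#'
#' @param candidates data.frame with columns id, sequence
#' @param profile an `fp_profile`
#' @param coverage_min minimum fraction of reference columns aligned to a
#'   residue (default 0.8)
#' @param max_gap_run longest tolerated internal gap run, in reference
#'   columns (default 30)
#' @return list with `complete` and `removed` data.frames (input columns
#'   plus coverage and max internal gap run); complete and removed
#'   partition the input
#' @export
filter_complete <- function(candidates, profile, coverage_min = 0.8,
                            max_gap_run = 30L) {
  cov <- numeric(nrow(candidates)); gapmax <- integer(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    al <- align_to_reference(candidates$sequence[i], profile)
    a <- strsplit(al$a, "")[[1]]   # candidate
    b <- strsplit(al$b, "")[[1]]   # consensus
    refcols <- b != "-"
    aligned <- refcols & a != "-"
    cov[i] <- sum(aligned) / sum(refcols)
    # internal gap runs on the candidate side, measured between the
    # first and last aligned reference column
    inside <- which(aligned)
    g <- 0L
    if (length(inside) >= 2) {
      span <- seq(min(inside), max(inside))
      r <- rle(a[span] == "-")
      if (any(r$values)) g <- max(r$lengths[r$values])
    }
    gapmax[i] <- g
  }
  res <- cbind(candidates, coverage = cov, max_internal_gap = gapmax)
  ok <- cov >= coverage_min & gapmax <= max_gap_run
  list(complete = res[ok, , drop = FALSE],
       removed = res[!ok, , drop = FALSE])
}

#' Extract the chromophore tripeptide of a candidate
#'
#' Reads the residues aligned to the reference chromophore columns.
#' Returns the tripeptide and a flag: `canonical` for X-Y-G, `divergent`
#' for X-F-G, `other` otherwise; gapped chromophore columns yield an
#' undefined tripeptide flagged `incomplete-at-chromophore`.
#'
#' @param sequence candidate protein sequence
#' @param profile an `fp_profile` with `chromophore_cols` set
#' @return list(tripeptide, flag)
#' @export
extract_chromophore <- function(sequence, profile) {
  if (is.null(profile$chromophore_cols) ||
      length(profile$chromophore_cols) != 3)
    stop("profile carries no chromophore column annotation")
  al <- align_to_reference(sequence, profile)
  a <- strsplit(al$a, "")[[1]]
  b <- strsplit(al$b, "")[[1]]
  refpos <- cumsum(b != "-")
  tri <- vapply(profile$chromophore_cols, function(cc) {
    k <- which(refpos == cc & b != "-")[1]
    if (is.na(k)) "-" else a[k]
  }, "")
  if (any(tri == "-"))
    return(list(tripeptide = NA_character_,
                flag = "incomplete-at-chromophore"))
  flag <- if (tri[2] == "Y" && tri[3] == "G") "canonical"
  else if (tri[2] == "F" && tri[3] == "G") "divergent"
  else "other"
  list(tripeptide = paste(tri, collapse = ""), flag = flag)
}

#' Scan one species' proteome into an FP candidate table
#'
#' Orchestrates [search_candidates()], [scan_domains()],
#' [split_multidomain()], [filter_complete()] and
#' [extract_chromophore()] over a proteome and (optionally) its gene
#' coordinates.
#'
#' @param proteome named character vector (names may be `species|gene_id`)
#' @param panel query panel with sequences
#' @param profile an `fp_profile`
#' @param features optional gene coordinate table (gene_id keyed)
#' @param species species label for the output table
#' @param e_threshold,coverage_min,max_gap_run,threshold_frac thresholds
#' @return data.frame of FP candidates: gene_id, species, scaffold,
#'   start, end, strand, evalue, best_query, n_domains, chromophore,
#'   chromophore_flag, coverage, complete, sequence
#' @export
scan_proteome <- function(proteome, panel, profile, features = NULL,
                          species = NA_character_, e_threshold = 1e-5,
                          coverage_min = 0.8, max_gap_run = 30L,
                          threshold_frac = 0.25) {
  hits <- search_candidates(proteome, panel, e_threshold)
  cand <- data.frame(id = character(), sequence = character(),
                     parent = character(), evalue = numeric(),
                     best_query = character(), n_domains = integer(),
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(hits))) {
    pid <- hits$protein_id[i]
    gid <- gene_of(pid)
    seqi <- proteome[[pid]]
    dh <- scan_domains(seqi, profile, threshold_frac)
    if (!nrow(dh)) {
      # similarity hit without a resolvable domain window: keep whole
      dh <- data.frame(start = 1L, end = nchar(seqi), score = NA_real_,
                       partial = TRUE)
    }
    pieces <- split_multidomain(gid, seqi, dh)
    cand <- rbind(cand, data.frame(
      id = pieces$id, sequence = pieces$sequence, parent = gid,
      evalue = hits$evalue[i], best_query = hits$best_query[i],
      n_domains = nrow(dh), stringsAsFactors = FALSE))
  }
  if (!nrow(cand)) {
    return(data.frame(gene_id = character(), species = character(),
                      scaffold = character(), start = integer(),
                      end = integer(), strand = character(),
                      evalue = numeric(), best_query = character(),
                      n_domains = integer(), chromophore = character(),
                      chromophore_flag = character(), coverage = numeric(),
                      complete = logical(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  fc <- filter_complete(cand, profile, coverage_min, max_gap_run)
  a <- fc$complete; a$complete <- rep(TRUE, nrow(a))
  b <- fc$removed;  b$complete <- rep(FALSE, nrow(b))
  all <- rbind(a, b)
  chrom <- lapply(all$sequence, extract_chromophore, profile = profile)
  all$chromophore <- vapply(chrom, function(x)
    if (is.na(x$tripeptide)) "undefined" else x$tripeptide, "")
  all$chromophore_flag <- vapply(chrom, `[[`, "", "flag")
  coords <- data.frame(scaffold = NA_character_, start = NA_integer_,
                       end = NA_integer_, strand = NA_character_)
  out <- data.frame(gene_id = all$id, species = species,
                    coords[rep(1, nrow(all)), , drop = FALSE],
                    evalue = all$evalue, best_query = all$best_query,
                    n_domains = all$n_domains,
                    chromophore = all$chromophore,
                    chromophore_flag = all$chromophore_flag,
                    coverage = all$coverage, complete = all$complete,
                    sequence = all$sequence,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(features)) {
    i <- match(all$parent, features$gene_id)
    out$scaffold <- features$scaffold[i]
    out$start <- features$start[i]
    out$end <- features$end[i]
    out$strand <- features$strand[i]
  }
  out
}
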