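# Candidate identification: similarity search (with exhaustive oracle),
# profile construction and domain scan, multi-domain splitting,
# completeness filter, chromophore extraction.

panel_small <- function() {
  p <- load_query_panel()
  p[c(1, 16, 28), ]   # one query per color class
}

test_that("search_candidates: empty proteome, threshold default, planted fixture", {
  panel <- panel_small()
  expect_equal(nrow(search_candidates(character(), panel)), 0)
  q <- panel$sequence[1]
  homs <- setNames(
    c(mutate_frac(q, 0.2, 1), mutate_frac(q, 0.3, 2), mutate_frac(q, 0.4, 3)),
    paste0("hom", 1:3))
  decs <- setNames(vapply(1:5, function(k) shuffle_prot(q, 100 + k), ""),
                   paste0("dec", 1:5))
  prote <- c(homs, decs)
  hits <- search_candidates(prote, panel, e_threshold = 1e-5)
  expect_setequal(hits$protein_id, names(homs))
  # oracle: identical scoring via Biostrings over all 8 proteins and all
  # panel queries, same Karlin-Altschul transform
  suppressMessages(library(Biostrings))
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  for (pid in names(prote)) {
    evals <- vapply(seq_len(nrow(panel)), function(j) {
      s <- score(pairwiseAlignment(
        AAString(panel$sequence[j]), AAString(prote[[pid]]), type = "local",
        substitutionMatrix = e$BLOSUM62, gapOpening = 11, gapExtension = 1))
      bits <- (0.267 * s - log(0.041)) / log(2)
      nchar(panel$sequence[j]) * nchar(prote[[pid]]) * 2^(-bits)
    }, 0)
    oracle_hit <- min(evals) <= 1e-5
    expect_identical(pid %in% hits$protein_id, oracle_hit, info = pid)
    if (oracle_hit)
      expect_equal(hits$evalue[hits$protein_id == pid], min(evals),
                   tolerance = 1e-8)
  }
})

test_that("search_candidates rejects records with non-amino-acid characters", {
  panel <- panel_small()
  prote <- c(good = panel$sequence[1], bad = "MKV*LY!!")
  expect_warning(hits <- search_candidates(prote, panel), "non-amino-acid")
  expect_false("bad" %in% hits$protein_id)
})

test_that("build_profile contracts: single row, consensus dominance, length", {
  ref <- load_reference_alignment()
  prof <- build_profile(ref$seqs, chromophore_cols = ref$chromophore_cols)
  expect_equal(prof$length, nchar(ref$seqs[[1]]))
  # single-sequence profile equals substitution-matrix rows
  s1 <- substr(ref$seqs[[1]], 1, 40)
  p1 <- build_profile(setNames(s1, "only"))
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  AA <- colnames(p1$scores)
  for (j in c(1, 10, 40))
    expect_equal(unname(p1$scores[j, ]),
                 unname(e$BLOSUM62[substr(s1, j, j), AA]))
  # consensus scores >= any reference row in every column
  m <- do.call(rbind, strsplit(unname(ref$seqs), ""))
  cons <- strsplit(prof$consensus, "")[[1]]
  for (j in seq_len(prof$length)) {
    cons_score <- prof$scores[j, cons[j]]
    for (i in seq_len(nrow(m)))
      if (m[i, j] %in% colnames(prof$scores))
        expect_gte(cons_score, prof$scores[j, m[i, j]])
  }
  # all-gap columns are dropped
  gappy <- c(a = "AC-G", b = "AC-G")
  expect_equal(build_profile(gappy)$length, 3)
})

test_that("scan_domains: self-hit, tandem construction, empirical null", {
  prof <- default_profile()
  hits <- scan_domains(prof$consensus, prof)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 1)
  expect_equal(hits$end, prof$length)
  expect_equal(hits$score, prof$max_score)
  # two consensus copies with a linker give two non-overlapping hits
  double <- paste0(prof$consensus, strrep("G", 10), prof$consensus)
  h2 <- scan_domains(double, prof)
  expect_equal(nrow(h2), 2)
  expect_lt(h2$end[1], h2$start[2])
  # shuffled consensus essentially never hits (empirical null; scaled
  # from the 1000-trial calibration to keep the suite fast)
  nulls <- vapply(1:200, function(k)
    nrow(scan_domains(shuffle_prot(prof$consensus, k), prof)), 0L)
  expect_lte(mean(nulls > 0), 0.01)
  # shorter-than-profile protein yields at most a flagged partial hit
  part <- scan_domains(substr(prof$consensus, 40, 160), prof)
  expect_lte(nrow(part), 1)
  if (nrow(part)) expect_true(part$partial)
})

test_that("split_multidomain cuts at midpoints and suffixes in order", {
  prof <- default_profile()
  one <- split_multidomain("g1", prof$consensus,
                           data.frame(start = 1, end = 230, score = 1,
                                      partial = FALSE))
  expect_identical(one$id, "g1")
  double <- paste0(prof$consensus, strrep("G", 10), prof$consensus)
  h2 <- scan_domains(double, prof)
  sp2 <- split_multidomain("g2", double, h2)
  expect_identical(sp2$id, c("g2_A", "g2_B"))
  # partition property: pieces reassemble the parent exactly
  expect_identical(paste0(sp2$sequence, collapse = ""), double)
  # three equally spaced domains on a long protein
  triple <- paste0(prof$consensus, strrep("A", 5), prof$consensus,
                   strrep("A", 5), prof$consensus)
  h3 <- scan_domains(triple, prof)
  expect_equal(nrow(h3), 3)
  sp3 <- split_multidomain("g3", triple, h3)
  expect_identical(sp3$id, c("g3_A", "g3_B", "g3_C"))
  expect_identical(paste0(sp3$sequence, collapse = ""), triple)
  cuts <- floor((h3$end[-3] + h3$start[-1]) / 2)
  expect_equal(sp3$to[1:2], cuts)
  # every split product re-scans to exactly one domain
  for (s in sp3$sequence)
    expect_equal(nrow(scan_domains(s, prof)), 1)
  # > 3 domains warns
  quad <- paste0(paste(rep(prof$consensus, 4), collapse = strrep("A", 5)))
  h4 <- scan_domains(quad, prof)
  expect_warning(sp4 <- split_multidomain("g4", quad, h4), "_C")
  expect_identical(sp4$id[4], "g4_D")
})

test_that("filter_complete partitions by coverage and is idempotent", {
  prof <- default_profile()
  full <- load_reference_alignment()$seqs[[1]]
  cands <- data.frame(
    id = c(paste0("ok", 1:6), paste0("trunc", 1:4)),
    sequence = c(vapply(1:6, function(k) mutate_frac(full, 0.1, k), ""),
                 vapply(1:4, function(k)
                   substr(mutate_frac(full, 0.1, 10 + k), 1, 115), "")),
    stringsAsFactors = FALSE)
  fc <- filter_complete(cands, prof, coverage_min = 0.8, max_gap_run = 30)
  expect_equal(nrow(fc$complete), 6)
  expect_equal(nrow(fc$removed), 4)
  expect_setequal(c(fc$complete$id, fc$removed$id), cands$id)
  # idempotent on the complete set
  fc2 <- filter_complete(fc$complete[, c("id", "sequence")], prof,
                         coverage_min = 0.8, max_gap_run = 30)
  expect_equal(nrow(fc2$removed), 0)
  # internal deletion beyond max_gap_run removes a candidate
  gapped <- paste0(substr(full, 1, 80), substr(full, 121, 230))
  fg <- filter_complete(data.frame(id = "del", sequence = gapped),
                        prof, coverage_min = 0.5, max_gap_run = 30)
  expect_equal(nrow(fg$removed), 1)
  expect_gte(fg$removed$max_internal_gap, 40 - 5)
})

test_that("extract_chromophore reads the aligned tripeptide and flags", {
  prof <- default_profile()
  arch <- fp_archetypes()
  g <- extract_chromophore(arch[["GFP/CFP"]], prof)
  expect_identical(g$tripeptide, "QYG")
  expect_identical(g$flag, "canonical")
  r <- extract_chromophore(arch[["RFP"]], prof)
  expect_identical(r$tripeptide, "DYG")
  expect_identical(r$flag, "canonical")
  # Y -> F at the middle column flags divergent
  v <- strsplit(arch[["GFP/CFP"]], "")[[1]]; v[64] <- "F"
  d <- extract_chromophore(paste(v, collapse = ""), prof)
  expect_identical(d$tripeptide, "QFG")
  expect_identical(d$flag, "divergent")
  # truncation across the chromophore -> undefined
  u <- extract_chromophore(substr(arch[["GFP/CFP"]], 100, 230), prof)
  expect_identical(u$flag, "incomplete-at-chromophore")
})

test_that("simulated decoys never pass the scan, planted genes always do", {
  tr <- five_taxon_tree()
  panel <- load_query_panel()
  prof <- default_profile()
  for (sd in 1:3) {
    cfg <- sim_config(tr, seed = sd, root_copies = 2, dup_rate = 0.2,
                      loss_rate = 0, subst_rate = 0.15,
                      decoy_genes_per_species = 6)
    so <- simulate_family(cfg)
    for (sp in c("A", "D")) {
      tab <- scan_proteome(so$proteomes[[sp]], panel, prof,
                           features = so$features[[sp]], species = sp)
      expect_false(any(grepl("DEC", tab$gene_id)))
      fp_true <- sum(so$truth$classes[grepl(paste0("^", sp, "_"),
                                            names(so$truth$classes))] != "")
      expect_equal(nrow(tab), fp_true)
      expect_true(all(tab$complete))
    }
  }
})
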