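# Fixture loaders (query panel, per-species counts, species tree, stem
# event ledger), summary tables, and pipeline orchestration.

#' Load the packaged 40-entry query panel
#'
#' Panel metadata (accession, description, source species, reported
#' emission color) transcribed from the published query table; the
#' sequences are synthetic stand-ins derived from the class archetypes
#' (real GenBank records are not shipped), stored in
#' `table1_panel_sequences_synthetic.fasta`.
#'
#' @param with_sequences attach the synthetic sequences (default TRUE)
#' @return data.frame: accession, description, species, color, acroporid
#'   flag, and (optionally) sequence
#' @export
load_query_panel <- function(with_sequences = TRUE) {
  panel <- read_tsv(coralfp_extdata("table1_query_panel.tsv"))
  if (anyDuplicated(panel$accession)) stop("panel accessions not unique")
  panel$acroporid <- grepl("^Acropora", panel$species)
  if (with_sequences) {
    seqs <- read_fasta_vec(
      coralfp_extdata("table1_panel_sequences_synthetic.fasta"))
    panel$sequence <- unname(seqs[panel$accession])
    if (anyNA(panel$sequence)) stop("panel sequence missing")
  }
  panel
}

#' Load the packaged synthetic reference alignment
#'
#' Nine gap-free synthetic FP sequences (three per color class) used to
#' build the domain profile; chromophore columns are 63-65.
#'
#' @return list(seqs = named gapped sequences, chromophore_cols)
#' @export
load_reference_alignment <- function() {
  seqs <- read_fasta_vec(
    coralfp_extdata("fp_reference_alignment_synthetic.fasta"))
  list(seqs = seqs, chromophore_cols = CHROMOPHORE_COLS)
}

#' Default FP domain profile from the packaged reference alignment
#' @return an `fp_profile`
#' @export
default_profile <- function() {
  ref <- load_reference_alignment()
  build_profile(ref$seqs, chromophore_cols = ref$chromophore_cols)
}

#' Load the packaged acroporid species tree
#'
#' Nineteen taxa (15 Acropora in clades I-IV, two Montipora, Astreopora,
#' plus the pocilloporid outgroup), rooted, with labeled internal nodes
#' and approximate relative ages. Within-clade branching orders are
#' partly conjectural (the source figure is graphical); see the methods
#' vignette.
#'
#' @param drop_outgroup drop the non-acroporid outgroup tip
#' @return rooted `phylo`
#' @export
load_species_tree <- function(drop_outgroup = FALSE) {
  tr <- ape::read.tree(coralfp_extdata("acroporid_species_tree.nwk"))
  if (drop_outgroup)
    tr <- ape::drop.tip(tr, "Stylophora_pistillata")
  ensure_node_labels(tr)
}

#' Load the packaged species -> clade table
#' @return data.frame species, clade
#' @export
load_species_clades <- function() read_tsv(coralfp_extdata("species_clades.tsv"))

#' Load the packaged per-species complete FP gene counts
#' @return data.frame species, clade, `GFP/CFP`, RFP, ChrP, fp_total
#' @export
load_counts_fixture <- function() {
  read_tsv(coralfp_extdata("table2_counts.tsv"))
}

#' Load the packaged stem-branch event ledger
#'
#' The published reconstruction reduced to machine form: the Acroporidae
#' ancestor carried five FP genes; eleven duplications on the branch
#' following the Montipora divergence yield the 16-gene Acropora
#' ancestral complement (9 GFP/CFP + 3 RFP + 4 ChrP). The per-class
#' decomposition of the root complement is a declared surrogate (the
#' source states only the total of five).
#'
#' @return data.frame node, class, dups, losses, copies
#' @export
load_stem_ledger <- function() read_tsv(coralfp_extdata("stem_event_ledger.tsv"))

#' Propagate a stem ledger along a root-to-node path
#'
#' Starting from the first node's copies, applies per-class dups - losses
#' down the given node order and checks the stored copies.
#'
#' @param ledger data.frame node, class, dups, losses, copies (node order
#'   = root-to-tip path)
#' @return data.frame node x class copies (propagated), with a `total`
#'   column
#' @export
propagate_stem_ledger <- function(ledger) {
  nodes <- unique(ledger$node)
  classes <- unique(ledger$class)
  cur <- setNames(ledger$copies[ledger$node == nodes[1]][
    match(classes, ledger$class[ledger$node == nodes[1]])], classes)
  out <- data.frame(node = nodes[1], t(cur), total = sum(cur),
                    check.names = FALSE)
  for (nd in nodes[-1]) {
    sub <- ledger[ledger$node == nd, ]
    cur <- cur + setNames(sub$dups - sub$losses,
                          sub$class)[classes]
    stored <- setNames(sub$copies, sub$class)[classes]
    if (any(cur != stored))
      stop("stem ledger inconsistent at ", nd)
    out <- rbind(out, data.frame(node = nd, t(cur), total = sum(cur),
                                 check.names = FALSE))
  }
  out
}

#' Per-species color-class counts table
#'
#' One row per species with GFP/CFP, RFP, ChrP counts and the FP total;
#' clade labels come from the species metadata (missing species get clade
#' "unknown" with a warning).
#'
#' @param candidates data.frame with species and class columns (complete
#'   candidates only)
#' @param clades data.frame species, clade
#' @return data.frame species, clade, `GFP/CFP`, RFP, ChrP, fp_total
#' @export
make_counts_table <- function(candidates, clades = load_species_clades()) {
  species <- sort(unique(candidates$species))
  rows <- lapply(species, function(sp) {
    k <- candidates$class[candidates$species == sp]
    data.frame(species = sp,
               clade = NA_character_,
               `GFP/CFP` = sum(k == "GFP/CFP"),
               RFP = sum(k == "RFP"),
               ChrP = sum(k == "ChrP"),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(species = character(), clade = character(),
                      `GFP/CFP` = integer(), RFP = integer(),
                      ChrP = integer(), check.names = FALSE)
  i <- match(out$species, clades$species)
  out$clade <- clades$clade[i]
  if (anyNA(out$clade)) {
    warning("species without clade metadata: ",
            paste(out$species[is.na(out$clade)], collapse = ", "))
    out$clade[is.na(out$clade)] <- "unknown"
  }
  out$fp_total <- out$`GFP/CFP` + out$RFP + out$ChrP
  out
}

#' Ancestral complement table from per-class ledgers
#'
#' Per species node and class, the copy number, plus per-node totals;
#' errors if a class ledger is internally inconsistent (conservation of
#' parent copies + dups - losses).
#'
#' @param ledgers named list of `fp_ledger` (one per class)
#' @param species_tree the species tree the ledgers refer to
#' @return data.frame node, one column per class, total
#' @export
summarize_ancestral <- function(ledgers, species_tree) {
  idx <- species_index(species_tree)
  check_ledger_conservation(ledgers, species_tree)
  nodes <- idx$labels
  out <- data.frame(node = nodes, stringsAsFactors = FALSE)
  for (k in names(ledgers)) {
    led <- ledgers[[k]]
    out[[k]] <- if (is.null(led)) 0L else
      led$branches$copies[match(nodes, led$branches$branch)]
  }
  out$total <- rowSums(out[, names(ledgers), drop = FALSE])
  out
}

#' @noRd
check_ledger_conservation <- function(ledgers, species_tree) {
  idx <- species_index(species_tree)
  bad <- character()
  for (k in names(ledgers)) {
    led <- ledgers[[k]]
    if (is.null(led)) next
    br <- led$branches
    for (e in seq_len(nrow(idx$tree$edge))) {
      p <- idx$labels[idx$tree$edge[e, 1]]
      v <- idx$labels[idx$tree$edge[e, 2]]
      ip <- match(p, br$branch); iv <- match(v, br$branch)
      if (br$copies[iv] != br$copies[ip] + br$dups[iv] - br$losses[iv])
        bad <- c(bad, paste0(k, ":", v))
    }
  }
  if (length(bad))
    stop("inconsistent sub-ledger branch(es): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

# --- pipeline ----------------------------------------------------------

#' Pipeline run configuration
#'
#' @param input_dir directory with `<species>.faa`, `<species>.gff3` and
#'   `species_tree.nwk` (as written by [write_sim_inputs()]); or NULL
#'   when `sim` is given
#' @param sim optional `sim_config`: simulate inputs in-memory
#' @param out_dir output directory
#' @param seed seed for bootstrap and polytomy resolution
#' @param e_threshold,coverage_min,max_gap_run,support_min,n_replicates,max_intervening
#'   stage thresholds (defaults: published values where printed, declared
#'   surrogates elsewhere)
#' @return list of class `run_config`
#' @export
run_config <- function(input_dir = NULL, sim = NULL, out_dir = tempfile("fp_run_"),
                       seed = 1L, e_threshold = 1e-5, coverage_min = 0.8,
                       max_gap_run = 30L, support_min = 90,
                       n_replicates = 1000L, max_intervening = 10L) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Write simulated inputs to disk in the pipeline's input layout
#' @param sim_out result of [simulate_family()]
#' @param config the `sim_config` used
#' @param dir target directory
#' @return dir, invisibly
#' @export
write_sim_inputs <- function(sim_out, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(sim_out$proteomes)) {
    write_fasta_vec(sim_out$proteomes[[sp]], file.path(dir, paste0(sp, ".faa")))
    write_gff3(sim_out$features[[sp]], file.path(dir, paste0(sp, ".gff3")))
  }
  ape::write.tree(config$species_tree, file.path(dir, "species_tree.nwk"))
  write_truth(sim_out$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Run the full analysis pipeline
#'
#' Stages: scan -> classify -> reconcile -> synteny -> report, writing
#' candidate, color, ledger and cluster tables plus a run log to
#' `out_dir`. Re-running with an identical configuration reproduces
#' identical tables.
#'
#' @param cfg a `run_config`
#' @return invisible list with the in-memory stage results
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$out_dir, "run.log")
  log <- function(stage, msg)
    cat(sprintf("[%s] %s\n", stage, msg), file = logf, append = TRUE)
  cat(sprintf("# coralfp run | seed=%d | cfg=%s\n", cfg$seed,
              config_hash(cfg)), file = logf)

  # ---- inputs
  if (!is.null(cfg$sim)) {
    simo <- simulate_family(cfg$sim)
    proteomes <- simo$proteomes
    features <- simo$features
    sptree <- cfg$sim$species_tree
    truth <- simo$truth
  } else {
    if (is.null(cfg$input_dir) || !dir.exists(cfg$input_dir))
      stop("input directory not found: ", cfg$input_dir)
    faa <- list.files(cfg$input_dir, "\\.faa$", full.names = TRUE)
    proteomes <- lapply(faa, read_fasta_vec)
    names(proteomes) <- sub("\\.faa$", "", basename(faa))
    features <- lapply(names(proteomes), function(sp) {
      p <- file.path(cfg$input_dir, paste0(sp, ".gff3"))
      if (!file.exists(p)) stop("missing GFF3: ", p)
      read_gff3(p)
    })
    names(features) <- names(proteomes)
    sptree <- ensure_node_labels(
      ape::read.tree(file.path(cfg$input_dir, "species_tree.nwk")))
    truth <- NULL
  }

  panel <- load_query_panel()
  profile <- default_profile()

  # ---- scan
  log("scan", sprintf("%d species", length(proteomes)))
  cands <- list()
  for (sp in names(proteomes)) {
    cands[[sp]] <- scan_proteome(
      proteomes[[sp]], panel, profile, features = features[[sp]],
      species = sp, e_threshold = cfg$e_threshold,
      coverage_min = cfg$coverage_min, max_gap_run = cfg$max_gap_run)
  }
  cand <- do.call(rbind, c(cands, list(make.row.names = FALSE)))
  write_tsv(cand, file.path(cfg$out_dir, "candidates.tsv"))
  comp <- cand[cand$complete, , drop = FALSE]
  if (nrow(comp) < 2) stop("stage classify: fewer than 2 complete candidates")

  # ---- classify
  refs <- panel[panel$color != "unreported", ]
  seqs <- c(setNames(comp$sequence, paste0(comp$species, "|", comp$gene_id)),
            setNames(refs$sequence, refs$accession))
  msa <- align_sequences(seqs)
  bs <- bootstrap_support(msa, n_replicates = cfg$n_replicates,
                          seed = cfg$seed)
  outg <- refs$accession[!refs$acroporid]
  rooted <- root_tree(bs$tree, outg)
  colors <- assign_colors(rooted,
                          setNames(refs$color, refs$accession),
                          bs$support, cfg$support_min)
  colors$species <- species_of(colors$gene_id)
  colors$gene <- gene_of(colors$gene_id)
  i <- match(colors$gene, comp$gene_id)
  colors$chromophore <- comp$chromophore[i]
  write_tsv(colors, file.path(cfg$out_dir, "colors.tsv"))

  # ---- reconcile
  cand_tree <- ape::keep.tip(rooted, setdiff(rooted$tip.label,
                                             refs$accession))
  cand_tree <- root_candidate_tree(cand_tree, rooted, refs$accession,
                                   sptree, cfg$seed)
  rec <- lca_map(cand_tree, sptree)
  ledger <- build_ledger(rec)
  write_tsv(ledger$branches, file.path(cfg$out_dir, "ledger_total.tsv"))
  class_ledgers <- per_class_history(
    cand_tree, setNames(colors$class, colors$gene_id), sptree)
  for (k in names(class_ledgers))
    if (!is.null(class_ledgers[[k]]))
      write_tsv(class_ledgers[[k]]$branches,
                file.path(cfg$out_dir, paste0(
                  "ledger_", gsub("[^A-Za-z]", "", k), ".tsv")))

  # ---- synteny
  links <- orthology_links(rec, cross_species_only = FALSE)
  clusters <- list()
  tandem <- data.frame(species = character(), gene_a = character(),
                       gene_b = character(), mode = character(),
                       stringsAsFactors = FALSE)
  for (sp in names(features)) {
    f <- features[[sp]]
    fp <- comp$gene_id[comp$species == sp]
    cl <- detect_clusters(f, fp, cfg$max_intervening)
    clusters[[sp]] <- cl
    # within-species paralog pairs
    par <- links[links$relation == "paralog" & links$species_a == sp &
                   links$species_b == sp, , drop = FALSE]
    for (r in seq_len(nrow(par))) {
      ga <- gene_of(par$gene_a[r]); gb <- gene_of(par$gene_b[r])
      if (!ga %in% f$gene_id || !gb %in% f$gene_id) next
      tandem <- rbind(tandem, data.frame(
        species = sp, gene_a = ga, gene_b = gb,
        mode = classify_duplication(ga, gb, cl, f),
        stringsAsFactors = FALSE))
    }
  }
  write_tsv(tandem, file.path(cfg$out_dir, "duplication_modes.tsv"))
  cl_rows <- do.call(rbind, lapply(names(clusters), function(sp) {
    if (!length(clusters[[sp]])) return(NULL)
    do.call(rbind, lapply(seq_along(clusters[[sp]]), function(i) {
      cl <- clusters[[sp]][[i]]
      data.frame(species = sp, cluster = i, scaffold = cl$scaffold,
                 n_members = nrow(cl$members),
                 members = paste(cl$members$gene_id, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(cl_rows)) cl_rows <- data.frame(species = character())
  write_tsv(cl_rows, file.path(cfg$out_dir, "clusters.tsv"))

  # ---- report
  counts <- make_counts_table(
    data.frame(species = colors$species, class = colors$class),
    clades = tryCatch(load_species_clades(), error = function(e) NULL))
  write_tsv(counts, file.path(cfg$out_dir, "counts.tsv"))
  anc <- summarize_ancestral(class_ledgers, sptree)
  write_tsv(anc, file.path(cfg$out_dir, "ancestral_complements.tsv"))
  log("report", "done")
  invisible(list(candidates = cand, colors = colors, gene_tree = cand_tree,
                 reconciliation = rec, ledger = ledger,
                 class_ledgers = class_ledgers, clusters = clusters,
                 duplication_modes = tandem, counts = counts,
                 ancestral = anc, truth = truth, msa = msa,
                 support = bs$support))
}

# Root the candidate-only tree: keep the position implied by the
# outgroup-rooted full tree when the candidates form a clade there;
# otherwise choose the rooting minimizing duplications + losses (ties by
# the lexicographically smallest bipartition).
#' @noRd
root_candidate_tree <- function(cand_tree, full_tree, refs, sptree, seed) {
  cand_labels <- setdiff(full_tree$tip.label, refs)
  implied_ok <- length(cand_labels) < ape::Ntip(full_tree) &&
    tryCatch(ape::is.monophyletic(full_tree, cand_labels),
             error = function(e) FALSE)
  if (implied_ok && ape::is.rooted(cand_tree) && ape::is.binary(cand_tree))
    return(cand_tree)
  cand_tree <- resolve_polytomies(ape::unroot(cand_tree), seed)
  best <- NULL; best_score <- Inf; best_key <- NULL
  ut <- ape::unroot(cand_tree)
  for (e in seq_len(nrow(ut$edge))) {
    child <- ut$edge[e, 2]
    tips_below <- if (child <= ape::Ntip(ut)) ut$tip.label[child] else
      ut$tip.label[unlist(phangorn::Descendants(ut, child, "tips"))]
    if (length(tips_below) == 0 ||
        length(tips_below) == length(ut$tip.label)) next
    rt <- tryCatch(ape::root(ut, outgroup = tips_below,
                             resolve.root = TRUE), error = function(x) NULL)
    if (is.null(rt) || !ape::is.binary(rt)) next
    rec <- tryCatch(lca_map(rt, sptree), error = function(x) NULL)
    if (is.null(rec)) next
    sc <- sum(rec$events == "duplication", na.rm = TRUE) + nrow(rec$losses)
    key <- bipart_key(tips_below, ut$tip.label)
    if (sc < best_score || (sc == best_score && key < best_key)) {
      best <- rt; best_score <- sc; best_key <- key
    }
  }
  if (is.null(best)) stop("could not root candidate tree")
  best
}

#' @noRd
config_hash <- function(cfg) {
  x <- cfg; x$out_dir <- NULL
  s <- paste(deparse(x[order(names(x))]), collapse = "")
  sprintf("%08x", str_hash(s))
}
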