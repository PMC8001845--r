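# Birth-death simulator of FP gene-family evolution along a species tree.
#
# Each gene lineage duplicates at rate dup_rate and dies at rate loss_rate
# per unit branch length. A duplicate inserts next to its parent gene with
# probability tandem_prob (inheriting the parent strand), else at a random
# position on a random scaffold with a random strand. Sequences evolve
# under a per-site Poisson clock with uniform replacement; chromophore
# columns are protected except when a duplication fires a chromophore
# switch (QYG <-> DYG class flip, or degradation to XFG).
#
# The simulator records two ledgers: the *true* ledger (every event that
# happened) and the *observable* ledger (events recoverable from extant
# genomes: a duplication is observable iff both daughter lineages left
# surviving descendants; a loss is observable iff it removed the last
# surviving descendant of a lineage below a speciation whose other side
# survived). Pipeline-recovery tests compare against the observable
# ledger, since no inference method can see events that left no trace.

#' Simulation configuration
#'
#' @param species_tree rooted `phylo` with positive branch lengths
#' @param seed master seed; per-branch substreams are derived from it
#' @param root_copies FP gene copies in the root species
#' @param dup_rate,loss_rate events per lineage per unit branch length
#' @param tandem_prob probability a duplicate inserts adjacent to its parent
#' @param subst_rate substitutions per site per unit branch length
#' @param chromophore_switch_prob probability a duplication switches the
#'   daughter's chromophore class
#' @param xfg_prob given a switch, probability of degrading to XFG rather
#'   than flipping QYG <-> DYG
#' @param decoy_genes_per_species non-FP background genes per species
#' @param n_scaffolds scaffolds per species genome
#' @param root_stem time units of divergence between each root lineage's
#'   starting sequence and its class archetype
#' @param root_class_props proportions of GFP/CFP, RFP, ChrP among root
#'   copies (largest-remainder rounding)
#' @param branch_rate_mods optional data.frame(branch, dup_mult, loss_mult)
#'   of per-branch rate multipliers keyed by the label of the node a
#'   branch ends at
#' @param emit_sequences if FALSE, skip sequence evolution and genome
#'   placement (copy-number-only runs for statistical checks)
#' @return object of class `sim_config`
#' @export
sim_config <- function(species_tree, seed = 1L, root_copies = 5L,
                       dup_rate = 0.3, loss_rate = 0.1, tandem_prob = 0.7,
                       subst_rate = 0.1, chromophore_switch_prob = 0.05,
                       xfg_prob = 0.1, decoy_genes_per_species = 20L,
                       n_scaffolds = 5L, root_stem = 0.5,
                       root_class_props = c(`GFP/CFP` = 0.6, RFP = 0.2, ChrP = 0.2),
                       branch_rate_mods = NULL,
                       emit_sequences = TRUE) {
  stopifnot(inherits(species_tree, "phylo"))
  if (!ape::is.rooted(species_tree) || !ape::is.binary(species_tree))
    stop("species_tree must be rooted and binary")
  if (is.null(species_tree$edge.length) || any(species_tree$edge.length <= 0))
    if (dup_rate > 0 || loss_rate > 0 || subst_rate > 0)
      stop("species tree has zero/negative-length branches but rates are nonzero")
  if (dup_rate < 0 || loss_rate < 0 || subst_rate < 0)
    stop("rates must be >= 0")
  for (p in c(tandem_prob, chromophore_switch_prob, xfg_prob))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  if (root_copies < 0) stop("root_copies must be >= 0")
  cfg <- list(species_tree = ensure_node_labels(species_tree),
              seed = as.integer(seed), root_copies = as.integer(root_copies),
              dup_rate = dup_rate, loss_rate = loss_rate,
              tandem_prob = tandem_prob, subst_rate = subst_rate,
              chromophore_switch_prob = chromophore_switch_prob,
              xfg_prob = xfg_prob,
              decoy_genes_per_species = as.integer(decoy_genes_per_species),
              n_scaffolds = as.integer(n_scaffolds),
              root_stem = root_stem,
              root_class_props = root_class_props,
              branch_rate_mods = branch_rate_mods,
              emit_sequences = isTRUE(emit_sequences))
  class(cfg) <- "sim_config"
  cfg
}

# label internal nodes N<k> when unlabeled; tree containers everywhere
# are ape "phylo" objects
#' @noRd
ensure_node_labels <- function(tree) {
  n <- ape::Ntip(tree)
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label))) {
    lab <- tree$node.label
    if (is.null(lab)) lab <- rep("", tree$Nnode)
    need <- !nzchar(lab)
    lab[need] <- paste0("N", which(need))
    tree$node.label <- lab
  }
  if (anyDuplicated(c(tree$tip.label, tree$node.label)))
    stop("species tree node labels must be unique")
  tree
}

#' @noRd
node_label <- function(tree, node) {
  n <- ape::Ntip(tree)
  ifelse(node <= n, tree$tip.label[node], tree$node.label[node - n])
}

#' @noRd
branch_mults <- function(cfg, branch_label) {
  m <- c(dup = 1, loss = 1)
  brm <- cfg$branch_rate_mods
  if (!is.null(brm)) {
    i <- match(branch_label, brm$branch)
    if (!is.na(i)) m <- c(dup = brm$dup_mult[i], loss = brm$loss_mult[i])
  }
  m
}

#' Mutate a protein sequence along a branch
#'
#' Per-site Poisson clock: each non-chromophore site changes with
#' probability 1 - exp(-subst_rate * branch_length), to a uniformly
#' chosen different residue. Chromophore columns are copied unchanged
#' unless `switch = TRUE`, in which case a QYG-class chromophore flips to
#' DYG (or vice versa), or degrades to XFG with probability `xfg_prob`;
#' a switch never leaves the chromophore unchanged. Draws come from the
#' current RNG stream.
#'
#' @param parent protein sequence (string)
#' @param branch_length branch length in time units
#' @param config `sim_config`
#' @param switch whether a chromophore switch event fires
#' @return mutated sequence string
#' @export
mutate_sequence <- function(parent, branch_length, config, switch = FALSE) {
  stopifnot(nchar(parent) > 0)
  s <- strsplit(parent, "")[[1]]
  chrom_idx <- intersect(CHROMOPHORE_COLS, seq_along(s))
  p <- 1 - exp(-config$subst_rate * branch_length)
  if (p > 0) {
    idx <- setdiff(seq_along(s), chrom_idx)
    hit <- idx[runif(length(idx)) < p]
    if (length(hit))
      s[hit] <- vapply(s[hit],
                       function(a) sample(setdiff(AA20, a), 1L), "")
  }
  if (switch && length(chrom_idx) == 3L) {
    tri <- s[chrom_idx]
    if (runif(1) < config$xfg_prob) {
      s[chrom_idx[2]] <- "F"                       # XYG -> XFG degenerate
    } else if (tri[1] == "D") {
      s[chrom_idx[1]] <- "Q"                       # DYG -> QYG
    } else {
      s[chrom_idx[1]] <- "D"                       # QYG (or other) -> DYG
    }
  }
  paste(s, collapse = "")
}

#' @noRd
alloc_classes <- function(n, props) {
  if (n == 0L) return(character())
  props <- props / sum(props)
  raw <- props * n
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  rep(names(props), times = k)
}

# --- internal mutable simulation state ---------------------------------

# Genome arrangement: per scaffold an ordered character vector of gene
# ids (FP lineage ids and decoy ids) plus a named strand vector.
#' @noRd
new_arrangement <- function(cfg, lineages, rng_ok) {
  sc <- paste0("scaf", seq_len(cfg$n_scaffolds))
  arr <- setNames(vector("list", length(sc)), sc)
  for (s in sc) arr[[s]] <- character()
  strands <- character()
  ids <- character()
  if (cfg$decoy_genes_per_species > 0)
    ids <- paste0("DEC", seq_len(cfg$decoy_genes_per_species))
  ids <- c(ids, lineages)
  for (i in seq_along(ids)) {
    s <- sc[if (rng_ok) sample.int(length(sc), 1L) else (i %% length(sc)) + 1L]
    pos <- if (rng_ok) sample.int(length(arr[[s]]) + 1L, 1L) else length(arr[[s]]) + 1L
    arr[[s]] <- append(arr[[s]], ids[i], after = pos - 1L)
    strands[ids[i]] <- if (rng_ok) sample(c("+", "-"), 1L) else "+"
  }
  list(scaffolds = arr, strands = strands)
}

#' @noRd
arr_scaffold_of <- function(arr, id) {
  for (s in names(arr$scaffolds))
    if (id %in% arr$scaffolds[[s]]) return(s)
  NA_character_
}

# tandem inserts land right after the parent (inheriting its strand);
# dispersed inserts land on a uniformly chosen *other* scaffold, so the
# recorded insertion mode is positionally recoverable
#' @noRd
arr_insert <- function(arr, id, strand, after_id = NULL, avoid_id = NULL) {
  if (!is.null(after_id)) {
    for (s in names(arr$scaffolds)) {
      k <- match(after_id, arr$scaffolds[[s]])
      if (!is.na(k)) {
        arr$scaffolds[[s]] <- append(arr$scaffolds[[s]], id, after = k)
        arr$strands[id] <- arr$strands[[after_id]]
        return(arr)
      }
    }
    stop("parent gene not placed: ", after_id)
  }
  pool <- names(arr$scaffolds)
  if (!is.null(avoid_id)) {
    av <- arr_scaffold_of(arr, avoid_id)
    if (!is.na(av) && length(pool) > 1) pool <- setdiff(pool, av)
  }
  s <- pool[sample.int(length(pool), 1L)]
  pos <- sample.int(length(arr$scaffolds[[s]]) + 1L, 1L)
  arr$scaffolds[[s]] <- append(arr$scaffolds[[s]], id, after = pos - 1L)
  arr$strands[id] <- strand
  arr
}

#' @noRd
arr_remove <- function(arr, id) {
  for (s in names(arr$scaffolds)) {
    k <- match(id, arr$scaffolds[[s]])
    if (!is.na(k)) { arr$scaffolds[[s]] <- arr$scaffolds[[s]][-k]; break }
  }
  arr$strands <- arr$strands[names(arr$strands) != id]
  arr
}

# Evolve one lineage over one species-tree branch. Returns a within-branch
# genealogy node (recursive list) or NULL if the lineage died leaving no
# survivor at branch end. st: shared environment holding arrangement,
# event rows, lineage counter.
#' @noRd
evolve_on_branch <- function(lin, t_remain, branch, cfg, st, t_elapsed = 0) {
  rate <- branch_mults(cfg, branch)
  lam <- cfg$dup_rate * rate[["dup"]]
  mu <- cfg$loss_rate * rate[["loss"]]
  tot <- lam + mu
  dt <- if (tot > 0) rexp(1, tot) else Inf
  if (dt >= t_remain) {
    if (cfg$emit_sequences)
      lin$seq <- mutate_sequence(lin$seq, t_remain, cfg)
    return(list(kind = "tip", lin = lin, t = t_elapsed + t_remain))
  }
  is_dup <- runif(1) < (if (tot > 0) lam / tot else 0)
  if (cfg$emit_sequences) lin$seq <- mutate_sequence(lin$seq, dt, cfg)
  t_now <- t_elapsed + dt
  if (!is_dup) {
    st$events <- rbind(st$events, data.frame(
      branch = branch, kind = "loss", lineage = lin$id, time = t_now,
      stringsAsFactors = FALSE))
    if (cfg$emit_sequences) st$arr <- arr_remove(st$arr, lin$id)
    return(NULL)
  }
  st$lin_counter <- st$lin_counter + 1L
  new_id <- paste0("L", st$lin_counter)
  switch_fired <- runif(1) < cfg$chromophore_switch_prob
  tandem <- runif(1) < cfg$tandem_prob
  child <- lin
  child$id <- new_id
  if (cfg$emit_sequences) {
    child$seq <- mutate_sequence(child$seq, 0, cfg, switch = switch_fired)
  } else if (switch_fired) {
    child$chrom_switched <- TRUE
  }
  if (switch_fired) {
    # class follows the chromophore: QYG-class <-> RFP flip; XFG keeps
    # the parent class but is flagged by downstream chromophore checks
    tri <- if (cfg$emit_sequences)
      substr(child$seq, CHROMOPHORE_COLS[1], CHROMOPHORE_COLS[3]) else ""
    if (nchar(tri) == 3 && substr(tri, 2, 2) != "F")
      child$class <- if (substr(tri, 1, 1) == "D") "RFP" else
        if (lin$class == "RFP") "GFP/CFP" else lin$class
  }
  st$events <- rbind(st$events, data.frame(
    branch = branch, kind = "duplication", lineage = new_id, time = t_now,
    stringsAsFactors = FALSE))
  st$insert_mode <- rbind(st$insert_mode, data.frame(
    lineage = new_id, parent = lin$id,
    mode = if (tandem) "tandem" else "dispersed", stringsAsFactors = FALSE))
  if (cfg$emit_sequences) {
    if (tandem) st$arr <- arr_insert(st$arr, new_id, NULL, after_id = lin$id)
    else st$arr <- arr_insert(st$arr, new_id, sample(c("+", "-"), 1L),
                              avoid_id = lin$id)
  }
  left <- evolve_on_branch(lin, t_remain - dt, branch, cfg, st, t_now)
  right <- evolve_on_branch(child, t_remain - dt, branch, cfg, st, t_now)
  if (is.null(left) && is.null(right)) return(NULL)
  if (is.null(left)) return(right)
  if (is.null(right)) return(left)
  list(kind = "dup", t = t_now, left = left, right = right, dup_id = new_id)
}

# collect survivor lineage records (at branch end) from a branch genealogy
#' @noRd
branch_survivors <- function(node) {
  if (is.null(node)) return(list())
  if (node$kind == "tip") return(list(node$lin))
  c(branch_survivors(node$left), branch_survivors(node$right))
}

#' Simulate FP gene-family evolution along a species tree
#'
#' Runs the birth-death process from `root_copies` seed genes at the
#' species-tree root, evolving sequences, genome placements and the true
#' gene tree. Emits per-species proteomes and gene features plus a
#' ground-truth event log.
#'
#' @param config a `sim_config`
#' @return list with `proteomes` (named list of named character vectors,
#'   FP genes and decoys), `features` (named list of GFF3-style gene
#'   tables), and `truth` (a `true_event_log`: `events` incl. an
#'   `observable` flag, `per_node_copies`, `obs_per_node_copies`,
#'   `ledger` with per-branch true and observable event counts,
#'   `gene_tree_true` pruned to survivors, `placements`, `classes`,
#'   `chromophores`, `insert_modes`)
#' @export
simulate_family <- function(config) {
  cfg <- config
  tree <- cfg$species_tree
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  labels <- c(tree$tip.label, tree$node.label)

  st <- new.env(parent = emptyenv())
  st$events <- data.frame(branch = character(), kind = character(),
                          lineage = character(), time = numeric(),
                          stringsAsFactors = FALSE)
  st$insert_mode <- data.frame(lineage = character(), parent = character(),
                               mode = character(), stringsAsFactors = FALSE)
  st$lin_counter <- 0L
  st$tip_data <- list()       # per tip species: lineage records + arrangement
  st$per_node <- setNames(integer(length(labels)), labels)

  root_classes <- alloc_classes(cfg$root_copies, cfg$root_class_props)
  root_lins <- list()
  with_seed(substream_seed(cfg$seed, "::root"), {
    for (i in seq_len(cfg$root_copies)) {
      st$lin_counter <- st$lin_counter + 1L
      id <- paste0("L", st$lin_counter)
      cls <- root_classes[i]
      sq <- if (cfg$emit_sequences)
        mutate_sequence(FP_ARCHETYPES[[cls]], cfg$root_stem, cfg) else NULL
      root_lins[[id]] <- list(id = id, class = cls, seq = sq)
    }
  })
  st$per_node[node_label(tree, root)] <- length(root_lins)

  children_of <- function(node) tree$edge[tree$edge[, 1] == node, 2]
  edge_len <- function(child) tree$edge.length[which(tree$edge[, 2] == child)]

  # Recursive descent over the species tree. For each incoming lineage
  # (present at `node`) returns NULL if it left no surviving descendant,
  # else list(nwk, depth): `nwk` a newick fragment WITHOUT a top branch
  # length, `depth` the time offset of the fragment's root below the
  # species node (0 for a speciation at the node or a leaf; > 0 when
  # unary passages were suppressed).
  descend <- function(node, lineages, arr) {
    lab <- node_label(tree, node)
    if (node <= ntip) {
      st$tip_data[[lab]] <- list(lineages = lineages, arr = arr)
      return(lapply(lineages, function(l)
        list(nwk = paste0(lab, "|", lab, "_", l$id), depth = 0)))
    }
    kids <- children_of(node)
    per_child <- list()
    for (k in kids) {
      klab <- node_label(tree, k)
      t_br <- edge_len(k)
      sub <- with_seed(substream_seed(cfg$seed, klab), {
        st$arr <- arr
        frag <- list()
        for (nm in names(lineages))
          frag[[nm]] <- evolve_on_branch(lineages[[nm]], t_br, klab, cfg, st)
        list(frag = frag, arr = st$arr)
      })
      all_surv <- unlist(lapply(sub$frag, branch_survivors),
                         recursive = FALSE)
      if (is.null(all_surv)) all_surv <- list()
      names(all_surv) <- vapply(all_surv, function(l) l$id, "")
      st$per_node[klab] <- length(all_surv)
      deeper <- descend(k, all_surv, sub$arr)
      # stitch the within-branch genealogy with the deeper fragments;
      # returns list(str = newick incl. top length, t = absolute time in
      # the branch of the fragment root) or NULL
      stitch <- function(nd) {
        if (is.null(nd)) return(NULL)
        if (nd$kind == "tip") {
          d <- deeper[[nd$lin$id]]
          if (is.null(d)) return(NULL)
          return(list(str = d$nwk, t = t_br + d$depth))
        }
        l <- stitch(nd$left)
        r <- stitch(nd$right)
        if (is.null(l) && is.null(r)) return(NULL)
        if (is.null(l) || is.null(r)) return(if (is.null(l)) r else l)
        st$obs_dups <- c(st$obs_dups, setNames(klab, nd$dup_id))
        str <- paste0("(", l$str, ":", l$t - nd$t, ",",
                      r$str, ":", r$t - nd$t, ")")
        list(str = str, t = nd$t)
      }
      per_child[[klab]] <- lapply(sub$frag, stitch)
    }
    res <- setNames(vector("list", length(lineages)), names(lineages))
    klabs <- vapply(kids, function(k) node_label(tree, k), "")
    for (nm in names(lineages)) {
      parts <- lapply(per_child, function(pc) pc[[nm]])
      alive <- !vapply(parts, is.null, TRUE)
      if (!any(alive)) { res[nm] <- list(NULL); next }
      if (sum(alive) < length(kids)) {
        # survived through some daughters only: one observable loss per
        # daughter branch with no surviving descendants of this lineage
        for (lb in klabs[!alive])
          st$obs_losses <- rbind(st$obs_losses, data.frame(
            branch = lb, lineage = nm, stringsAsFactors = FALSE))
      }
      live <- parts[alive]
      if (length(live) == 1L) {
        res[[nm]] <- list(nwk = live[[1]]$str, depth = live[[1]]$t)
      } else {
        str <- paste0("(", live[[1]]$str, ":", live[[1]]$t, ",",
                      live[[2]]$str, ":", live[[2]]$t, ")", lab)
        res[[nm]] <- list(nwk = str, depth = 0)
      }
    }
    res
  }

  st$obs_losses <- data.frame(branch = character(), lineage = character(),
                              stringsAsFactors = FALSE)
  st$obs_dups <- character()

  root_arr <- if (cfg$emit_sequences)
    with_seed(substream_seed(cfg$seed, "::arrangement"),
              new_arrangement(cfg, names(root_lins), TRUE)) else
    list(scaffolds = list(), strands = character())

  tops <- descend(root, root_lins, root_arr)
  tops <- tops[!vapply(tops, is.null, TRUE)]

  # --- true gene tree ---------------------------------------------------
  # Root lineages that survive are joined by a caterpillar of pre-root
  # stem duplications, grouped by color class (classes are ancient clades
  # in the real family), with a fixed small stem spacing. Reconciliation
  # maps these stem joins to the species root, so inferred root-branch
  # duplications equal surviving root copies - 1 by construction.
  gene_tree <- NULL
  n_leaves <- sum(vapply(tops, function(p)
    length(gregexpr("\\|", p$nwk)[[1]]), 0L))
  if (length(tops) && n_leaves >= 2) {
    stem <- 0.05
    joins <- new.env(parent = emptyenv()); joins$k <- 0L
    cls_of <- vapply(names(tops), function(nm) root_lins[[nm]]$class, "")
    # position convention: time relative to the species root (fragment
    # roots sit at +depth); each successive stem join sits one `stem`
    # step further above the root
    join_group <- function(members) {
      cur <- NULL; cur_pos <- 0
      for (m in members) {
        if (is.null(cur)) { cur <- m$nwk; cur_pos <- m$depth; next }
        joins$k <- joins$k + 1L
        pos <- -stem * joins$k
        cur <- paste0("(", cur, ":", cur_pos - pos, ",",
                      m$nwk, ":", m$depth - pos, ")")
        cur_pos <- pos
      }
      list(nwk = cur, depth = cur_pos)
    }
    groups <- lapply(split(tops, cls_of), function(g)
      join_group(g[order(names(g))]))
    all <- join_group(groups[order(names(groups))])
    nwk <- all$nwk
    if (grepl("\\)[^(),:]*$", nwk)) nwk <- sub("\\)[^(),:]*$", ")", nwk)
    gene_tree <- ape::read.tree(text = paste0(nwk, "root;"))
    if (is.null(gene_tree$node.label)) gene_tree$node.label <-
        rep("", gene_tree$Nnode)
  }

  proteomes <- list(); features <- list(); placements <- list()
  classes <- character(); chroms <- character()
  for (sp in tree$tip.label) {
    td <- st$tip_data[[sp]]
    lins <- td$lineages
    fp_ids <- vapply(lins, function(l) l$id, "")
    gene_ids <- if (length(fp_ids)) paste0(sp, "_", fp_ids) else character(0)
    if (cfg$emit_sequences) {
      seqs <- setNames(vapply(lins, function(l) l$seq, ""),
                       if (length(gene_ids)) paste0(sp, "|", gene_ids)
                       else character(0))
      dec <- with_seed(substream_seed(cfg$seed, paste0("::decoy::", sp)), {
        nd <- cfg$decoy_genes_per_species
        if (nd > 0) {
          d <- vapply(seq_len(nd), function(i)
            paste(sample(AA20, 150 + (i * 7) %% 120, replace = TRUE),
                  collapse = ""), "")
          setNames(d, paste0(sp, "|", sp, "_DEC", seq_len(nd)))
        } else character()
      })
      proteomes[[sp]] <- c(seqs, dec)
      feat <- empty_features()
      for (sc in names(td$arr$scaffolds)) {
        ids <- td$arr$scaffolds[[sc]]
        if (!length(ids)) next
        n <- length(ids)
        start <- (seq_len(n) - 1L) * 1200L + 1L
        feat <- rbind(feat, data.frame(
          scaffold = sc, start = start, end = start + 689L,
          strand = unname(td$arr$strands[ids]),
          gene_id = paste0(sp, "_", ifelse(grepl("^DEC", ids),
                                           ids, ids)),
          family = ifelse(grepl("^DEC", ids), "decoy", "FP"),
          stringsAsFactors = FALSE))
      }
      features[[sp]] <- feat
      fp_feat <- feat[feat$family == "FP", , drop = FALSE]
      placements[[sp]] <- fp_feat
      for (i in seq_along(lins)) {
        gid <- gene_ids[i]
        classes[gid] <- lins[[i]]$class
        chroms[gid] <- substr(lins[[i]]$seq, CHROMOPHORE_COLS[1],
                              CHROMOPHORE_COLS[3])
      }
    } else {
      for (i in seq_along(lins)) classes[gene_ids[i]] <- lins[[i]]$class
    }
  }

  ledger <- truth_ledger(tree, st)
  truth <- list(events = ledger$events, per_node_copies = st$per_node,
                obs_per_node_copies = ledger$obs_copies,
                ledger = ledger$branches, gene_tree_true = gene_tree,
                placements = placements, classes = classes,
                chromophores = chroms, insert_modes = st$insert_mode)
  class(truth) <- "true_event_log"
  list(proteomes = proteomes, features = features, truth = truth)
}

# per-branch true + observable ledgers; observability from survivorship
#' @noRd
truth_ledger <- function(tree, st) {
  labels <- c(tree$tip.label, tree$node.label)
  ev <- st$events
  surv_ids <- unlist(lapply(st$tip_data, function(td)
    vapply(td$lineages, function(l) l$id, "")))
  obs_dup_lineages <- names(st$obs_dups)
  ev$observable <- ifelse(ev$kind == "duplication",
                          ev$lineage %in% obs_dup_lineages, FALSE)
  # observable losses were recorded at speciation passages
  br <- data.frame(branch = labels,
                   dups = 0L, losses = 0L, obs_dups = 0L, obs_losses = 0L,
                   stringsAsFactors = FALSE)
  if (nrow(ev)) {
    td <- table(ev$branch[ev$kind == "duplication"])
    tl <- table(ev$branch[ev$kind == "loss"])
    br$dups <- as.integer(td[br$branch]); br$dups[is.na(br$dups)] <- 0L
    br$losses <- as.integer(tl[br$branch]); br$losses[is.na(br$losses)] <- 0L
  }
  if (length(st$obs_dups)) {
    tod <- table(unname(st$obs_dups))
    br$obs_dups <- as.integer(tod[br$branch]); br$obs_dups[is.na(br$obs_dups)] <- 0L
  }
  if (nrow(st$obs_losses)) {
    tol <- table(st$obs_losses$branch)
    br$obs_losses <- as.integer(tol[br$branch]); br$obs_losses[is.na(br$obs_losses)] <- 0L
  }
  # observable copies: lineages at each node with surviving descendants;
  # recompute by propagation
  root_lab <- node_label(tree, ape::Ntip(tree) + 1L)
  obs <- setNames(integer(length(labels)), labels)
  # root observable copies = root lineages with any surviving tip data
  # (derivable from obs ledger propagation bottom-up is harder; do top-down)
  # count root lineages with survivors:
  # a root lineage survives if any tip lineage descends from it; lineage
  # ancestry is encoded in insert_mode (parent links)
  parent_of <- setNames(st$insert_mode$parent, st$insert_mode$lineage)
  root_anc <- function(id) {
    while (id %in% names(parent_of)) id <- parent_of[[id]]
    id
  }
  # propagate: obs copies at node = obs at parent + obs_dups - obs_losses
  obs[root_lab] <- length(unique(vapply(surv_ids, root_anc, "")))
  recurse <- function(node) {
    for (k in tree$edge[tree$edge[, 1] == node, 2]) {
      klab <- node_label(tree, k)
      plab <- node_label(tree, node)
      obs[klab] <<- obs[plab] + br$obs_dups[br$branch == klab] -
        br$obs_losses[br$branch == klab]
      if (k > ape::Ntip(tree)) recurse(k)
    }
  }
  recurse(ape::Ntip(tree) + 1L)
  list(events = ev, branches = br, obs_copies = obs)
}

#' Write a ground-truth event log to a tab-separated file
#'
#' Serializes the event table, per-node copy numbers, gene placements and
#' class labels as sectioned TSV text that `read_truth()` restores.
#'
#' @param log a `true_event_log`
#' @param path output path
#' @export
write_truth <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#coralfp-truth\tv1", con)
  sect <- function(name, df) {
    writeLines(paste0("##", name), con)
    writeLines(paste(colnames(df), collapse = "\t"), con)
    if (nrow(df))
      writeLines(do.call(paste, c(lapply(df, as.character), sep = "\t")), con)
  }
  sect("events", log$events)
  sect("ledger", log$ledger)
  cop <- data.frame(node = names(log$per_node_copies),
                    copies = as.integer(log$per_node_copies),
                    obs_copies = as.integer(
                      log$obs_per_node_copies[names(log$per_node_copies)]),
                    stringsAsFactors = FALSE)
  sect("copies", cop)
  cls <- data.frame(gene_id = names(log$classes),
                    class = unname(log$classes), stringsAsFactors = FALSE)
  sect("classes", cls)
  if (length(log$placements)) {
    pl <- do.call(rbind, Map(function(sp, df) {
      if (!nrow(df)) return(NULL)
      cbind(species = sp, df)
    }, names(log$placements), log$placements))
    if (is.null(pl)) pl <- data.frame(species = character())
  } else pl <- data.frame(species = character())
  sect("placements", pl)
  im <- log$insert_modes
  sect("insert_modes", im)
  writeLines("##gene_tree", con)
  if (!is.null(log$gene_tree_true))
    writeLines(ape::write.tree(log$gene_tree_true), con)
  invisible(path)
}

#' Read a ground-truth event log written by `write_truth()`
#' @param path file path
#' @return a `true_event_log` (placement tables and numeric columns restored)
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#coralfp-truth")) stop("not a coralfp truth file")
  marks <- grep("^##", lines)
  out <- list()
  for (i in seq_along(marks)) {
    name <- sub("^##", "", lines[marks[i]])
    end <- if (i < length(marks)) marks[i + 1] - 1L else length(lines)
    body <- lines[(marks[i] + 1L):end]
    body <- body[nzchar(body)]
    if (name == "gene_tree") {
      out$gene_tree_true <- if (length(body))
        ape::read.tree(text = body[1]) else NULL
      next
    }
    header <- strsplit(body[1], "\t")[[1]]
    rows <- if (length(body) > 1)
      do.call(rbind, strsplit(body[-1], "\t")) else
      matrix(character(), 0, length(header))
    df <- as.data.frame(rows, stringsAsFactors = FALSE)
    colnames(df) <- header
    for (cc in c("time", "start", "end", "dups", "losses", "obs_dups",
                 "obs_losses", "copies", "obs_copies"))
      if (cc %in% colnames(df)) df[[cc]] <- as.numeric(df[[cc]])
    if ("observable" %in% colnames(df))
      df$observable <- df$observable == "TRUE"
    out[[name]] <- df
  }
  log <- list(events = out$events, ledger = out$ledger)
  log$per_node_copies <- setNames(as.integer(out$copies$copies),
                                  out$copies$node)
  log$obs_per_node_copies <- setNames(as.integer(out$copies$obs_copies),
                                      out$copies$node)
  log$classes <- setNames(out$classes$class, out$classes$gene_id)
  pl <- out$placements
  log$placements <- if (nrow(pl)) split(pl[setdiff(colnames(pl), "species")],
                                        pl$species) else list()
  log$insert_modes <- out$insert_modes
  log$gene_tree_true <- out$gene_tree_true
  class(log) <- "true_event_log"
  log
}
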