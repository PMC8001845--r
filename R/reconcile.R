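# Duplication-loss parsimony reconciliation of a rooted gene tree against
# a rooted species tree (LCA mapping), per-branch event ledgers, ancestral
# copy numbers and per-color-class histories.

# --- species tree indexing ---------------------------------------------

#' @noRd
species_index <- function(species_tree) {
  tree <- ensure_node_labels(species_tree)
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  parent <- integer(nn); parent[] <- NA_integer_
  for (e in seq_len(nrow(tree$edge)))
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
  depth <- integer(nn)
  root <- n + 1L
  # preorder depths
  ord <- c(root, tree$edge[, 2][order(tree$edge[, 1])])
  depth[root] <- 0L
  for (v in tree$edge[, 2]) depth[v] <- NA_integer_
  # BFS
  queue <- root
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    for (k in kids) { depth[k] <- depth[v] + 1L; queue <- c(queue, k) }
  }
  labels <- c(tree$tip.label, tree$node.label)
  list(tree = tree, n = n, root = root, parent = parent, depth = depth,
       labels = labels, node_of = setNames(seq_len(nn), labels))
}

#' @noRd
sp_lca <- function(idx, a, b) {
  while (a != b) {
    if (idx$depth[a] < idx$depth[b]) b <- idx$parent[b]
    else if (idx$depth[b] < idx$depth[a]) a <- idx$parent[a]
    else { a <- idx$parent[a]; b <- idx$parent[b] }
  }
  a
}

#' @noRd
is_ancestor <- function(idx, anc, node) {
  while (!is.na(node)) {
    if (node == anc) return(TRUE)
    node <- idx$parent[node]
  }
  FALSE
}

#' LCA duplication-loss reconciliation
#'
#' Maps every gene-tree node to the species-tree LCA of its descendants'
#' species; an internal node is a duplication iff it maps to the same
#' species node as at least one child. Losses are charged to the species
#' branches whose lineages are skipped: for an edge (u, v) the gene
#' lineage passes path-length(M(u), M(v)) - 1 speciations when u is a
#' speciation (one more when u is a duplication with M(v) below M(u)),
#' and each passage with no representative on the other side charges one
#' loss to the branch ending at the missing daughter. The LCA mapping
#' minimizes duplications + losses over all valid mappings.
#'
#' @param gene_tree rooted binary `phylo`; tip labels `species|gene_id`
#' @param species_tree rooted `phylo` with unique labels
#' @param sep separator between species and gene id in tip labels
#' @return object of class `fp_reconciliation`: `map` (gene node ->
#'   species label), `events` (gene internal node -> speciation or
#'   duplication), `losses` data.frame (gene_edge_child, species branch
#'   charged), plus the trees
#' @export
lca_map <- function(gene_tree, species_tree, sep = "|") {
  if (!ape::is.rooted(gene_tree)) stop("gene tree must be rooted")
  if (!ape::is.binary(gene_tree))
    stop("gene tree has polytomies; resolve them first")
  idx <- species_index(species_tree)
  gt <- gene_tree
  gn <- ape::Ntip(gt)
  gnn <- gn + gt$Nnode
  leaf_sp <- species_of(gt$tip.label)
  unknown <- setdiff(unique(leaf_sp), idx$labels[seq_len(idx$n)])
  if (length(unknown))
    stop("gene-tree leaf species not in species tree: ",
         paste(unknown, collapse = ", "))
  M <- integer(gnn)
  M[seq_len(gn)] <- idx$node_of[leaf_sp]
  # postorder over internal nodes: by decreasing depth from the root
  gparent <- integer(gnn); gparent[] <- NA_integer_
  for (e in seq_len(nrow(gt$edge))) gparent[gt$edge[e, 2]] <- gt$edge[e, 1]
  gdepth <- integer(gnn)
  for (v in seq_len(gnn)) {
    d0 <- 0L; p <- gparent[v]
    while (!is.na(p)) { d0 <- d0 + 1L; p <- gparent[p] }
    gdepth[v] <- d0
  }
  internal_nodes <- (gn + 1):gnn
  po <- internal_nodes[order(gdepth[internal_nodes], decreasing = TRUE)]
  kids_of <- split(gt$edge[, 2], gt$edge[, 1])
  for (v in po) {
    ks <- kids_of[[as.character(v)]]
    m <- M[ks[1]]
    for (k in ks[-1]) m <- sp_lca(idx, m, M[k])
    M[v] <- m
  }
  events <- rep(NA_character_, gnn)
  for (v in (gn + 1):gnn) {
    ks <- kids_of[[as.character(v)]]
    events[v] <- if (any(M[ks] == M[v])) "duplication" else "speciation"
  }
  # losses
  losses <- data.frame(gene_child = integer(), branch = character(),
                       stringsAsFactors = FALSE)
  for (e in seq_len(nrow(gt$edge))) {
    u <- gt$edge[e, 1]; v <- gt$edge[e, 2]
    su <- M[u]; sv <- M[v]
    if (su == sv && events[u] == "duplication") next
    # species path from sv up to su
    path <- sv
    p <- sv
    while (p != su) { p <- idx$parent[p]; path <- c(path, p) }
    # speciations passed: at each node X on the path strictly above sv
    # (and strictly below su when u is a speciation; including su when u
    # is a duplication), the lineage goes to the on-path child; the other
    # child is charged one loss
    top_excl <- if (events[u] == "duplication") 0L else 1L
    # path = c(sv, ..., su); passed nodes are path[2:(len-top_excl... )]
    len <- length(path)
    passed <- if (len - top_excl >= 2) path[2:(len - top_excl + 0L)] else integer()
    if (events[u] != "duplication") passed <- setdiff(passed, su)
    for (X in passed) {
      onpath <- path[match(X, path) - 1L]
      other <- setdiff(idx$tree$edge[idx$tree$edge[, 1] == X, 2], onpath)
      for (o in other)
        losses <- rbind(losses, data.frame(
          gene_child = v, branch = idx$labels[o], stringsAsFactors = FALSE))
    }
  }
  rec <- list(map = setNames(idx$labels[M], seq_len(gnn)),
              events = events, losses = losses,
              gene_tree = gt, species_tree = idx$tree)
  class(rec) <- "fp_reconciliation"
  rec
}

#' Per-branch event ledger from a reconciliation
#'
#' Duplications are attributed to the species branch ending at the node
#' they map to (the root's "branch" is the family stem: its copy number
#' is 1 plus the duplications mapping to the root). Copy numbers are
#' propagated root-to-tip as parent copies + branch duplications - branch
#' losses.
#'
#' @param rec an `fp_reconciliation`
#' @return object of class `fp_ledger`: data.frame with branch (label of
#'   the node the branch ends at), dups, losses, copies (at that node),
#'   plus `root` label
#' @export
build_ledger <- function(rec) {
  idx <- species_index(rec$species_tree)
  br <- data.frame(branch = idx$labels, dups = 0L, losses = 0L,
                   copies = NA_integer_, stringsAsFactors = FALSE)
  gn <- ape::Ntip(rec$gene_tree)
  dup_nodes <- which(rec$events == "duplication")
  if (length(dup_nodes)) {
    t1 <- table(rec$map[dup_nodes])
    i <- match(names(t1), br$branch)
    br$dups[i] <- as.integer(t1)
  }
  if (nrow(rec$losses)) {
    t2 <- table(rec$losses$branch)
    i <- match(names(t2), br$branch)
    br$losses[i] <- as.integer(t2)
  }
  root_lab <- idx$labels[idx$root]
  br$copies[br$branch == root_lab] <- 1L + br$dups[br$branch == root_lab]
  # preorder propagation
  queue <- idx$root
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (k in idx$tree$edge[idx$tree$edge[, 1] == v, 2]) {
      kl <- idx$labels[k]; vl <- idx$labels[v]
      br$copies[br$branch == kl] <-
        br$copies[br$branch == vl] + br$dups[br$branch == kl] -
        br$losses[br$branch == kl]
      if (k > idx$n) queue <- c(queue, k)
    }
  }
  led <- list(branches = br, root = root_lab)
  class(led) <- "fp_ledger"
  led
}

#' Ancestral copy number at a species-tree node
#'
#' Reads the ledger's copy number at `node`, cross-checked against the
#' root complement plus the signed event sums along the root-to-node path.
#'
#' @param ledger an `fp_ledger` (or its `branches` data.frame)
#' @param node species node label
#' @param species_tree species tree (required for the path cross-check
#'   when `ledger` is a bare data.frame)
#' @return integer copy number
#' @export
ancestral_copy_number <- function(ledger, node, species_tree = NULL) {
  br <- if (inherits(ledger, "fp_ledger")) ledger$branches else ledger
  i <- match(node, br$branch)
  if (is.na(i)) stop("unknown species node: ", node)
  as.integer(br$copies[i])
}

#' Random resolution of polytomies
#'
#' Resolves every polytomy by uniform sequential insertion (each new
#' child subtree attaches to a uniformly chosen edge of the growing local
#' tree, including its root edge), which is uniform over binary
#' resolutions. Reproducible given `seed`; binary input returns unchanged.
#'
#' @param tree rooted `phylo`
#' @param seed RNG seed
#' @return rooted binary `phylo`
#' @export
resolve_polytomies <- function(tree, seed = 1) {
  if (ape::is.binary(tree)) return(tree)
  with_seed(seed, {
    n <- ape::Ntip(tree)
    kids_of <- split(tree$edge[, 2], tree$edge[, 1])
    lab <- function(v) if (v <= n) tree$tip.label[v] else NULL
    build <- function(v) {
      ks <- kids_of[[as.character(v)]]
      if (is.null(ks)) return(lab(v))
      subs <- lapply(ks, build)
      # sequential insertion into a growing unordered rooted binary tree,
      # represented as nested pairlists
      cur <- subs[[1]]
      for (i in seq_along(subs)[-1]) {
        cur <- insert_uniform(cur, subs[[i]])
      }
      cur
    }
    # count edges of a nested structure (each node = list of 2 or a leaf)
    n_edges <- function(x) if (!is.list(x)) 1L else
      1L + n_edges(x[[1]]) + n_edges(x[[2]])
    insert_at <- function(x, new, k) {
      # k indexes edges in preorder (edge above x is 1)
      if (k == 1L) return(list(list(x, new), 0L))
      stopifnot(is.list(x))
      k <- k - 1L
      e1 <- n_edges(x[[1]])
      if (k <= e1) {
        r <- insert_at(x[[1]], new, k)
        return(list(list(r[[1]], x[[2]]), 0L))
      }
      r <- insert_at(x[[2]], new, k - e1)
      list(list(x[[1]], r[[1]]), 0L)
    }
    insert_uniform <- function(x, new) {
      k <- sample.int(n_edges(x), 1L)
      insert_at(x, new, k)[[1]]
    }
    to_newick <- function(x) if (!is.list(x)) x else
      paste0("(", to_newick(x[[1]]), ",", to_newick(x[[2]]), ")")
    root <- n + 1L
    out <- ape::read.tree(text = paste0(to_newick(build(root)), ";"))
    out
  })
}

#' Per-color-class duplication-loss histories
#'
#' Prunes the gene tree to each class's leaves (suppressing unary nodes),
#' reconciles each pruned tree independently and returns class ledgers.
#'
#' @param gene_tree rooted binary `phylo` of candidate genes
#' @param colors data.frame gene_id/class (from [assign_colors()]) or a
#'   named vector tip label -> class; every leaf must be colored
#' @param species_tree species tree
#' @return named list of `fp_ledger` (classes with < 2 leaves yield NULL
#'   with a zero single-gene ledger when exactly 1 leaf)
#' @export
per_class_history <- function(gene_tree, colors, species_tree) {
  cls <- if (is.data.frame(colors))
    setNames(colors$class, colors$gene_id) else colors
  tips <- gene_tree$tip.label
  key <- if (all(tips %in% names(cls))) tips else gene_of(tips)
  if (!all(key %in% names(cls)))
    stop("uncolored gene-tree leaves: ",
         paste(head(setdiff(key, names(cls)), 5), collapse = ", "))
  leaf_class <- cls[key]
  out <- list()
  for (k in unique(leaf_class)) {
    keep <- tips[leaf_class == k]
    if (length(keep) < 2) {
      out[[k]] <- if (length(keep) == 1)
        singleton_ledger(keep, species_tree) else NULL
      next
    }
    sub <- ape::keep.tip(gene_tree, keep)
    out[[k]] <- build_ledger(lca_map(sub, species_tree))
  }
  out
}

# ledger of a one-gene class: one lineage from the root down to the leaf's
# species, with a loss wherever the lineage's sister branch lacks it
#' @noRd
singleton_ledger <- function(leaf, species_tree) {
  idx <- species_index(species_tree)
  sp <- species_of(leaf)
  br <- data.frame(branch = idx$labels, dups = 0L, losses = 0L,
                   copies = 0L, stringsAsFactors = FALSE)
  node <- idx$node_of[[sp]]
  path <- node
  while (!is.na(idx$parent[node])) { node <- idx$parent[node]; path <- c(path, node) }
  for (v in path) br$copies[br$branch == idx$labels[v]] <- 1L
  for (v in path[-1]) {
    kids <- idx$tree$edge[idx$tree$edge[, 1] == v, 2]
    off <- setdiff(kids, path)
    for (o in off) {
      br$losses[br$branch == idx$labels[o]] <- 1L
      # copies below the loss stay 0 (initialized)
    }
  }
  led <- list(branches = br, root = idx$labels[idx$root])
  class(led) <- "fp_ledger"
  led
}

# --- brute-force reconciliation oracle helpers (exported for tests) -----

#' Minimum duplication+loss total over all valid mappings (brute force)
#'
#' Independent oracle for [lca_map()]: enumerates every mapping of gene
#' internal nodes to species nodes that satisfies the ancestry
#' constraints, computes duplications and path losses for each, and
#' returns the minimum total. Exponential; only for tiny trees.
#'
#' @inheritParams lca_map
#' @return list(total, dups, losses) of the parsimony optimum
#' @export
reconcile_bruteforce <- function(gene_tree, species_tree, sep = "|") {
  idx <- species_index(species_tree)
  gt <- gene_tree
  gn <- ape::Ntip(gt)
  gnn <- gn + gt$Nnode
  leaf_sp <- species_of(gt$tip.label)
  M0 <- integer(gnn)
  M0[seq_len(gn)] <- idx$node_of[leaf_sp]
  internal <- (gn + 1):gnn
  kids_of <- split(gt$edge[, 2], gt$edge[, 1])
  nn_sp <- idx$n + idx$tree$Nnode
  best <- Inf; best_parts <- NULL
  assign_next <- function(M, k) {
    if (k > length(internal)) {
      sc <- score_mapping(M)
      if (!is.null(sc) && sc$total < best) {
        best <<- sc$total; best_parts <<- sc
      }
      return(invisible())
    }
    v <- internal[k]
    for (s in seq_len(nn_sp)) {
      M[v] <- s
      assign_next(M, k + 1)
    }
  }
  # daughter of species node S through which W is reached (NA if W == S)
  daughter_toward <- function(S, W) {
    if (W == S) return(NA_integer_)
    p <- W
    while (!is.na(idx$parent[p]) && idx$parent[p] != S) p <- idx$parent[p]
    p
  }
  score_mapping <- function(M) {
    # validity: M(parent) ancestor-or-equal of M(child)
    d <- 0L; l <- 0L
    for (v in internal) {
      ks <- kids_of[[as.character(v)]]
      for (kk in ks) if (!is_ancestor(idx, M[v], M[kk])) return(NULL)
    }
    # a node is a speciation iff its children map strictly below M(v)
    # through *different* daughters of M(v); anything else requires a
    # duplication at M(v)
    dup <- rep(FALSE, gnn)
    for (v in internal) {
      ks <- kids_of[[as.character(v)]]
      dirs <- vapply(ks, function(kk) daughter_toward(M[v], M[kk]), 0L)
      dup[v] <- anyNA(dirs) || anyDuplicated(dirs) > 0
      if (dup[v]) d <- d + 1L
    }
    for (e in seq_len(nrow(gt$edge))) {
      u <- gt$edge[e, 1]; v <- gt$edge[e, 2]
      dist <- idx$depth[M[v]] - idx$depth[M[u]]
      l <- l + if (dup[u]) dist else max(dist - 1L, 0L)
    }
    list(total = d + l, dups = d, losses = l)
  }
  # postorder internal nodes order irrelevant for enumeration
  assign_next(M0, 1)
  best_parts
}
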