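# Alignment, distance tree with bootstrap, and clade-based color
# classification. Neighbor-joining on p-distances stands in for ML tree
# search: the downstream classification consumes only clade membership
# and support values.

#' Center-star progressive multiple alignment
#'
#' The center is the sequence maximizing the summed pairwise global
#' alignment score; all others are aligned to it pairwise and merged
#' under "once a gap, always a gap". Deterministic; duplicate ids error.
#'
#' @param sequences named character vector (>= 2 sequences)
#' @param submat substitution matrix (default BLOSUM62)
#' @param gap_open,gap_ext affine gap penalties
#' @return object of class `fp_msa`: named character vector `seqs` of
#'   equal-length gapped rows, `center` id, `n_cols`
#' @export
align_sequences <- function(sequences, submat = blosum62(),
                            gap_open = 11, gap_ext = 1) {
  n <- length(sequences)
  stopifnot(n >= 2)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must carry unique names")
  ids <- names(sequences)
  # choose the center
  tot <- setNames(numeric(n), ids)
  pair_cache <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    al <- .nw_align(sequences[[i]], sequences[[j]], submat, gap_open, gap_ext)
    tot[i] <- tot[i] + al$score
    tot[j] <- tot[j] + al$score
    pair_cache[[paste(i, j)]] <- al
  }
  ci <- which.max(tot)            # ties: first (deterministic)
  center <- sequences[[ci]]
  # master holds the center row with accumulated gaps; each merged row is
  # re-padded when new center gaps appear ("once a gap, always a gap")
  master <- strsplit(center, "")[[1]]
  rows <- list()
  rows[[ids[ci]]] <- master
  for (k in seq_len(n)[-ci]) {
    al <- if (k < ci) pair_cache[[paste(k, ci)]] else pair_cache[[paste(ci, k)]]
    if (k < ci) { sa <- al$b; sb <- al$a } else { sa <- al$a; sb <- al$b }
    # sa = center as aligned in the pair, sb = new sequence
    ca <- strsplit(sa, "")[[1]]
    cb <- strsplit(sb, "")[[1]]
    # map: walk master and pair-center together, inserting gaps on the
    # side that lacks them
    mi <- 1; pi <- 1
    new_master <- character(); new_row <- character()
    width_old <- length(master)
    patch <- list()  # column insertions applied to existing rows
    while (mi <= length(master) || pi <= length(ca)) {
      m_gap <- mi <= length(master) && master[mi] == "-"
      p_gap <- pi <= length(ca) && ca[pi] == "-"
      m_res <- mi <= length(master) && !m_gap
      p_res <- pi <= length(ca) && !p_gap
      if (m_res && p_res) {
        new_master <- c(new_master, master[mi])
        new_row <- c(new_row, cb[pi])
        mi <- mi + 1; pi <- pi + 1
      } else if (m_gap) {
        # master has a gap column the pair alignment lacks
        new_master <- c(new_master, "-")
        new_row <- c(new_row, "-")
        mi <- mi + 1
      } else if (p_gap) {
        # pair alignment inserts a new gap into the center
        new_master <- c(new_master, "-")
        new_row <- c(new_row, cb[pi])
        patch[[length(patch) + 1]] <- length(new_master)
        pi <- pi + 1
      } else break
    }
    if (length(patch)) {
      at <- unlist(patch)
      for (nm in names(rows)) {
        old <- rows[[nm]]
        out <- character(length(new_master))
        oi <- 1
        for (col in seq_along(new_master)) {
          if (col %in% at) out[col] <- "-"
          else { out[col] <- old[oi]; oi <- oi + 1 }
        }
        rows[[nm]] <- out
      }
    }
    master <- new_master
    rows[[ids[k]]] <- new_row
  }
  # rows may be shorter than master if merged before later insertions --
  # patched above; sanity check
  lens <- vapply(rows, length, 0L)
  stopifnot(all(lens == length(master)))
  seqs <- vapply(rows[ids], paste, "", collapse = "")
  obj <- list(seqs = seqs, center = ids[ci], n_cols = length(master))
  class(obj) <- "fp_msa"
  obj
}

#' Pairwise p-distance matrix from an alignment
#'
#' Proportion of differing residues over pairwise-complete (both ungapped)
#' columns. A pair with zero comparable columns is an error naming the
#' pair.
#'
#' @param msa an `fp_msa`, a named character vector of equal-length gapped
#'   sequences, or a character matrix (rows = sequences)
#' @return symmetric numeric matrix with zero diagonal
#' @export
distance_matrix <- function(msa) {
  m <- if (is.matrix(msa)) msa else {
    seqs <- if (inherits(msa, "fp_msa")) msa$seqs else msa
    stopifnot(length(seqs) >= 2, length(unique(nchar(seqs))) == 1)
    mm <- do.call(rbind, strsplit(unname(seqs), ""))
    rownames(mm) <- names(seqs)
    mm
  }
  n <- nrow(m)
  ids <- rownames(m)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  gap <- m == "-"
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !gap[i, ] & !gap[j, ]
    if (!any(ok))
      stop("no comparable columns between ", ids[i], " and ", ids[j])
    d[i, j] <- d[j, i] <- mean(m[i, ok] != m[j, ok])
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Q-criterion agglomeration. Ties in the Q minimum are broken
#' by the lexicographically smallest joined-pair labels; negative branch
#' lengths are clamped to zero with the deficit moved to the sibling
#' branch.
#'
#' @param d symmetric distance matrix with labels (n >= 3)
#' @return unrooted `phylo`
#' @export
nj_tree <- function(d) {
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix not symmetric")
  labs <- rownames(d)
  stopifnot(!is.null(labs), length(labs) >= 3)
  n <- length(labs)
  # working nodes carry newick fragments
  frag <- setNames(as.list(labs), labs)
  D <- d
  active <- labs
  while (length(active) > 3) {
    m <- length(active)
    Ds <- D[active, active]
    r <- rowSums(Ds)
    Q <- (m - 2) * Ds - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pairs <- cbind(active[cand[, 1]], active[cand[, 2]])
    key <- apply(pairs, 1, function(p) paste(sort(p), collapse = "\r"))
    pick <- which.min(rank(key, ties.method = "first"))
    a <- pairs[pick, 1]; b <- pairs[pick, 2]
    dab <- D[a, b]
    la <- dab / 2 + (r[a] - r[b]) / (2 * (m - 2))
    lb <- dab - la
    if (la < 0) { lb <- lb + la; la <- 0 }
    if (lb < 0) { la <- la + lb; lb <- 0 }
    u <- paste0("U", n - length(active) + 1)
    frag[[u]] <- paste0("(", frag[[a]], ":", format(la, digits = 12), ",",
                        frag[[b]], ":", format(lb, digits = 12), ")")
    others <- setdiff(active, c(a, b))
    newd <- (D[a, others] + D[b, others] - dab) / 2
    D <- rbind(cbind(D, 0), 0)
    rownames(D)[nrow(D)] <- colnames(D)[ncol(D)] <- u
    D[u, others] <- D[others, u] <- newd
    active <- c(others, u)
  }
  a <- active[1]; b <- active[2]; c3 <- active[3]
  la <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  lb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
  lc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
  fix <- function(x) max(x, 0)
  nwk <- paste0("(", frag[[a]], ":", format(fix(la), digits = 12), ",",
                frag[[b]], ":", format(fix(lb), digits = 12), ",",
                frag[[c3]], ":", format(fix(lc), digits = 12), ");")
  ape::read.tree(text = nwk)
}

# canonical key of the bipartition induced by the tips `inside` on a tree
# with tip set `all_tips`: the lexicographically smaller side, sorted
#' @noRd
bipart_key <- function(inside, all_tips) {
  a <- sort(inside)
  b <- sort(setdiff(all_tips, inside))
  ka <- paste(a, collapse = "\r")
  kb <- paste(b, collapse = "\r")
  if (length(a) < length(b) || (length(a) == length(b) && ka < kb)) ka else kb
}

#' @noRd
tree_biparts <- function(tree) {
  tips <- tree$tip.label
  n <- ape::Ntip(tree)
  keys <- character()
  for (node in (n + 2):(n + tree$Nnode)) {   # skip the root
    below <- tips[unlist(phangorn::Descendants(tree, node, "tips"))]
    if (length(below) > 1 && length(below) < length(tips) - 1)
      keys <- c(keys, bipart_key(below, tips))
  }
  unique(keys)
}

#' Bootstrap support for the bipartitions of an alignment's NJ tree
#'
#' Columns are resampled with replacement `n_replicates` times; support
#' for a bipartition is the percentage of replicate NJ trees containing
#' it. Deterministic given `seed`.
#'
#' @param msa an `fp_msa` (or named gapped sequences)
#' @param n_replicates bootstrap replicates (default 1000)
#' @param seed RNG seed
#' @return list: `tree` (NJ tree of the full alignment), `support` named
#'   numeric vector keyed by canonical bipartition, percentages
#' @export
bootstrap_support <- function(msa, n_replicates = 1000, seed = 1) {
  stopifnot(n_replicates >= 1)
  seqs <- if (inherits(msa, "fp_msa")) msa$seqs else msa
  m <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(m) <- names(seqs)
  base_tree <- nj_tree(distance_matrix(seqs))
  counts <- new.env(parent = emptyenv())
  with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      idx <- sample.int(ncol(m), ncol(m), replace = TRUE)
      mm <- m[, idx, drop = FALSE]
      dt <- tryCatch(distance_matrix(mm), error = function(e) NULL)
      if (is.null(dt)) next
      bt <- nj_tree(dt)
      for (k in tree_biparts(bt)) {
        cur <- if (is.null(counts[[k]])) 0L else counts[[k]]
        assign(k, cur + 1L, envir = counts)
      }
    }
  })
  keys <- tree_biparts(base_tree)
  supp <- vapply(keys, function(k) {
    c0 <- if (is.null(counts[[k]])) 0L else counts[[k]]
    100 * c0 / n_replicates
  }, 0)
  list(tree = base_tree, support = supp)
}

#' Root a gene tree on an outgroup
#'
#' Roots on the given outgroup leaf set if it forms one side of a
#' bipartition of the unrooted tree; otherwise falls back to midpoint
#' rooting with a warning (also used when the set is empty).
#'
#' @param tree unrooted (or rooted) `phylo`
#' @param outgroup character vector of outgroup tip labels
#' @return rooted `phylo`
#' @export
root_tree <- function(tree, outgroup = character()) {
  outgroup <- intersect(outgroup, tree$tip.label)
  if (length(outgroup)) {
    ok <- length(outgroup) == 1 ||
      ape::is.monophyletic(tree, outgroup) ||
      ape::is.monophyletic(tree, setdiff(tree$tip.label, outgroup))
    if (ok) {
      rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
      return(rooted)
    }
    warning("outgroup is not a cluster; falling back to midpoint rooting")
  }
  phangorn::midpoint(tree)
}

#' Assign color classes from clade membership
#'
#' The RFP clade is the smallest rooted clade containing all RFP-labeled
#' references; if its bootstrap support reaches `support_min`, its member
#' candidates are classified RFP (likewise ChrP). Everything else falls
#' to the default GFP/CFP class, mirroring the inability of sequence data
#' to separate GFPs from CFPs. If the two supported clades overlap, the
#' smaller wins and the conflict is logged as a warning.
#'
#' @param tree rooted `phylo` whose tips include candidates and references
#' @param reference_colors named character vector: reference tip label ->
#'   color in Green/Cyan/Red/Non-fluorescent (or GFP/CFP / RFP / ChrP)
#' @param support named support vector from [bootstrap_support()]
#'   (bipartition-keyed); clade support defaults to 0 when absent
#' @param support_min minimum percent support (default 90)
#' @return data.frame: gene_id, class, provenance (clade/default) for
#'   every non-reference tip
#' @export
assign_colors <- function(tree, reference_colors, support = numeric(),
                          support_min = 90) {
  canon <- c(Green = "GFP/CFP", Cyan = "GFP/CFP", `GFP/CFP` = "GFP/CFP",
             Red = "RFP", RFP = "RFP",
             `Non-fluorescent` = "ChrP", ChrP = "ChrP")
  refs <- names(reference_colors)
  cls <- canon[reference_colors]
  if (!any(cls == "RFP", na.rm = TRUE) || !any(cls == "ChrP", na.rm = TRUE))
    stop("need at least one RFP and one ChrP reference in the tree")
  tips <- tree$tip.label
  clade_of <- function(klass) {
    members <- refs[which(cls == klass)]
    members <- intersect(members, tips)
    if (!length(members)) return(NULL)
    if (length(members) == 1) {
      node <- match(members, tips)
    } else node <- ape::getMRCA(tree, members)
    below <- tips[unlist(phangorn::Descendants(tree, node, "tips"))]
    if (length(below) == length(tips)) return(NULL)    # whole tree
    key <- bipart_key(below, tips)
    supp <- if (key %in% names(support)) support[[key]] else
      if (length(below) == 1) 100 else 0
    list(members = below, support = supp)
  }
  rfp <- clade_of("RFP")
  chrp <- clade_of("ChrP")
  take_rfp <- !is.null(rfp) && rfp$support >= support_min
  take_chrp <- !is.null(chrp) && chrp$support >= support_min
  if (take_rfp && take_chrp &&
      length(intersect(rfp$members, chrp$members))) {
    warning("RFP and ChrP clades overlap; smaller clade wins")
    if (length(rfp$members) <= length(chrp$members))
      chrp$members <- setdiff(chrp$members, rfp$members)
    else rfp$members <- setdiff(rfp$members, chrp$members)
  }
  cand <- setdiff(tips, refs)
  class_out <- setNames(rep("GFP/CFP", length(cand)), cand)
  prov <- setNames(rep("default", length(cand)), cand)
  if (take_rfp) {
    k <- intersect(cand, rfp$members)
    class_out[k] <- "RFP"; prov[k] <- "clade"
  }
  if (take_chrp) {
    k <- intersect(cand, chrp$members)
    class_out[k] <- "ChrP"; prov[k] <- "clade"
  }
  data.frame(gene_id = cand, class = unname(class_out),
             provenance = unname(prov), stringsAsFactors = FALSE,
             row.names = NULL)
}
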