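# shared miniature worlds for the test suite; everything is built in code

five_taxon_tree <- function() {
  coralfp:::ensure_node_labels(ape::read.tree(
    text = "((A:0.3,B:0.3)AB:0.4,(C:0.4,(D:0.2,E:0.2)DE:0.2)CDE:0.3)Root;"))
}

two_species_tree <- function() {
  tr <- ape::read.tree(text = "(A:1,B:1)r;")
  coralfp:::ensure_node_labels(tr)
}

# random amino-acid sequence
rand_prot <- function(n, seed) {
  set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, TRUE),
        collapse = "")
}

# shuffle a sequence (composition-preserving)
shuffle_prot <- function(s, seed) {
  set.seed(seed)
  paste(sample(strsplit(s, "")[[1]]), collapse = "")
}

# mutate fraction `frac` of residues (outside the chromophore columns)
mutate_frac <- function(s, frac, seed) {
  set.seed(seed)
  AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  v <- strsplit(s, "")[[1]]
  idx <- setdiff(seq_along(v), 63:65)
  pos <- sample(idx, round(frac * length(idx)))
  v[pos] <- vapply(v[pos], function(a) sample(setdiff(AA, a), 1), "")
  paste(v, collapse = "")
}

# unit-cost scoring matrix for alignment-cost arguments (match 0,
# mismatch -1), used with gap_open = 0, gap_ext = 1 so that maximizing
# score is minimizing unit edit cost
unit_submat <- function() {
  AA <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
  m <- matrix(-1, length(AA), length(AA), dimnames = list(AA, AA))
  diag(m) <- 0
  m
}

# uniform random rooted binary tree on given labels (sequential insertion)
rand_rooted_topology <- function(labels, seed) {
  set.seed(seed)
  nwk_of <- function(x) if (!is.list(x)) x else
    paste0("(", nwk_of(x[[1]]), ",", nwk_of(x[[2]]), ")")
  n_edges <- function(x) if (!is.list(x)) 1L else
    1L + n_edges(x[[1]]) + n_edges(x[[2]])
  insert_at <- function(x, new, k) {
    if (k == 1L) return(list(x, new))
    k <- k - 1L
    e1 <- n_edges(x[[1]])
    if (k <= e1) list(insert_at(x[[1]], new, k), x[[2]])
    else list(x[[1]], insert_at(x[[2]], new, k - e1))
  }
  cur <- labels[1]
  for (i in seq_along(labels)[-1])
    cur <- if (!is.list(cur) && i == 2) list(labels[1], labels[2]) else
      insert_at(cur, labels[i], sample.int(n_edges(cur), 1L))
  ape::read.tree(text = paste0(nwk_of(cur), ";"))
}
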