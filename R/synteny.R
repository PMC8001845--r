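# Gene clusters on scaffolds, cross-species ortholog links, tandem vs
# dispersed duplication classification, and gene-order comparison of
# clusters (the gene-order surrogate for nucleotide dot plots).

#' Detect FP gene clusters on scaffolds
#'
#' Two FP genes belong to one cluster iff they lie on the same scaffold
#' with at most `max_intervening` non-FP genes between them (transitive
#' closure). Singletons are not clusters. Overlapping coordinates are
#' ordered by start then end with a warning.
#'
#' @param features gene table (scaffold, start, end, strand, gene_id)
#' @param fp_ids character vector of FP gene ids
#' @param max_intervening maximum intervening non-FP genes (default 10;
#'   gene-order units)
#' @return list of clusters; each a list with species-agnostic fields:
#'   scaffold, members (data.frame gene_id, strand, rank, start, end),
#'   flank_left, flank_right (neighboring non-FP gene ids or NA)
#' @export
detect_clusters <- function(features, fp_ids, max_intervening = 10L) {
  out <- list()
  if (!nrow(features)) return(out)
  if (any(duplicated(features[c("scaffold", "start")])) ||
      any(features$end < features$start))
    warning("overlapping or malformed gene coordinates; ordering by start, end")
  for (sc in unique(features$scaffold)) {
    f <- features[features$scaffold == sc, , drop = FALSE]
    f <- f[order(f$start, f$end), , drop = FALSE]
    f$rank <- seq_len(nrow(f))
    is_fp <- f$gene_id %in% fp_ids
    pos <- which(is_fp)
    if (length(pos) < 2) next
    grp <- cumsum(c(1, diff(pos) - 1 > max_intervening))
    for (g in unique(grp)) {
      p <- pos[grp == g]
      if (length(p) < 2) next
      members <- f[p, c("gene_id", "strand", "rank", "start", "end")]
      rownames(members) <- NULL
      left <- if (min(p) > 1) f$gene_id[min(p) - 1] else NA_character_
      right <- if (max(p) < nrow(f)) f$gene_id[max(p) + 1] else NA_character_
      out[[length(out) + 1]] <- list(scaffold = sc, members = members,
                                     flank_left = left, flank_right = right)
    }
  }
  out
}

#' Ortholog/paralog links from a reconciliation
#'
#' For every pair of gene-tree leaves, the relation is read off the event
#' label of their gene-tree LCA: speciation = ortholog, duplication =
#' paralog.
#'
#' @param rec an `fp_reconciliation`
#' @param cross_species_only keep only pairs from different species
#'   (default TRUE, matching the figure-style ortholog symbols)
#' @return data.frame gene_a, gene_b, species_a, species_b, relation,
#'   lca_event_node
#' @export
orthology_links <- function(rec, cross_species_only = TRUE) {
  gt <- rec$gene_tree
  n <- ape::Ntip(gt)
  labs <- gt$tip.label
  out <- data.frame(gene_a = character(), gene_b = character(),
                    species_a = character(), species_b = character(),
                    relation = character(), lca = integer(),
                    stringsAsFactors = FALSE)
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    spi <- species_of(labs[i]); spj <- species_of(labs[j])
    if (cross_species_only && spi == spj) next
    lca <- ape::getMRCA(gt, c(labs[i], labs[j]))
    rel <- if (rec$events[lca] == "speciation") "ortholog" else "paralog"
    out <- rbind(out, data.frame(
      gene_a = labs[i], gene_b = labs[j], species_a = spi, species_b = spj,
      relation = rel, lca = lca, stringsAsFactors = FALSE))
  }
  out
}

#' Classify a paralog pair as tandem or dispersed
#'
#' Tandem iff both genes are members of the same detected cluster, else
#' dispersed. Unplaced genes are an error.
#'
#' @param gene_a,gene_b gene ids
#' @param clusters cluster list from [detect_clusters()]
#' @param features gene table used to verify placement
#' @return "tandem" or "dispersed"
#' @export
classify_duplication <- function(gene_a, gene_b, clusters, features) {
  for (g in c(gene_a, gene_b))
    if (!g %in% features$gene_id) stop("unplaced gene: ", g)
  for (cl in clusters) {
    m <- cl$members$gene_id
    if (gene_a %in% m && gene_b %in% m) return("tandem")
  }
  "dispersed"
}

#' Compare the gene order of two clusters through ortholog links
#'
#' Maps cluster B's ranks onto cluster A via the links and classifies the
#' relation: `collinear` (monotone increasing ranks, strands mostly
#' concordant), `inverted` (monotone decreasing, strands mostly
#' anti-concordant), else `rearranged`. Fewer than 2 links yields
#' `insufficient links`. Symmetric in its arguments.
#'
#' @param cluster_a,cluster_b clusters from [detect_clusters()]
#' @param links data.frame from [orthology_links()] (ortholog rows used)
#' @return list(verdict, n_links, table) where table is the order
#'   alignment (gene/rank/strand on both sides)
#' @export
compare_cluster_order <- function(cluster_a, cluster_b, links) {
  ma <- cluster_a$members; mb <- cluster_b$members
  links <- links[links$relation == "ortholog", , drop = FALSE]
  strip <- function(x) gene_of(x)
  la <- strip(links$gene_a); lb <- strip(links$gene_b)
  tab <- data.frame(gene_a = character(), rank_a = integer(),
                    strand_a = character(), gene_b = character(),
                    rank_b = integer(), strand_b = character(),
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(links))) {
    ga <- la[k]; gb <- lb[k]
    ia <- match(ga, ma$gene_id); ib <- match(gb, mb$gene_id)
    if (is.na(ia) || is.na(ib)) {
      ia <- match(gb, ma$gene_id); ib <- match(ga, mb$gene_id)
      if (is.na(ia) || is.na(ib)) next
      tmp <- ga; ga <- gb; gb <- tmp
    }
    tab <- rbind(tab, data.frame(
      gene_a = ga, rank_a = ma$rank[ia], strand_a = ma$strand[ia],
      gene_b = gb, rank_b = mb$rank[ib], strand_b = mb$strand[ib],
      stringsAsFactors = FALSE))
  }
  if (nrow(tab) < 2)
    return(list(verdict = "insufficient links", n_links = nrow(tab),
                table = tab))
  tab <- tab[order(tab$rank_a), , drop = FALSE]
  rb <- tab$rank_b
  inc <- all(diff(rb) > 0)
  dec <- all(diff(rb) < 0)
  same <- sum(tab$strand_a == tab$strand_b)
  opp <- nrow(tab) - same
  verdict <- if (inc && same >= opp) "collinear"
  else if (dec && opp >= same) "inverted"
  else "rearranged"
  list(verdict = verdict, n_links = nrow(tab), table = tab)
}
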