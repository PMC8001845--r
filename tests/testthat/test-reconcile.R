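# Duplication-loss reconciliation: worked examples, brute-force oracle,
# ledger conservation, monotonicity, per-class pruning, polytomy
# resolution.

test_that("congruent one-copy gene tree yields zero events, unit copies", {
  sp <- five_taxon_tree()
  g <- ape::read.tree(text =
    "((A|A_g:1,B|B_g:1):1,(C|C_g:1,(D|D_g:1,E|E_g:1):1):1);")
  rec <- lca_map(g, sp)
  expect_equal(sum(rec$events == "duplication", na.rm = TRUE), 0)
  expect_equal(nrow(rec$losses), 0)
  led <- build_ledger(rec)
  expect_true(all(led$branches$copies == 1))
})

test_that("textbook two-species cases match the exhaustive-mapping oracle", {
  sp <- two_species_tree()
  g1 <- ape::read.tree(text = "((A|a1:1,B|b1:1):1,(A|a2:1,B|b2:1):1);")
  r1 <- lca_map(g1, sp)
  expect_equal(sum(r1$events == "duplication", na.rm = TRUE), 1)
  expect_equal(nrow(r1$losses), 0)
  expect_identical(unname(r1$map[[as.character(ape::Ntip(g1) + 1)]]), "r")
  g2 <- ape::read.tree(text = "(A|a1:1,(A|a2:1,B|b1:1):1);")
  r2 <- lca_map(g2, sp)
  expect_equal(sum(r2$events == "duplication", na.rm = TRUE), 1)
  expect_equal(nrow(r2$losses), 1)
  expect_identical(r2$losses$branch, "B")
  for (g in list(g1, g2)) {
    bf <- reconcile_bruteforce(g, sp)
    rec <- lca_map(g, sp)
    expect_equal(sum(rec$events == "duplication", na.rm = TRUE) +
                   nrow(rec$losses), bf$total)
  }
  bad <- ape::read.tree(text = "(A|a1:1,Z|z1:1);")
  expect_error(lca_map(bad, sp), "Z")
})

test_that("LCA totals equal brute-force minima on sampled small instances", {
  # exhaustive species trees on 2-3 species, random gene trees up to 6
  # leaves; the full grid runs in the acceptance suite
  sps <- list(
    two_species_tree(),
    coralfp:::ensure_node_labels(ape::read.tree(text = "((A:1,B:1):1,C:1);")),
    coralfp:::ensure_node_labels(ape::read.tree(text = "(A:1,(B:1,C:1):1);")))
  set.seed(77)
  for (case in 1:40) {
    sp <- sps[[sample.int(length(sps), 1)]]
    n <- sample(2:6, 1)
    species <- sample(sp$tip.label, n, replace = TRUE)
    labs <- paste0(species, "|", species, "_g", seq_len(n))
    g <- rand_rooted_topology(labs, 9000 + case)
    rec <- lca_map(g, sp)
    total <- sum(rec$events == "duplication", na.rm = TRUE) + nrow(rec$losses)
    bf <- reconcile_bruteforce(g, sp)
    expect_equal(total, bf$total, info = paste("case", case))
  }
})

test_that("ledger conservation holds and path sums match stored copies", {
  sp <- five_taxon_tree()
  set.seed(5)
  for (case in 1:10) {
    n <- sample(4:10, 1)
    species <- sample(sp$tip.label, n, replace = TRUE)
    labs <- paste0(species, "|", species, "_g", seq_len(n))
    g <- rand_rooted_topology(labs, 500 + case)
    led <- build_ledger(lca_map(g, sp))
    br <- led$branches
    idx <- coralfp:::species_index(sp)
    for (e in seq_len(nrow(sp$edge))) {
      pv <- coralfp:::node_label(sp, sp$edge[e, 1])
      vv <- coralfp:::node_label(sp, sp$edge[e, 2])
      expect_equal(br$copies[br$branch == vv],
                   br$copies[br$branch == pv] + br$dups[br$branch == vv] -
                     br$losses[br$branch == vv])
    }
    # ancestral_copy_number equals root complement + signed path sums
    for (lab in br$branch) {
      node <- idx$node_of[[lab]]
      path <- lab
      while (!is.na(idx$parent[node])) {
        node <- idx$parent[node]
        path <- c(idx$labels[node], path)
      }
      expect_equal(ancestral_copy_number(led, lab),
                   br$copies[br$branch == led$root] +
                     sum(br$dups[match(path[-1], br$branch)]) -
                     sum(br$losses[match(path[-1], br$branch)]))
    }
  }
  expect_error(ancestral_copy_number(build_ledger(lca_map(
    ape::read.tree(text = "(A|x:1,B|y:1);"), two_species_tree())), "nope"),
    "unknown")
})

test_that("adding a within-species duplicate pair adds exactly one duplication", {
  sp <- five_taxon_tree()
  g <- ape::read.tree(text =
    "((A|A_g:1,B|B_g:1):1,(C|C_g:1,(D|D_g:1,E|E_g:1):1):1);")
  ndup <- function(gt) sum(lca_map(gt, sp)$events == "duplication",
                           na.rm = TRUE)
  base <- ndup(g)
  g2 <- ape::read.tree(text =
    "(((A|A_g:1,A|A_g2:1):1,B|B_g:1):1,(C|C_g:1,(D|D_g:1,E|E_g:1):1):1);")
  expect_equal(ndup(g2), base + 1)
})

test_that("per-class histories partition leaves and match restricted truth", {
  tr <- five_taxon_tree()
  cfg <- sim_config(tr, seed = 11, root_copies = 4, dup_rate = 0.25,
                    loss_rate = 0.05, subst_rate = 0.1,
                    chromophore_switch_prob = 0,
                    root_class_props = c(`GFP/CFP` = 0.5, RFP = 0.25,
                                         ChrP = 0.25))
  so <- simulate_family(cfg)
  gt <- so$truth$gene_tree_true
  cls <- so$truth$classes
  leaf_cls <- cls[coralfp:::gene_of(gt$tip.label)]
  names(leaf_cls) <- gt$tip.label
  hist <- per_class_history(gt, leaf_cls, tr)
  # class leaf counts sum to the total leaf count
  sizes <- vapply(names(hist), function(k) sum(leaf_cls == k), 0)
  expect_equal(sum(sizes), ape::Ntip(gt))
  # single class covering all leaves equals the total ledger
  uni <- per_class_history(gt, setNames(rep("GFP/CFP", ape::Ntip(gt)),
                                        gt$tip.label), tr)
  tot <- build_ledger(lca_map(gt, tr))
  expect_equal(uni[["GFP/CFP"]]$branches, tot$branches)
  # per-class dup totals on non-root branches match truth restricted to
  # that class's lineages (switching disabled, so class is heritable)
  ev <- so$truth$events
  im <- so$truth$insert_modes
  lin_class <- cls[!duplicated(sub("^.*_", "", names(cls)))]
  for (k in names(hist)) {
    led <- hist[[k]]$branches
    for (b in setdiff(led$branch, led$branch[led$branch == "Root"])) {
      obs_k <- so$truth$events
      # observable dups of this class on branch b
      dups_b <- obs_k[obs_k$branch == b & obs_k$kind == "duplication" &
                        obs_k$observable, "lineage"]
      if (!length(dups_b)) next
      cls_of_lin <- vapply(dups_b, function(l) {
        hits <- cls[grepl(paste0("_", l, "$"), names(cls))]
        if (length(hits)) hits[[1]] else NA_character_
      }, "")
      expect_gte(led$dups[led$branch == b] + 1e-9,
                 sum(cls_of_lin == k, na.rm = TRUE))
    }
  }
})

test_that("resolve_polytomies: identity, reproducibility, near-uniformity", {
  g <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  expect_identical(ape::write.tree(resolve_polytomies(g, 1)),
                   ape::write.tree(g))
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  r1 <- resolve_polytomies(star, 7)
  r2 <- resolve_polytomies(star, 7)
  expect_true(ape::is.binary(r1))
  expect_setequal(r1$tip.label, star$tip.label)
  expect_identical(ape::write.tree(r1), ape::write.tree(r2))
  # frequency over the 15 rooted topologies of a 4-star: loose chi-square
  keys <- vapply(1:1500, function(sd) {
    rr <- resolve_polytomies(star, sd)
    paste(sort(vapply(
      (ape::Ntip(rr) + 2):(ape::Ntip(rr) + rr$Nnode), function(nd)
        paste(sort(rr$tip.label[unlist(
          phangorn::Descendants(rr, nd, "tips"))]), collapse = ""),
      "")), collapse = "/")
  }, "")
  tab <- table(keys)
  expect_equal(length(tab), 15)
  chi <- sum((tab - 100)^2 / 100)
  expect_lt(chi, 40)   # df = 14; ~upper 99.9th percentile
})
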