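test_that("motif alignments concatenate additively in composition order", {
  fx <- clean_fixture()
  res <- clean_reconstruction()
  comp <- fx$compositions
  hom <- res$homologs |>
    dplyr::filter(primary, family %in% c("MPP", "SPP", "PreP"))
  # shared subset M16 + M16C across the three M16-like subfamilies
  sub <- tibble::tibble(motif_id = c("M16", "M16C"))
  aln <- align_family_motifs(hom, res$domain_hits, fx$proteome, sub)
  bounds <- attr(aln, "boundaries")
  expect_equal(nrow(bounds), 2)
  expect_equal(unique(nchar(aln)), max(bounds$end))
  expect_equal(bounds$end[2] - bounds$start[1] + 1,
               sum(bounds$end - bounds$start + 1))
  # column count at least the longest extracted instance
  m16_hits <- res$domain_hits |>
    dplyr::filter(gene_id %in% hom$gene_id, motif_id == "M16")
  expect_gte(bounds$end[1] - bounds$start[1] + 1,
             max(m16_hits$end - m16_hits$start + 1))

  # identical homologs give identical gap-free rows
  two <- hom[match(unique(hom$gene_id)[1:2], hom$gene_id), ]
  p2 <- fx$proteome
  p2$sequence[match(two$gene_id[2], p2$gene_id)] <-
    p2$sequence[match(two$gene_id[1], p2$gene_id)]
  dh2 <- annotate_domains(two, p2, fx$motif_models)
  a2 <- align_family_motifs(two, dh2, p2, sub)
  expect_equal(unname(a2[1]), unname(a2[2]))
})

test_that("tree inference handles minimal and additive cases", {
  aln3 <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAC", c = "CCCCCAAAAA")
  tr <- infer_tree(aln3)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  expect_true(all(tr$edge.length >= 0))
  expect_error(infer_tree(aln3[1:2]), "at least 3")

  # additive matrix from a known tree is reconstructed exactly
  true <- rand_tree(8)
  dm <- ape::cophenetic.phylo(true)
  rec <- infer_tree(dm)
  expect_equal(phangorn::RF.dist(ape::unroot(rec), ape::unroot(true)), 0)

  # row order does not change the unrooted topology
  fx <- clean_fixture()
  res <- clean_reconstruction()
  hom <- res$homologs |> dplyr::filter(primary, family == "OOP") |> head(12)
  aln <- align_family_motifs(hom, res$domain_hits, fx$proteome,
                             dplyr::filter(fx$compositions, family == "OOP"))
  t1 <- infer_tree(aln)
  t2 <- infer_tree(aln[rev(seq_along(aln))])
  expect_equal(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)), 0)
})

test_that("sequences simulated on a known tree are recovered by NJ", {
  models <- generate_motif_models(seed = 2)
  true <- ape::rtree(8, br = function(n) runif(n, 0.5, 1))
  fs <- family_spec("MPP", c("M16", "M16C"), core_rate_multiplier = 1,
                    linker_rate_multiplier = 1)
  ev <- evolve_sequences(true, fs, models, subst_rate = 0.3, seed = 3)
  aln <- setNames(ev$sequences$sequence, ev$sequences$gene_id)
  # blocks never indel, so raw sequences align position-wise per block
  blocks <- ev$blocks |> dplyr::filter(motif_id == "M16")
  rows <- setNames(substr(aln[blocks$gene_id], blocks$start, blocks$end),
                   blocks$gene_id)
  rec <- infer_tree(rows)
  expect_lte(phangorn::RF.dist(ape::unroot(rec), ape::unroot(true)), 2)
})

test_that("midpoint rooting matches hand computations and is idempotent", {
  two <- ape::read.tree(text = "(A:2,B:4);")
  r2 <- midpoint_root(two)
  d2 <- ape::node.depth.edgelength(r2)
  expect_equal(sort(d2[1:2]), c(3, 3))

  tr <- ape::read.tree(text = "((A:1,B:2):3,C:4);")
  r <- midpoint_root(tr)
  d <- ape::node.depth.edgelength(r)
  names(d)[1:3] <- r$tip.label
  expect_equal(unname(d["B"]), 4.5)
  expect_equal(unname(d["C"]), 4.5)

  r_again <- midpoint_root(r)
  expect_equal(phangorn::RF.dist(r, r_again, rooted = TRUE), 0)
  expect_equal(ape::node.depth.edgelength(r_again)[1:3],
               ape::node.depth.edgelength(r)[1:3])

  expect_warning(midpoint_root(ape::read.tree(text = "(A:0,B:0,(C:0,D:0):0);")),
                 "zero")
})

test_that("midpoint root minimizes the maximum leaf depth", {
  set.seed(11)
  for (rep in 1:20) {
    tr <- ape::unroot(rand_tree(sample(10:50, 1)))
    rooted <- midpoint_root(tr)
    got <- max(ape::node.depth.edgelength(rooted)[seq_along(rooted$tip.label)])
    # diameter endpoints equidistant within 1e-9
    dd <- ape::cophenetic.phylo(tr)
    diam <- max(dd)
    expect_lt(abs(got - diam / 2), 1e-9)
    # oracle: rooting anywhere along any edge never beats the midpoint —
    # sample candidate root positions on every edge and compare max depths
    dn <- ape::dist.nodes(tr)
    n_tip <- length(tr$tip.label)
    best_alt <- Inf
    for (e in seq_len(nrow(tr$edge))) {
      u <- tr$edge[e, 1]; v <- tr$edge[e, 2]; len <- tr$edge.length[e]
      for (f in seq(0, 1, length.out = 10)) {
        depth <- max(pmin(dn[u, seq_len(n_tip)] + f * len,
                          dn[v, seq_len(n_tip)] + (1 - f) * len))
        best_alt <- min(best_alt, depth)
      }
    }
    expect_lte(got, best_alt + 1e-9)
  }
})

test_that("monophyly test returns the smallest containing clade", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
  expect_true(isTRUE(is_monophyletic(tr, c("A", "B", "C"))))
  expect_true(isTRUE(is_monophyletic(tr, c("A", "B"))))
  res <- is_monophyletic(tr, c("A", "C"))
  expect_false(isTRUE(res))
  expect_equal(attr(res, "clade"), c("A", "B", "C"))
  expect_error(is_monophyletic(tr, "Z"), "not in tree")
})

test_that("group collapsing conserves counts and never mixes groups", {
  tr <- ape::read.tree(text = "((A1:1,A2:1):1,(B1:1,(A3:1,B2:1):1):1);")
  groups <- setNames(substr(tr$tip.label, 1, 1), tr$tip.label)
  cb <- collapse_by_group(tr, groups)
  expect_equal(sum(cb$leaves$n_leaves), 5)
  expect_setequal(cb$leaves$label, c("A|2", "B|1", "A|1", "B|1"))

  # all leaves in one group: a single pseudo-leaf
  one <- collapse_by_group(tr, setNames(rep("G", 5), tr$tip.label))
  expect_equal(nrow(one$leaves), 1)
  expect_equal(one$leaves$n_leaves, 5)

  expect_error(collapse_by_group(tr, groups[-1]), "unlabeled")

  # random trees: bookkeeping equals a brute-force clade scan
  set.seed(13)
  for (rep in 1:10) {
    tr2 <- rand_tree(20)
    g2 <- setNames(sample(c("x", "y", "z"), 20, replace = TRUE), tr2$tip.label)
    cb2 <- collapse_by_group(tr2, g2)
    expect_equal(sum(cb2$leaves$n_leaves), 20)
    for (grp in c("x", "y", "z")) {
      expect_equal(sum(cb2$leaves$n_leaves[cb2$leaves$group == grp]),
                   sum(g2 == grp))
    }
  }
})

test_that("misclassification counting agrees with the exhaustive oracle", {
  # perfectly sorted families: zero misclassified
  tr <- ape::read.tree(text = "(((x1:1,x2:1):1,x3:1):1,((y1:1,y2:1):1,y3:1):1);")
  lab <- setNames(substr(tr$tip.label, 1, 1), tr$tip.label)
  mc <- count_misclassified(tr, lab)
  expect_equal(mc$misclassified, c(0L, 0L))

  # one grafted leaf
  tr2 <- ape::read.tree(text = "(((x1:1,x2:1):1,x3:1):1,((y1:1,x4:1):1,y3:1):1);")
  lab2 <- setNames(substr(tr2$tip.label, 1, 1), tr2$tip.label)
  mc2 <- count_misclassified(tr2, lab2)
  expect_equal(mc2$misclassified[mc2$family == "x"], 1L)

  # single-leaf family: its own core clade, zero misclassified
  lab3 <- lab2; lab3["x4"] <- "z"
  mc3 <- count_misclassified(tr2, lab3)
  expect_equal(mc3$misclassified[mc3$family == "z"], 0L)
  expect_equal(mc3$core_size[mc3$family == "z"], 1L)

  # random label swaps: counts equal a brute-force scan over all clades
  set.seed(17)
  for (rep in 1:10) {
    tr4 <- rand_tree(15)
    lab4 <- setNames(sample(c("p", "q"), 15, replace = TRUE), tr4$tip.label)
    mc4 <- count_misclassified(tr4, lab4)
    desc <- phangorn::Descendants(tr4, seq_len(15 + tr4$Nnode), "tips")
    for (fam in unique(lab4)) {
      fam_tips <- which(lab4[tr4$tip.label] == fam)
      f1s <- vapply(desc, function(tp) {
        2 * sum(tp %in% fam_tips) / (length(tp) + length(fam_tips))
      }, numeric(1))
      best_f1 <- max(f1s)
      # all clades achieving best F1, take the minimum misclassified
      # consistent with the tie-break (smallest clade)
      cands <- which(abs(f1s - best_f1) < 1e-12)
      sizes <- lengths(desc[cands])
      chosen <- cands[order(sizes, cands)][1]
      oracle_mis <- sum(!(fam_tips %in% desc[[chosen]]))
      expect_equal(mc4$misclassified[mc4$family == fam], oracle_mis)
    }
  }
})

test_that("complement monophyly only at the root bipartition", {
  tr <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,(D:1,E:1):1);")
  left <- c("A", "B", "C")
  expect_true(isTRUE(is_monophyletic(tr, left)))
  expect_true(isTRUE(is_monophyletic(tr, c("D", "E"))))
  # a non-root split: subset monophyletic but complement not
  expect_true(isTRUE(is_monophyletic(tr, c("A", "B"))))
  expect_false(isTRUE(is_monophyletic(tr, c("C", "D", "E"))))
})
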