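test_that("seed search finds exact copies with full coverage and skips noise", {
  set.seed(1)
  ref <- rand_seq(200)
  prot <- tibble::tibble(
    gene_id = c("self", "junk1", "junk2"),
    species_id = c("s1", "s2", "s3"),
    sequence = c(ref, rand_seq(200), rand_seq(150))
  )
  hits <- seed_search(prot, ref)
  expect_true("self" %in% hits$gene_id)
  expect_equal(hits$coverage[hits$gene_id == "self"], 1.0)
  expect_false(any(c("junk1", "junk2") %in% hits$gene_id))
  # empty proteome is an empty result, not an error
  expect_equal(nrow(seed_search(prot[0, ], ref)), 0)
})

test_that("seed search recovers simulated family members", {
  fx <- noisy_fixture()
  hits <- seed_search(fx$proteome, fx$references[["OOP"]])
  oop <- fx$proteome$gene_id[fx$proteome$family_truth == "OOP"]
  # every gene still carrying the family's blocks is recovered
  intact <- fx$families$OOP$blocks |>
    dplyr::count(gene_id) |>
    dplyr::filter(n == 2) |>
    dplyr::pull(gene_id)
  expect_true(all(intact %in% hits$gene_id))
})

test_that("small clusters merge into their sister clades", {
  st <- default_species_tree()
  mk_hits <- function(counts) {
    purrr::imap_dfr(counts, function(n, cl) {
      sp <- st$taxonomy$species_id[st$taxonomy$clade == cl][seq_len(min(n, 10))]
      tibble::tibble(
        gene_id = sprintf("%s_h%d", cl, seq_len(n)),
        species_id = rep(sp, length.out = n)
      )
    })
  }
  # two clusters, one small: single merged cluster of 13
  h <- mk_hits(c(alpha = 10L, beta = 3L))
  cl <- cluster_hits(h, st, min_cluster_size = 5)
  expect_equal(length(unique(cl$cluster)), 1)
  expect_equal(nrow(cl), 13)

  # all clusters large enough: unchanged partition
  h2 <- mk_hits(c(alpha = 6L, beta = 7L, gamma = 9L))
  cl2 <- cluster_hits(h2, st, min_cluster_size = 5)
  expect_equal(sort(unique(cl2$cluster)), c("alpha", "beta", "gamma"))

  # merging replayed by an exhaustive oracle on a three-cluster chain
  h3 <- mk_hits(c(alpha = 2L, beta = 2L, gamma = 10L))
  cl3 <- cluster_hits(h3, st, min_cluster_size = 5)
  # oracle: repeatedly merge the smallest (alphabetical tie-break) into its
  # nearest cluster by minimum clade-to-clade patristic distance
  ctree <- egtrace:::clade_tree(st)
  dd <- ape::cophenetic.phylo(ctree)
  members <- list(alpha = "alpha", beta = "beta", gamma = "gamma")
  sizes <- c(alpha = 2, beta = 2, gamma = 10)
  while (length(members) > 1 && any(sizes < 5)) {
    small <- names(members)[order(sizes, names(members))][1]
    others <- setdiff(names(members), small)
    nd <- vapply(others, function(o) min(dd[members[[small]], members[[o]]]),
                 numeric(1))
    tgt <- others[order(nd, others)][1]
    members[[tgt]] <- sort(c(members[[tgt]], members[[small]]))
    sizes[tgt] <- sizes[tgt] + sizes[small]
    members[[small]] <- NULL
    sizes <- sizes[names(members)]
  }
  oracle_parts <- sort(vapply(members, paste, character(1), collapse = "+"))
  expect_equal(sort(unique(cl3$cluster)), unname(oracle_parts))

  # species absent from the taxonomy is an error naming it
  bad <- tibble::tibble(gene_id = "g", species_id = "martian_01")
  expect_error(cluster_hits(bad, st), "martian_01")
})

test_that("profiles summarize clusters and serialize losslessly", {
  s <- "MKLVANNHEWILTARHC"
  p <- build_profile(c(a = s, b = s))
  expect_equal(p$consensus, s)
  expect_false(p$degenerate)
  expect_true(build_profile(c(only = s))$degenerate)

  fx <- noisy_fixture()
  mpp <- fx$proteome |> dplyr::filter(family_truth == "MPP") |> head(20)
  prof <- build_profile(setNames(mpp$sequence, mpp$gene_id), family = "MPP")
  expect_gte(prof$length, min(nchar(mpp$sequence)))
  expect_lte(prof$length, max(nchar(mpp$sequence)))
  # top-scoring fixture sequence under this profile is an MPP gene
  sc <- egtrace:::sw_hits(prof$consensus,
                          setNames(fx$proteome$sequence, fx$proteome$gene_id))
  top <- sc$subject_id[which.max(sc$score)]
  expect_equal(fx$proteome$family_truth[fx$proteome$gene_id == top], "MPP")

  path <- withr::local_tempfile(fileext = ".json")
  write_profile(prof, path)
  back <- read_profile(path)
  expect_equal(back$consensus, prof$consensus)
  expect_equal(back$freq, prof$freq, tolerance = 1e-12)
  expect_equal(back$alignment, prof$alignment)
})

test_that("profile scan applies both E-value and coverage thresholds", {
  set.seed(2)
  core <- rand_seq(150)
  prof <- build_profile(c(a = core, b = core), family = "F")
  prot <- tibble::tibble(
    gene_id = c("full", "half", "junk"),
    species_id = c("s1", "s2", "s3"),
    sequence = c(core, substr(core, 1, 75), rand_seq(150))
  )
  cand <- profile_scan(list(prof), prot)
  expect_true("full" %in% cand$gene_id)
  expect_gte(cand$coverage[cand$gene_id == "full"], 0.99)
  expect_false("half" %in% cand$gene_id)   # covers only 0.5 of the profile
  expect_false("junk" %in% cand$gene_id)
  expect_error(profile_scan(list(), prot), "at least one profile")
})

test_that("profile scan recall is at least seed-search recall on the fixture", {
  fx <- noisy_fixture()
  res <- noisy_reconstruction()
  for (fam in names(fx$families)) {
    truth <- fx$proteome$gene_id[fx$proteome$family_truth == fam]
    seed_rec <- mean(truth %in% res$hits$gene_id[res$hits$family == fam])
    cand_rec <- mean(truth %in% res$candidates$gene_id)
    expect_gte(cand_rec, seed_rec)
  }
})

test_that("domain annotation finds blocks in simulated order and copies", {
  fx <- clean_fixture()
  spp <- fx$proteome |> dplyr::filter(family_truth == "SPP") |> head(10)
  dh <- annotate_domains(spp, fx$proteome, fx$motif_models,
                         compositions = fx$compositions)
  truth <- fx$families$SPP$blocks
  for (g in spp$gene_id) {
    got <- dh |> dplyr::filter(gene_id == g) |>
      dplyr::filter(motif_id %in% c("M16", "M16C")) |> dplyr::arrange(start)
    want <- truth |> dplyr::filter(gene_id == g) |> dplyr::arrange(start)
    expect_equal(got$motif_id, want$motif_id)
    # found coordinates line up with the simulated layout
    expect_true(all(abs(got$start - want$start) <= 2))
  }
  # scrambled sequence has no hits
  set.seed(3)
  junk <- tibble::tibble(gene_id = "junk", species_id = "s", sequence = rand_seq(300))
  expect_equal(nrow(annotate_domains(junk, junk, fx$motif_models)), 0)
  # a composition naming an unknown motif is a configuration error
  bad_comp <- tibble::tibble(family = "Z", motif_id = "NOPE")
  expect_error(annotate_domains(spp, fx$proteome, fx$motif_models,
                                compositions = bad_comp), "no model")
})

test_that("composition filter implements the published multisets", {
  mk <- function(motifs) {
    tibble::tibble(
      gene_id = "g1", motif_id = motifs,
      start = seq(1, by = 100, length.out = length(motifs)),
      end = seq(80, by = 100, length.out = length(motifs)),
      score = 100, evalue = 1e-10
    )
  }
  cand <- tibble::tibble(gene_id = "g1", species_id = "s1")
  # M16 + M16C: MPP only (SPP needs M16C twice, PreP needs M16C_assoc)
  hom <- filter_by_composition(cand, mk(c("M16", "M16C")))
  expect_equal(hom$family, "MPP")
  # no motifs at all: no family
  expect_equal(nrow(filter_by_composition(cand, mk(character()))), 0)
  # M16 + M16C + M16C_assoc satisfies MPP and PreP; PreP (larger) is primary
  hom2 <- filter_by_composition(cand, mk(c("M16", "M16C", "M16C_assoc")))
  expect_setequal(hom2$family, c("MPP", "PreP"))
  expect_equal(hom2$family[hom2$primary], "PreP")
  # doubled M16C satisfies MPP and SPP
  hom3 <- filter_by_composition(cand, mk(c("M16", "M16C", "M16C")))
  expect_setequal(hom3$family, c("MPP", "SPP"))
  expect_equal(hom3$family[hom3$primary], "SPP")
})

test_that("composition filter is order-independent", {
  fx <- clean_fixture()
  res <- clean_reconstruction()
  cand <- res$candidates
  set.seed(4)
  perm <- cand[sample(nrow(cand)), ]
  a <- filter_by_composition(cand, res$domain_hits, fx$compositions)
  b <- filter_by_composition(perm, res$domain_hits, fx$compositions)
  expect_equal(a, b)
})

test_that("zero-divergence catalog has perfect precision and recall", {
  fx <- clean_fixture()
  res <- clean_reconstruction()
  hom <- res$homologs |> dplyr::filter(primary)
  truth <- setNames(fx$proteome$family_truth, fx$proteome$gene_id)
  for (fam in names(fx$families)) {
    called <- hom$gene_id[hom$family == fam]
    actual <- names(truth)[truth == fam]
    expect_equal(sort(called), sort(actual), label = fam)
  }
})

test_that("homolog counts follow the catalog schema", {
  fx <- noisy_fixture()
  res <- noisy_reconstruction()
  counts <- res$counts
  expect_true(all(counts$n_species <= counts$n_proteins))
  expect_true(all(counts$family %in% names(fx$families)))
  # homologs are a subset of candidates
  expect_true(all(res$homologs$gene_id %in% res$candidates$gene_id))
})

test_that("additional-domain catalog reports the simulated extra block", {
  fx <- clean_fixture()
  res <- clean_reconstruction()
  extra <- catalog_additional_domains(
    res$homologs |> dplyr::filter(primary), fx$proteome, fx$motif_models,
    compositions = fx$compositions
  )
  # the OOP family carries a TPR-like block beyond its required M3
  oop_extras <- extra$extras |> dplyr::filter(family == "OOP")
  expect_true(all(oop_extras$motif_id == "TPR"))
  expect_gt(nrow(oop_extras), 0)
  # primary MPP homologs carry exactly the required motifs: no extras
  expect_equal(nrow(extra$extras |> dplyr::filter(family == "MPP")), 0)
  # species-sharing counts equal a brute-force group-by
  brute <- extra$extras |>
    dplyr::left_join(fx$proteome[, c("gene_id", "species_id")], by = "gene_id") |>
    dplyr::group_by(family, motif_id) |>
    dplyr::summarise(n = dplyr::n_distinct(species_id), .groups = "drop")
  expect_equal(extra$sharing$n_species, brute$n)
})

test_that("sample set picks one species per group plus resistant genera", {
  fx <- noisy_fixture()
  res <- noisy_reconstruction()
  hom <- res$homologs |> dplyr::filter(primary)
  ss <- suppressWarnings(
    sample_set(hom, fx$taxonomy, forced_species = "eukaryotes_01", seed = 5)
  )
  sel <- attr(ss, "selected_species")
  # determinism
  ss2 <- suppressWarnings(
    sample_set(hom, fx$taxonomy, forced_species = "eukaryotes_01", seed = 5)
  )
  expect_identical(sel, attr(ss2, "selected_species"))
  expect_true("eukaryotes_01" %in% sel)
  # oracle recomputation: one per clade with carriers, one per resistant
  # genus with carriers, plus forced; selection is within those set bounds
  carriers <- unique(hom$species_id)
  clades_with <- unique(fx$taxonomy$clade[fx$taxonomy$species_id %in% carriers])
  res_genera <- unique(fx$taxonomy$genus[fx$taxonomy$resistant == 1])
  genera_with <- res_genera[vapply(res_genera, function(g) {
    any(fx$taxonomy$species_id[fx$taxonomy$genus == g] %in% carriers)
  }, logical(1))]
  expect_gte(length(sel), length(clades_with))
  expect_lte(length(sel), length(clades_with) + length(genera_with) + 1)
  # every clade with carriers is represented
  expect_true(all(clades_with %in%
                    fx$taxonomy$clade[fx$taxonomy$species_id %in% sel]))
  # all homologs of each selected species are included
  expect_setequal(ss$gene_id, hom$gene_id[hom$species_id %in% sel])
})

test_that("relaxing thresholds never shrinks hit or candidate sets", {
  fx <- noisy_fixture()
  prot <- fx$proteome
  strict <- seed_search(prot, fx$references[["MPP"]],
                        min_coverage = 0.8, max_evalue = 1e-8)
  loose <- seed_search(prot, fx$references[["MPP"]],
                       min_coverage = 0.6, max_evalue = 1e-3)
  expect_true(all(strict$gene_id %in% loose$gene_id))

  res <- noisy_reconstruction()
  cand_loose <- profile_scan(res$profiles, prot,
                             max_evalue = 1e-1, min_profile_coverage = 0.6)
  expect_true(all(res$candidates$gene_id %in% cand_loose$gene_id))
})
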