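# End-to-end drivers: family reconstruction from a proteome collection, and
# the full analysis pipeline writing its result tables to disk.

#' Reconstruct peptidase families from a proteome collection
#'
#' Runs the whole catalog stage: seeded similarity search with each family
#' reference, clade clustering of the hits with small-cluster merging,
#' per-cluster profile construction, profile scan of the proteome, domain
#' annotation of the candidates and the motif-composition filter.
#'
#' @param proteome tibble `gene_id`, `species_id`, `sequence`.
#' @param references named character vector of family reference sequences.
#' @param species_tree `egt_species_tree` (taxonomy + tree, for clustering).
#' @param motif_models named character vector of motif models.
#' @param compositions composition table ([family_compositions()]).
#' @param seed_max_evalue,seed_min_coverage seeded-search thresholds.
#' @param scan_max_evalue,scan_min_coverage profile-scan thresholds.
#' @param domain_max_evalue domain-annotation threshold.
#' @param min_cluster_size minimum hits per clade cluster before merging.
#' @return list: `hits` (per family seed hits), `profiles`, `candidates`,
#'   `domain_hits`, `homologs`, `counts` (Table-1 schema).
#' @export
reconstruct_families <- function(proteome, references, species_tree,
                                 motif_models,
                                 compositions = family_compositions(),
                                 seed_max_evalue = 1e-5,
                                 seed_min_coverage = 0.70,
                                 scan_max_evalue = 1e-2,
                                 scan_min_coverage = 0.70,
                                 domain_max_evalue = 1e-2,
                                 min_cluster_size = 5) {
  proteome <- as_tibble(proteome)
  hits <- purrr::imap(references, function(ref, fam) {
    seed_search(proteome, ref, min_coverage = seed_min_coverage,
                max_evalue = seed_max_evalue) |>
      mutate(family = fam)
  })
  profiles <- purrr::imap(hits, function(h, fam) {
    if (nrow(h) == 0) return(list())
    cl <- cluster_hits(h, species_tree, min_cluster_size = min_cluster_size)
    purrr::imap(split(cl$gene_id, cl$cluster), function(g, cname) {
      build_profile(
        setNames(proteome$sequence[match(g, proteome$gene_id)], g),
        family = fam, cluster = cname
      )
    })
  }) |> purrr::flatten()
  candidates <- profile_scan(profiles, proteome,
                             max_evalue = scan_max_evalue,
                             min_profile_coverage = scan_min_coverage)
  domain_hits <- annotate_domains(candidates, proteome, motif_models,
                                  max_evalue = domain_max_evalue,
                                  compositions = compositions)
  homologs <- filter_by_composition(candidates, domain_hits, compositions)
  list(
    hits = bind_rows(hits),
    profiles = profiles,
    candidates = candidates,
    domain_hits = domain_hits,
    homologs = homologs,
    counts = homolog_counts(homologs, species_tree$taxonomy)
  )
}

#' Run the full analysis pipeline and write its result tables
#'
#' simulate -> catalog -> per-family gene tree -> proximity metrics with
#' top-k / pan-top-k -> resistant-vs-other comparison -> co-occurrence
#' enrichment -> logo statistics. All outputs are plain-text tables, so two
#' runs with identical configuration and seed are byte-identical.
#'
#' @param out_dir output directory.
#' @param seed root seed for every stage.
#' @param k top-k cutoff for donor-candidate selection.
#' @param fixture optional pre-built `egt_fixture`; by default one is
#'   simulated from `seed` at the package's default study conditions.
#' @return invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(out_dir, seed = 1, k = 10, fixture = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fx <- fixture %||% simulate_fixture(seed = seed)
  emit_fixture(fx, file.path(out_dir, "fixture"))

  cat_res <- reconstruct_families(
    fx$proteome, fx$references, fx$species_tree, fx$motif_models,
    fx$compositions
  )
  readr::write_tsv(cat_res$homologs, file.path(out_dir, "homologs.tsv"))
  readr::write_tsv(cat_res$candidates, file.path(out_dir, "candidates.tsv"))
  readr::write_tsv(cat_res$counts, file.path(out_dir, "family_counts.tsv"))

  annot <- leaf_annotations(fx)
  prox <- list()
  logos <- list()
  for (fam in sort(unique(cat_res$homologs$family[cat_res$homologs$primary]))) {
    hom <- filter(cat_res$homologs, .data$primary, .data$family == fam)
    if (nrow(hom) < 3) next
    aln <- align_family_motifs(hom, cat_res$domain_hits, fx$proteome,
                               filter(fx$compositions, .data$family == fam))
    tree <- midpoint_root(infer_tree(aln))
    ape::write.tree(tree, file.path(out_dir, sprintf("tree_%s.nwk", fam)))
    fam_annot <- filter(annot, .data$gene_id %in% tree$tip.label)
    if (any(fam_annot$domain_of_life == "Eukaryota")) {
      prox[[fam]] <- proximity_records(tree, fam_annot, fx$proteome,
                                       family = fam)
    }
    ls <- logo_stats(aln)
    ls$family <- fam
    logos[[fam]] <- ls
  }
  prox <- bind_rows(prox)
  readr::write_tsv(prox, file.path(out_dir, "proximity.tsv"))
  readr::write_tsv(bind_rows(logos), file.path(out_dir, "logo_stats.tsv"))

  topk <- purrr::map_dfr(sort(unique(prox$family)), function(fam) {
    pan <- pan_top_k(prox, fam, k = k)
    purrr::map_dfr(c("dist_E", "dist_T", "dist_S"), function(m) {
      tibble(family = fam, metric = m,
             species_id = top_k(prox, fam, m, k = k))
    }) |>
      bind_rows(tibble(family = fam, metric = "pan", species_id = pan))
  })
  readr::write_tsv(topk, file.path(out_dir, "top_k.tsv"))

  pres <- build_presence(
    filter(cat_res$homologs, .data$primary), fx$taxonomy,
    families = sort(unique(fx$compositions$family))
  )
  readr::write_tsv(pres, file.path(out_dir, "presence.tsv"))
  fams <- sort(unique(fx$compositions$family))
  pairs <- utils::combn(fams, 2, simplify = FALSE)
  enr <- purrr::map_dfr(pairs, function(p) {
    cooccurrence_enrichment(pres, p)
  })
  readr::write_tsv(enr, file.path(out_dir, "cooccurrence.tsv"))

  invisible(list(
    fixture = fx, catalog = cat_res, proximity = prox, top_k = topk,
    presence = pres, enrichment = enr, logos = bind_rows(logos)
  ))
}

#' Leaf annotation table for a fixture's gene trees
#'
#' @param fixture an `egt_fixture`.
#' @return tibble `gene_id`, `species_id`, `family_truth`,
#'   `domain_of_life`, `clade`, `genus`, `resistant`.
#' @export
leaf_annotations <- function(fixture) {
  fixture$proteome |>
    select("gene_id", "species_id", "family_truth") |>
    left_join(fixture$taxonomy, by = "species_id")
}
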