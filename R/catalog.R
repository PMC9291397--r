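# Family reconstruction: seeded similarity search, phylum-clustered profile
# construction, profile scan, domain annotation and the Table-1-style
# composition filter.

#' Seeded similarity search of a reference peptidase against a proteome
#'
#' @param proteome tibble with `gene_id`, `species_id`, `sequence`.
#' @param reference amino-acid string (the query; coverage is measured on it).
#' @param min_coverage minimum fraction of the reference covered by the
#'   local alignment (default 0.70).
#' @param max_evalue maximum E-value (default 1e-5).
#' @return tibble of hits: `gene_id`, `species_id`, `score`, `evalue`,
#'   `coverage`, sorted by E-value.
#' @export
seed_search <- function(proteome, reference, min_coverage = 0.70,
                        max_evalue = 1e-5) {
  stopifnot(nchar(reference) > 0)
  proteome <- as_tibble(proteome)
  if (nrow(proteome) == 0) {
    return(tibble(gene_id = character(), species_id = character(),
                  score = numeric(), evalue = numeric(), coverage = numeric()))
  }
  hits <- sw_hits(reference, setNames(proteome$sequence, proteome$gene_id))
  hits |>
    filter(.data$evalue <= max_evalue, .data$query_cov >= min_coverage) |>
    mutate(
      gene_id = .data$subject_id,
      species_id = proteome$species_id[match(.data$subject_id, proteome$gene_id)],
      coverage = .data$query_cov
    ) |>
    select("gene_id", "species_id", "score", "evalue", "coverage") |>
    arrange(.data$evalue, .data$gene_id)
}

# clade-level tree: one representative tip per clade, relabeled
clade_tree <- function(species_tree) {
  tax <- species_tree$taxonomy
  rep <- tax |> group_by(.data$clade) |> dplyr::slice(1) |> ungroup()
  tr <- ape::keep.tip(species_tree$tree, rep$species_id)
  tr$tip.label <- rep$clade[match(tr$tip.label, rep$species_id)]
  tr
}

#' Cluster search hits by clade, merging small clusters into sisters
#'
#' Hits are partitioned by the clade of their species; any cluster with
#' fewer than `min_cluster_size` hits is merged into the cluster of its
#' nearest sister clade on the taxonomy tree (patristic distance at clade
#' level; ties broken alphabetically by clade name), repeating until every
#' cluster reaches the minimum or only one cluster remains.
#'
#' @param hits tibble with `species_id` (and anything else, carried along).
#' @param species_tree an `egt_species_tree` providing taxonomy + tree.
#' @param min_cluster_size minimum hits per cluster (default 5).
#' @return `hits` with added columns `clade` and `cluster` (cluster name =
#'   sorted member clades joined with `+`).
#' @export
cluster_hits <- function(hits, species_tree, min_cluster_size = 5) {
  hits <- as_tibble(hits)
  tax <- species_tree$taxonomy
  unknown <- setdiff(unique(hits$species_id), tax$species_id)
  if (length(unknown) > 0) {
    stop("species missing from taxonomy: ", paste(unknown, collapse = ", "))
  }
  hits$clade <- tax$clade[match(hits$species_id, tax$species_id)]
  if (nrow(hits) == 0) {
    hits$cluster <- character()
    return(hits)
  }

  ct <- clade_tree(species_tree)
  dd <- ape::cophenetic.phylo(ct)
  # cluster membership: named list cluster -> clades
  members <- as.list(sort(unique(hits$clade)))
  names(members) <- unlist(members)
  sizes <- function() {
    vapply(members, function(cl) sum(hits$clade %in% cl), integer(1))
  }
  repeat {
    sz <- sizes()
    if (length(members) <= 1 || all(sz >= min_cluster_size)) break
    small <- names(members)[order(sz, names(members))][1]
    # nearest other cluster by minimum clade-to-clade patristic distance
    others <- setdiff(names(members), small)
    best <- vapply(others, function(o) {
      min(dd[members[[small]], members[[o]], drop = FALSE])
    }, numeric(1))
    target <- others[order(best, others)][1]
    members[[target]] <- sort(c(members[[target]], members[[small]]))
    members[[small]] <- NULL
  }
  cluster_of <- unlist(unname(purrr::map(members, function(cl) {
    setNames(rep(paste(cl, collapse = "+"), length(cl)), cl)
  })))
  hits$cluster <- unname(cluster_of[hits$clade])
  hits
}

#' Build a position-specific profile from a cluster of sequences
#'
#' Members are anchored on the shortest member (reference-coordinate
#' multiple alignment), so the profile models the compact core architecture
#' and remote homologs can still clear the profile-coverage threshold;
#' precision is delegated to the downstream composition filter. The profile
#' stores per-column residue frequencies and a majority-rule consensus used
#' as the scan query.
#'
#' @param seqs named character vector of cluster member sequences.
#' @param family,cluster optional labels carried on the profile.
#' @return an `egt_profile`: `consensus`, `freq` (20 x L matrix),
#'   `alignment`, `n`, `length`, `degenerate` (single-member flag).
#' @export
build_profile <- function(seqs, family = NA_character_, cluster = NA_character_) {
  if (length(seqs) == 0) stop("cannot build a profile from an empty cluster")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  ref <- seqs[[which.min(nchar(seqs))]]
  aln <- align_to_reference(seqs, ref)
  mat <- do.call(rbind, strsplit(aln, ""))
  counts <- apply(mat, 2, function(col) {
    tabulate(factor(col[col %in% AA_ALPHABET], levels = AA_ALPHABET), nbins = 20)
  })
  counts <- matrix(counts, nrow = 20)
  freq <- sweep(counts, 2, pmax(colSums(counts), 1), "/")
  # majority consensus, ties alphabetical; all-gap columns fall back to ref
  consensus <- vapply(seq_len(ncol(freq)), function(j) {
    if (all(freq[, j] == 0)) substr(ref, j, j) else AA_ALPHABET[which.max(freq[, j])]
  }, character(1))
  structure(
    list(
      consensus = paste(consensus, collapse = ""),
      freq = matrix(freq, nrow = 20, dimnames = list(AA_ALPHABET, NULL)),
      alignment = aln, n = length(seqs), length = nchar(ref),
      degenerate = length(seqs) == 1, family = family, cluster = cluster
    ),
    class = "egt_profile"
  )
}

#' @export
print.egt_profile <- function(x, ...) {
  cat("Sequence profile (", x$length, " columns, ", x$n, " members",
      if (x$degenerate) ", degenerate" else "", ")\n", sep = "")
  invisible(x)
}

#' Serialize / restore a profile
#' @param profile an `egt_profile`.
#' @param path file path.
#' @return `path` (write) or the restored `egt_profile` (read).
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "egt_profile"))
  x <- unclass(profile)
  x$freq <- as.data.frame(t(x$freq))
  x$alignment <- list(names = names(profile$alignment),
                      rows = unname(profile$alignment))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$freq <- t(as.matrix(x$freq))
  dimnames(x$freq) <- list(AA_ALPHABET, NULL)
  x$alignment <- setNames(x$alignment$rows, x$alignment$names)
  structure(x, class = "egt_profile")
}

#' Scan a proteome with family profiles
#'
#' A protein is a candidate for a family if, for at least one of the
#' family's profiles, the local alignment has E-value <= `max_evalue` and
#' covers more than `min_profile_coverage` of the profile. The best E-value
#' and its coverage are retained per (protein, family).
#'
#' @param profiles list of `egt_profile`s (with their `family` labels set).
#' @param proteome tibble with `gene_id`, `species_id`, `sequence`.
#' @param max_evalue E-value threshold (default 1e-2).
#' @param min_profile_coverage profile-coverage threshold, exclusive
#'   (default 0.70).
#' @return candidate tibble: `gene_id`, `species_id`, `family`, `evalue`,
#'   `coverage`.
#' @export
profile_scan <- function(profiles, proteome, max_evalue = 1e-2,
                         min_profile_coverage = 0.70) {
  if (length(profiles) == 0) stop("at least one profile is required")
  proteome <- as_tibble(proteome)
  subjects <- setNames(proteome$sequence, proteome$gene_id)
  all_hits <- purrr::map_dfr(profiles, function(pf) {
    sw_hits(pf$consensus, subjects) |>
      filter(.data$evalue <= max_evalue, .data$query_cov > min_profile_coverage) |>
      mutate(family = pf$family)
  })
  if (nrow(all_hits) == 0) {
    return(tibble(gene_id = character(), species_id = character(),
                  family = character(), evalue = numeric(), coverage = numeric()))
  }
  all_hits |>
    group_by(.data$subject_id, .data$family) |>
    slice_min(.data$evalue, n = 1, with_ties = FALSE) |>
    ungroup() |>
    mutate(
      gene_id = .data$subject_id,
      species_id = proteome$species_id[match(.data$subject_id, proteome$gene_id)],
      coverage = .data$query_cov
    ) |>
    select("gene_id", "species_id", "family", "evalue", "coverage") |>
    arrange(.data$family, .data$evalue, .data$gene_id)
}

#' Annotate candidate sequences with motif-model hits
#'
#' Repeated greedy local search per motif model: the best hit is recorded,
#' its span masked, and the search repeated, so multiple non-overlapping
#' instances of the same motif (e.g. the doubled M16C of the stromal
#' processing peptidase) are all found, resolved by descending score.
#'
#' @param candidates tibble with `gene_id` (typically from [profile_scan()]).
#' @param proteome tibble with `gene_id`, `sequence`.
#' @param motif_models named character vector of motif model sequences; every
#'   motif named in `compositions` must be present.
#' @param max_evalue hit threshold (default 1e-2).
#' @param compositions optional composition table ([family_compositions()])
#'   used to validate motif coverage.
#' @param max_copies per-motif cap on instances per protein.
#' @return domain-hit tibble: `gene_id`, `motif_id`, `start`, `end`
#'   (1-based inclusive), `score`, `evalue`.
#' @export
annotate_domains <- function(candidates, proteome, motif_models,
                             max_evalue = 1e-2, compositions = NULL,
                             max_copies = 4) {
  if (!is.null(compositions)) {
    missing <- setdiff(unique(compositions$motif_id), names(motif_models))
    if (length(missing) > 0) {
      stop("composition names motifs with no model: ", paste(missing, collapse = ", "))
    }
  }
  genes <- unique(candidates$gene_id)
  proteome <- as_tibble(proteome)
  seqs <- setNames(proteome$sequence, proteome$gene_id)[genes]
  if (anyNA(seqs)) stop("candidate gene missing from proteome")
  out <- list()
  for (motif in names(motif_models)) {
    active <- seqs
    for (iter in seq_len(max_copies)) {
      if (length(active) == 0) break
      h <- sw_hits(motif_models[[motif]], active) |>
        filter(.data$evalue <= max_evalue)
      if (nrow(h) == 0) break
      out[[length(out) + 1L]] <- h |>
        mutate(motif_id = motif) |>
        select(gene_id = "subject_id", "motif_id",
               start = "s_start", end = "s_end", "score", "evalue")
      # mask found spans and rescan for further copies
      masked <- vapply(seq_len(nrow(h)), function(i) {
        s <- active[[h$subject_id[i]]]
        paste0(substr(s, 1, h$s_start[i] - 1),
               strrep("X", h$s_end[i] - h$s_start[i] + 1),
               substr(s, h$s_end[i] + 1, nchar(s)))
      }, character(1))
      active <- setNames(masked, h$subject_id)
    }
  }
  if (length(out) == 0) {
    return(tibble(gene_id = character(), motif_id = character(),
                  start = integer(), end = integer(),
                  score = numeric(), evalue = numeric()))
  }
  bind_rows(out) |> arrange(.data$gene_id, .data$start)
}

#' Assign candidates to peptidase families by motif composition
#'
#' A candidate is a homolog of a family if its motif multiset contains the
#' family's required multiset (multiplicity-aware). Candidates satisfying
#' several compositions are reported under every satisfied family, with the
#' largest required multiset flagged `primary` (ties broken alphabetically).
#'
#' @param candidates tibble with `gene_id`, `species_id` (deduplicated on
#'   `gene_id`).
#' @param domain_hits output of [annotate_domains()].
#' @param compositions composition table ([family_compositions()]).
#' @return homolog tibble: `gene_id`, `species_id`, `family`, `primary`,
#'   `motifs` (comma-joined ids with coordinates).
#' @export
filter_by_composition <- function(candidates, domain_hits,
                                  compositions = family_compositions()) {
  cand <- as_tibble(candidates) |>
    distinct(.data$gene_id, .data$species_id) |>
    arrange(.data$gene_id)
  req <- compositions |> count(.data$family, .data$motif_id, name = "required")
  have <- domain_hits |> count(.data$gene_id, .data$motif_id, name = "found")
  fam_size <- req |> group_by(.data$family) |> summarise(size = sum(.data$required))

  assign_one <- function(gid) {
    h <- have[have$gene_id == gid, ]
    sat <- req |>
      left_join(h, by = "motif_id") |>
      group_by(.data$family) |>
      summarise(ok = all(!is.na(.data$found) & .data$found >= .data$required))
    fams <- sort(sat$family[sat$ok])
    if (length(fams) == 0) return(NULL)
    sizes <- fam_size$size[match(fams, fam_size$family)]
    tibble(gene_id = gid, family = fams,
           primary = fams == fams[sizes == max(sizes)][1])
  }
  homologs <- purrr::map_dfr(cand$gene_id, assign_one)
  if (nrow(homologs) == 0) {
    return(tibble(gene_id = character(), species_id = character(),
                  family = character(), primary = logical(), motifs = character()))
  }
  motif_str <- domain_hits |>
    mutate(tag = sprintf("%s:%d-%d", .data$motif_id, .data$start, .data$end)) |>
    group_by(.data$gene_id) |>
    summarise(motifs = paste(.data$tag, collapse = ","))
  homologs |>
    left_join(cand, by = "gene_id") |>
    left_join(motif_str, by = "gene_id") |>
    select("gene_id", "species_id", "family", "primary", "motifs") |>
    arrange(.data$family, .data$gene_id)
}

#' Per-family homolog and species counts by domain of life
#'
#' The Table-1 schema: for each family and domain of life, the number of
#' homologous proteins and of species carrying at least one.
#'
#' @param homologs output of [filter_by_composition()].
#' @param taxonomy tibble with `species_id`, `domain_of_life`.
#' @return tibble `family`, `domain_of_life`, `n_proteins`, `n_species`.
#' @export
homolog_counts <- function(homologs, taxonomy) {
  homologs |>
    filter(.data$primary) |>
    left_join(select(taxonomy, "species_id", "domain_of_life"), by = "species_id") |>
    group_by(.data$family, .data$domain_of_life) |>
    summarise(n_proteins = n(),
              n_species = dplyr::n_distinct(.data$species_id), .groups = "drop")
}

#' Catalog additional domains beyond a family's required composition
#'
#' Scans homologs against the full motif database at a stricter threshold
#' and reports, per homolog-family pair, motif instances in excess of the
#' family's required multiset, with the number of species sharing each
#' extra motif.
#'
#' @param homologs output of [filter_by_composition()].
#' @param proteome tibble with `gene_id`, `sequence`.
#' @param motif_db named character vector: the full motif model collection.
#' @param max_evalue threshold for the full-database scan (default 1e-5).
#' @param compositions composition table.
#' @return list with `extras` (tibble `gene_id`, `family`, `motif_id`,
#'   `n_extra`) and `sharing` (tibble `family`, `motif_id`, `n_species`).
#' @export
catalog_additional_domains <- function(homologs, proteome, motif_db,
                                       max_evalue = 1e-5,
                                       compositions = family_compositions()) {
  hits <- annotate_domains(distinct(homologs, .data$gene_id), proteome,
                           motif_db, max_evalue = max_evalue)
  have <- hits |> count(.data$gene_id, .data$motif_id, name = "found")
  req <- compositions |> count(.data$family, .data$motif_id, name = "required")
  extras <- homologs |>
    distinct(.data$gene_id, .data$species_id, .data$family) |>
    left_join(have, by = "gene_id", relationship = "many-to-many") |>
    filter(!is.na(.data$motif_id)) |>
    left_join(req, by = c("family", "motif_id")) |>
    mutate(n_extra = .data$found - dplyr::coalesce(.data$required, 0L)) |>
    filter(.data$n_extra > 0)
  sharing <- extras |>
    group_by(.data$family, .data$motif_id) |>
    summarise(n_species = dplyr::n_distinct(.data$species_id), .groups = "drop")
  list(
    extras = select(extras, "gene_id", "family", "motif_id", "n_extra"),
    sharing = sharing
  )
}

#' Down-sample homologs to one species per taxonomic group
#'
#' Picks one species uniformly at random in each group, plus one species
#' per antimicrobial-peptide-resistant genus, plus all `forced_species`;
#' every homolog of a selected species is kept.
#'
#' @param homologs output of [filter_by_composition()].
#' @param taxonomy tibble with `species_id`, `clade`, `genus`, `resistant`.
#' @param group_col taxonomy column defining the groups (default `"clade"`).
#' @param forced_species species always included.
#' @param seed integer seed; same seed, same selection.
#' @return homologs of the selected species, with attribute
#'   `selected_species`.
#' @export
sample_set <- function(homologs, taxonomy, group_col = "clade",
                       forced_species = character(), seed = 1) {
  taxonomy <- as_tibble(taxonomy)
  carriers <- unique(homologs$species_id)
  with_seed(derive_seed(seed, "sample_set"), {
    pick_one <- function(pool) pool[sample(rep(seq_along(pool), 2), 1)]
    groups <- sort(unique(taxonomy[[group_col]]))
    picked <- character()
    for (g in groups) {
      pool <- sort(intersect(taxonomy$species_id[taxonomy[[group_col]] == g], carriers))
      if (length(pool) == 0) {
        warning("group '", g, "' has no species with homologs; skipped")
        next
      }
      picked <- c(picked, pick_one(pool))
    }
    res_genera <- sort(unique(taxonomy$genus[taxonomy$resistant == 1]))
    for (g in res_genera) {
      pool <- sort(intersect(taxonomy$species_id[taxonomy$genus == g], carriers))
      if (length(pool) > 0) picked <- c(picked, pick_one(pool))
    }
    selected <- sort(unique(c(picked, forced_species)))
    out <- filter(homologs, .data$species_id %in% selected)
    attr(out, "selected_species") <- selected
    out
  })
}
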