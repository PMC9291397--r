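# Distance of each bacterium to its closest eukaryotic homolog, under three
# metrics: dist_E (sum of branch lengths on the gene tree), dist_T (number
# of internal nodes separating the leaves) and dist_S (log10 E-value of the
# best local alignment against the eukaryotic homolog set). Species with
# several homologs contribute their minimum. top-k / pan-top-k then select
# donor-candidate bacteria, and a one-sided rank test compares resistant
# against other bacteria.

#' Branch-length distance between two leaves
#'
#' @param tree `phylo` with branch lengths.
#' @param leaf_a,leaf_b leaf labels.
#' @return sum of branch lengths on the unique path (0 iff same leaf).
#' @export
evolutionary_distance <- function(tree, leaf_a, leaf_b) {
  if (leaf_a == leaf_b) {
    if (!leaf_a %in% tree$tip.label) stop("leaf not in tree: ", leaf_a)
    return(0)
  }
  path <- leaf_path_nodes(tree, leaf_a, leaf_b)
  elen <- setNames(tree$edge.length, tree$edge[, 2])
  mrca <- path[which.max(node_depth_rank(tree, path))]
  sum(elen[as.character(setdiff(path, mrca))])
}

# helper: rank nodes by closeness to root so the path's MRCA is identifiable
node_depth_rank <- function(tree, nodes) {
  d <- node_depths_topological(tree)
  -d[nodes]
}

node_depths_topological <- function(tree) {
  t2 <- tree
  t2$edge.length <- rep(1, nrow(tree$edge))
  node_depths(t2)
}

#' Topological distance between two leaves
#'
#' The number of internal nodes on the simple path between the leaves
#' (cherry partners are separated by exactly one).
#'
#' @inheritParams evolutionary_distance
#' @return integer count (0 iff same leaf).
#' @export
topological_distance <- function(tree, leaf_a, leaf_b) {
  if (leaf_a == leaf_b) {
    if (!leaf_a %in% tree$tip.label) stop("leaf not in tree: ", leaf_a)
    return(0L)
  }
  path <- leaf_path_nodes(tree, leaf_a, leaf_b)
  length(path) - 2L
}

#' Similarity distance of a bacterial sequence to a eukaryotic homolog set
#'
#' Local alignment of the bacterial sequence against every eukaryotic
#' homolog; the distance is log10 of the smallest E-value.
#'
#' @param bacterial_seq amino-acid string.
#' @param eukaryote_seqs named character vector (nonempty).
#' @param max_evalue detectability floor: if no alignment reaches this
#'   E-value the record is marked missing (`NA`). The default (1e-3) sits
#'   well below random-alignment noise, so unrelated sequences come back
#'   missing and reported distances satisfy dist_S < 0.
#' @return one-row tibble: `dist_S` (log10 E-value, `NA` if missing),
#'   `closest` (eukaryote id or `NA`).
#' @export
similarity_distance <- function(bacterial_seq, eukaryote_seqs, max_evalue = 1e-3) {
  stopifnot(length(eukaryote_seqs) > 0)
  h <- sw_hits(bacterial_seq, eukaryote_seqs) |>
    filter(.data$evalue <= max_evalue) |>
    arrange(.data$evalue, .data$subject_id)
  if (nrow(h) == 0) {
    return(tibble(dist_S = NA_real_, closest = NA_character_))
  }
  tibble(dist_S = log10(h$evalue[1]), closest = h$subject_id[1])
}

#' Per-bacterium proximity records for one family's gene tree
#'
#' For every bacterial species with a homolog on the tree, the minimum
#' distance to any eukaryotic homolog under each metric, with the closest
#' eukaryotic gene per metric (ties broken by lexicographic id).
#'
#' @param tree the family's gene tree (`phylo`, leaves = gene ids).
#' @param annotations tibble `gene_id`, `species_id`, `domain_of_life`
#'   (and anything else, carried through joins elsewhere).
#' @param proteome tibble `gene_id`, `sequence`; needed for `dist_S`
#'   (pass `NULL` to skip the similarity metric).
#' @param family family name stamped on the records.
#' @param reduce `"species"` (default: one record per bacterial species,
#'   the minimum over its homologs) or `"homolog"` (one per bacterial gene).
#' @return tibble of proximity records: `species_id`, `family`, `dist_E`,
#'   `closest_E`, `dist_T`, `closest_T`, `dist_S`, `closest_S` (and
#'   `gene_id` when `reduce = "homolog"`). Metrics that cannot be computed
#'   are `NA`, never imputed.
#' @export
proximity_records <- function(tree, annotations, proteome = NULL,
                              family = NA_character_,
                              reduce = c("species", "homolog")) {
  reduce <- match.arg(reduce)
  annotations <- as_tibble(annotations)
  ann <- filter(annotations, .data$gene_id %in% tree$tip.label)
  euk <- filter(ann, .data$domain_of_life == "Eukaryota")
  bac <- filter(ann, .data$domain_of_life == "Bacteria")
  if (nrow(euk) == 0) stop("tree has no eukaryotic leaves")
  if (nrow(bac) == 0) {
    return(tibble(species_id = character(), family = character(),
                  dist_E = numeric(), closest_E = character(),
                  dist_T = numeric(), closest_T = character(),
                  dist_S = numeric(), closest_S = character()))
  }

  dE <- ape::cophenetic.phylo(tree)
  tT <- tree
  tT$edge.length <- rep(1, nrow(tree$edge))
  dT <- ape::cophenetic.phylo(tT) - 1  # edges - 1 = internal nodes on path

  euk_ids <- sort(euk$gene_id)
  per_gene <- purrr::map_dfr(seq_len(nrow(bac)), function(i) {
    g <- bac$gene_id[i]
    e_row <- dE[g, euk_ids]
    t_row <- dT[g, euk_ids]
    iE <- order(e_row, euk_ids)[1]
    iT <- order(t_row, euk_ids)[1]
    out <- tibble(
      gene_id = g, species_id = bac$species_id[i], family = family,
      dist_E = unname(e_row[iE]), closest_E = euk_ids[iE],
      dist_T = unname(t_row[iT]), closest_T = euk_ids[iT],
      dist_S = NA_real_, closest_S = NA_character_
    )
    if (!is.null(proteome)) {
      seqs <- setNames(
        proteome$sequence[match(euk_ids, proteome$gene_id)], euk_ids
      )
      s <- similarity_distance(
        proteome$sequence[match(g, proteome$gene_id)], seqs
      )
      out$dist_S <- s$dist_S
      out$closest_S <- s$closest
    }
    out
  })
  if (reduce == "homolog") return(per_gene)

  min_by <- function(df, metric, closest) {
    df <- df[!is.na(df[[metric]]), ]
    if (nrow(df) == 0) {
      return(tibble("{metric}" := NA_real_, "{closest}" := NA_character_))
    }
    i <- order(df[[metric]], df[[closest]])[1]
    tibble("{metric}" := df[[metric]][i], "{closest}" := df[[closest]][i])
  }
  per_gene |>
    group_by(.data$species_id) |>
    dplyr::group_modify(function(df, key) {
      bind_cols(
        min_by(df, "dist_E", "closest_E"),
        min_by(df, "dist_T", "closest_T"),
        min_by(df, "dist_S", "closest_S")
      )
    }) |>
    ungroup() |>
    mutate(family = family) |>
    select("species_id", "family", dplyr::everything()) |>
    arrange(.data$species_id)
}

#' Closest eukaryotic homolog of one bacterial species
#'
#' @inheritParams proximity_records
#' @param species_id bacterial species id.
#' @param metric `"dist_E"`, `"dist_T"` or `"dist_S"`.
#' @return one-row tibble `distance`, `closest`; zero rows if the species
#'   has no homolog on the tree.
#' @export
closest_eukaryote <- function(tree, annotations, species_id,
                              metric = c("dist_E", "dist_T", "dist_S"),
                              proteome = NULL) {
  metric <- match.arg(metric)
  rec <- proximity_records(tree, annotations, proteome = proteome)
  rec <- rec[rec$species_id == species_id, ]
  if (nrow(rec) == 0) {
    return(tibble(distance = numeric(), closest = character()))
  }
  closest_col <- sub("dist", "closest", metric)
  tibble(distance = rec[[metric]], closest = rec[[closest_col]])
}

#' Top-k bacteria closest to their eukaryotic homologs
#'
#' @param records proximity records ([proximity_records()]).
#' @param family family to rank.
#' @param metric `"dist_E"`, `"dist_T"` or `"dist_S"`.
#' @param k number of species to keep (all if fewer; default 200, the
#'   published cut).
#' @return character vector of species ids, deterministically tie-broken
#'   by id.
#' @export
top_k <- function(records, family, metric, k = 200) {
  rec <- records[records$family == family & !is.na(records[[metric]]), ]
  rec <- rec[order(rec[[metric]], rec$species_id), ]
  head(rec$species_id, k)
}

#' Pan-top-k: union of the per-metric top-k sets
#'
#' @inheritParams top_k
#' @param metrics metrics to combine (those absent from the records are
#'   skipped).
#' @return sorted character vector of species ids; size between k_eff and
#'   `3 * k_eff`.
#' @export
pan_top_k <- function(records, family, k = 200,
                      metrics = c("dist_E", "dist_T", "dist_S")) {
  metrics <- intersect(metrics, names(records))
  avail <- metrics[vapply(metrics, function(m) {
    any(!is.na(records[[m]][records$family == family]))
  }, logical(1))]
  if (length(avail) == 0) stop("no metric available for family ", family)
  sort(unique(unlist(lapply(avail, function(m) top_k(records, family, m, k)))))
}

#' Compare proximity of resistant vs other bacteria within a clade
#'
#' One-sided Wilcoxon rank-sum test of the hypothesis that
#' antimicrobial-peptide-resistant bacteria lie closer to their eukaryotic
#' homologs than the other bacteria of the same clade, with a rank-biserial
#' effect size (positive = resistant closer).
#'
#' @param records proximity records.
#' @param taxonomy tibble `species_id`, `clade`, `resistant`.
#' @param family family to test.
#' @param metric which distance to compare.
#' @param clade restrict to one clade (default: all bacteria with records).
#' @return a `resistance_test` object; see [tidy()] / [glance()].
#' @export
compare_resistant <- function(records, taxonomy, family,
                              metric = c("dist_E", "dist_T", "dist_S"),
                              clade = NULL) {
  metric <- match.arg(metric)
  rec <- records[records$family == family, ]
  rec <- left_join(rec, select(as_tibble(taxonomy), "species_id", "clade",
                               "resistant"), by = "species_id")
  if (!is.null(clade)) rec <- rec[rec$clade == clade, ]
  rec <- rec[!is.na(rec[[metric]]), ]
  x <- rec[[metric]][rec$resistant == 1]
  y <- rec[[metric]][rec$resistant == 0]
  out <- list(
    family = family, metric = metric, clade = clade %||% NA_character_,
    n_resistant = length(x), n_other = length(y),
    computable = length(x) >= 2 && length(y) >= 2,
    statistic = NA_real_, p_value = NA_real_, effect = NA_real_
  )
  if (out$computable) {
    wt <- suppressWarnings(wilcox.test(x, y, alternative = "less"))
    out$statistic <- unname(wt$statistic)
    out$p_value <- wt$p.value
    # rank-biserial: positive when resistant distances are smaller
    out$effect <- 1 - 2 * unname(wt$statistic) / (length(x) * length(y))
  }
  structure(out, class = "resistance_test")
}

#' @export
print.resistance_test <- function(x, ...) {
  cat("Resistant-vs-other proximity (", x$family, ", ", x$metric,
      if (!is.na(x$clade)) paste0(", clade ", x$clade), "): ", sep = "")
  if (!x$computable) {
    cat("not computable (n_resistant = ", x$n_resistant,
        ", n_other = ", x$n_other, ")\n", sep = "")
  } else {
    cat(sprintf("W = %.1f, one-sided p = %.4g, rank-biserial = %.3f (n = %d vs %d)\n",
                x$statistic, x$p_value, x$effect, x$n_resistant, x$n_other))
  }
  invisible(x)
}

#' @export
tidy.resistance_test <- function(x, ...) {
  tibble(
    family = x$family, metric = x$metric, clade = x$clade,
    statistic = x$statistic, p_value = x$p_value, effect = x$effect,
    n_resistant = x$n_resistant, n_other = x$n_other,
    computable = x$computable
  )
}

#' @export
glance.resistance_test <- function(x, ...) tidy(x)
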