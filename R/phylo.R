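# Motif-concatenated alignments and the tree operations the analysis rests
# on: neighbor-joining inference, midpoint rooting, monophyly testing,
# group collapsing and misclassification counting.

#' Concatenated motif alignment for a family's homologs
#'
#' Extracts each required motif instance from every homolog (using the
#' annotated coordinates), aligns the instances of each motif against the
#' longest instance, and concatenates the per-motif alignments in
#' composition order. Homologs missing a required motif are excluded with a
#' warning. A motif subset can be selected (e.g. only the two blocks shared
#' across the M16 subfamilies, for the combined tree).
#'
#' @param homologs tibble with `gene_id` (one row per homolog; extra
#'   columns ignored).
#' @param domain_hits [annotate_domains()] output covering those genes.
#' @param proteome tibble `gene_id`, `sequence`.
#' @param composition composition rows for this family (or the shared
#'   subset): tibble with `motif_id`, repeats meaning multiple instances.
#' @param motifs optional character vector restricting the motif subset.
#' @return named character vector of aligned rows (equal widths), with
#'   attribute `boundaries`: tibble `motif_id`, `instance`, `start`, `end`
#'   of each motif segment in alignment coordinates.
#' @export
align_family_motifs <- function(homologs, domain_hits, proteome,
                                composition, motifs = NULL) {
  req <- composition$motif_id
  if (!is.null(motifs)) req <- req[req %in% motifs]
  if (length(req) == 0) stop("empty motif subset")
  need <- table(req)
  genes <- unique(homologs$gene_id)
  proteome <- as_tibble(proteome)

  # per gene, per motif: instances ordered by coordinate
  inst <- domain_hits |>
    filter(.data$gene_id %in% genes, .data$motif_id %in% names(need)) |>
    arrange(.data$gene_id, .data$motif_id, .data$start) |>
    group_by(.data$gene_id, .data$motif_id) |>
    mutate(instance = row_number()) |>
    ungroup()

  ok <- vapply(genes, function(g) {
    h <- inst[inst$gene_id == g, ]
    all(vapply(names(need), function(m) {
      sum(h$motif_id == m) >= need[[m]]
    }, logical(1)))
  }, logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " homolog(s) missing a required motif; excluded: ",
            paste(head(genes[!ok], 5), collapse = ", "),
            if (sum(!ok) > 5) ", ..." else "")
  }
  genes <- genes[ok]
  if (length(genes) == 0) stop("no homolog carries the full motif set")

  slots <- tibble(motif_id = req) |>
    group_by(.data$motif_id) |>
    mutate(instance = row_number()) |>
    ungroup()

  seqs <- setNames(proteome$sequence[match(genes, proteome$gene_id)], genes)
  pieces <- purrr::pmap(slots, function(motif_id, instance) {
    sub <- inst |>
      filter(.data$motif_id == !!motif_id, .data$instance == !!instance,
             .data$gene_id %in% genes)
    sub <- sub[match(genes, sub$gene_id), ]
    x <- substr(seqs[genes], sub$start, sub$end)
    names(x) <- genes
    ref <- x[[which.max(nchar(x))]]
    align_to_reference(x, ref)
  })
  widths <- vapply(pieces, function(p) nchar(p[[1]]), integer(1))
  rows <- vapply(genes, function(g) {
    paste(vapply(pieces, function(p) p[[g]], character(1)), collapse = "")
  }, character(1))
  boundaries <- mutate(slots,
    end = cumsum(widths), start = .data$end - widths + 1L
  )[, c("motif_id", "instance", "start", "end")]
  attr(rows, "boundaries") <- boundaries
  rows
}

# Poisson-corrected pairwise distance between aligned rows
alignment_distances <- function(alignment) {
  mat <- do.call(rbind, strsplit(unname(alignment), ""))
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  valid <- matrix(mat %in% AA_ALPHABET, nrow = n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- valid[i, ] & valid[j, ]
      if (!any(shared)) {
        p <- NA_real_
      } else {
        p <- mean(mat[i, shared] != mat[j, shared])
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  # Poisson correction, capped below saturation
  dc <- -log(pmax(1 - d, 0.05))
  dc[is.na(dc)] <- max(dc, na.rm = TRUE)
  diag(dc) <- 0
  dc
}

#' Infer a gene tree from a concatenated motif alignment
#'
#' Default inference is neighbor joining on Poisson-corrected pairwise
#' distances — deterministic, with no external dependencies. An external
#' approximate-maximum-likelihood tool can be plugged in through `method`:
#' pass a function taking the alignment and returning a `phylo` (supports,
#' if present as node labels, are carried through).
#'
#' @param alignment named character vector of equal-width aligned rows, or
#'   a pairwise distance matrix (dimnames = leaf ids).
#' @param method `"nj"` (default) or a function `alignment -> phylo`.
#' @return unrooted `phylo` with branch lengths (negative NJ estimates
#'   clamped to 0); node-label supports carried when the method provides
#'   them.
#' @export
infer_tree <- function(alignment, method = "nj") {
  if (is.function(method)) return(method(alignment))
  stopifnot(identical(method, "nj"))
  d <- if (is.matrix(alignment)) alignment else alignment_distances(alignment)
  if (nrow(d) < 3) stop("tree inference needs at least 3 sequences")
  tree <- ape::nj(stats::as.dist(d))
  tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

#' Midpoint-root a tree
#'
#' Places the root halfway along the longest leaf-to-leaf path. The two
#' diameter endpoints end up equidistant from the root (within 1e-9);
#' already-midpoint-rooted trees are returned unchanged (idempotent).
#'
#' @param tree a `phylo` with branch lengths.
#' @return rooted `phylo`.
#' @export
midpoint_root <- function(tree) {
  if (is.null(tree$edge.length)) stop("midpoint rooting needs branch lengths")
  if (all(tree$edge.length == 0)) {
    warning("all branch lengths are zero; rooting at an arbitrary node")
    return(ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE))
  }
  phangorn::midpoint(tree)
}

#' Test whether a leaf set is monophyletic
#'
#' @param tree rooted `phylo`.
#' @param leaves nonempty character vector of leaf labels.
#' @return logical; attribute `clade` holds the leaf set of the smallest
#'   clade containing `leaves` (equal to `leaves` iff monophyletic).
#' @export
is_monophyletic <- function(tree, leaves) {
  stopifnot(length(leaves) > 0)
  missing <- setdiff(leaves, tree$tip.label)
  if (length(missing) > 0) {
    stop("leaf not in tree: ", paste(missing, collapse = ", "))
  }
  idx <- match(leaves, tree$tip.label)
  node <- if (length(idx) == 1) idx else ape::getMRCA(tree, idx)
  clade <- tree$tip.label[phangorn::Descendants(tree, node, "tips")[[1]]]
  structure(setequal(clade, leaves), clade = sort(clade))
}

#' Collapse maximal single-group clades to pseudo-leaves
#'
#' Every maximal clade whose leaves all carry the same group label becomes
#' one pseudo-leaf labeled `group|n` (n = number of collapsed leaves).
#' Pseudo-leaf counts always sum to the original leaf count, and leaves of
#' different groups are never merged.
#'
#' @param tree rooted `phylo`.
#' @param groups named character vector: leaf label -> group.
#' @return list: `tree` (collapsed `phylo`), `leaves` (tibble `label`,
#'   `group`, `n_leaves`).
#' @export
collapse_by_group <- function(tree, groups) {
  unlabeled <- setdiff(tree$tip.label, names(groups))
  if (length(unlabeled) > 0) {
    stop("unlabeled leaves: ", paste(head(unlabeled, 5), collapse = ", "))
  }
  n_tip <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, seq_len(n_tip + tree$Nnode), "tips")
  grp <- function(node) {
    g <- unique(groups[tree$tip.label[desc[[node]]]])
    if (length(g) == 1) g else NA_character_
  }
  node_grp <- vapply(seq_len(n_tip + tree$Nnode), grp, character(1))
  parent <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- n_tip + 1L
  maximal <- which(!is.na(node_grp) &
                     (seq_along(node_grp) == root | is.na(node_grp[pmax(parent, 1)])))

  keep <- integer()
  labels <- character()
  meta <- list()
  for (node in maximal) {
    tips <- desc[[node]]
    rep_tip <- tips[1]
    keep <- c(keep, rep_tip)
    lab <- sprintf("%s|%d", node_grp[node], length(tips))
    labels <- c(labels, lab)
    meta[[length(meta) + 1L]] <- tibble(
      label = lab, group = node_grp[node], n_leaves = length(tips)
    )
  }
  collapsed <- ape::keep.tip(tree, keep)
  collapsed$tip.label <- labels[match(collapsed$tip.label, tree$tip.label[keep])]
  list(tree = collapsed, leaves = bind_rows(meta))
}

#' Count misclassified homologs on a family-labeled tree
#'
#' Each family's core clade is the clade maximizing the F1 score between
#' the clade's leaf set and the family's leaf set (a reproducible criterion
#' for what is identified visually on published trees; ties broken toward
#' the smaller clade, then the lower node id). A family member outside its
#' core clade is misclassified; leaves of other families inside the core
#' clade are reported as foreign.
#'
#' @param tree rooted `phylo`.
#' @param labels named character vector: leaf label -> family.
#' @return tibble: `family`, `n_leaves`, `core_size`, `f1`,
#'   `misclassified`, `foreign`.
#' @export
count_misclassified <- function(tree, labels) {
  unlabeled <- setdiff(tree$tip.label, names(labels))
  if (length(unlabeled) > 0) {
    stop("unlabeled leaves: ", paste(head(unlabeled, 5), collapse = ", "))
  }
  n_tip <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, seq_len(n_tip + tree$Nnode), "tips")
  leaf_fam <- labels[tree$tip.label]
  purrr::map_dfr(sort(unique(leaf_fam)), function(fam) {
    fam_tips <- which(leaf_fam == fam)
    stats <- vapply(desc, function(tips) {
      inter <- sum(tips %in% fam_tips)
      c(f1 = 2 * inter / (length(tips) + length(fam_tips)), size = length(tips))
    }, numeric(2))
    best <- order(-stats["f1", ], stats["size", ], seq_len(ncol(stats)))[1]
    core <- desc[[best]]
    tibble(
      family = fam,
      n_leaves = length(fam_tips),
      core_size = length(core),
      f1 = stats["f1", best],
      misclassified = sum(!(fam_tips %in% core)),
      foreign = sum(!(core %in% fam_tips))
    )
  })
}
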