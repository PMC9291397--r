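# Labeled species-tree simulation.
#
# Clades are grown as ultrametric Yule subtrees and grafted monophyletically
# onto a domain-of-life backbone (Bacteria,(Archaea,Eukaryota)), so clade and
# domain monophyly hold by construction and downstream monophyly tests have
# exact ground truth. The final tree is scaled to unit root-to-tip depth;
# all simulation times are expressed in these units (root = 0, tips = 1).

CLADE_HEIGHT <- 0.3

#' Simulate a labeled species tree
#'
#' @param clade_plan data frame with one row per clade: `clade` (name),
#'   `domain_of_life` (`"Bacteria"`, `"Eukaryota"` or `"Archaea"`),
#'   `n_species` (>= 1) and optionally `resistant_fraction` in `[0, 1]`
#'   (antimicrobial-peptide resistance; only meaningful — and only allowed
#'   to be nonzero — for bacterial clades).
#' @param seed integer seed; identical plan + seed gives an identical tree.
#' @param genus_size target number of species per genus within a clade.
#'   Resistance is a genus-level flag: whole genera are marked resistant
#'   until the clade's resistant species fraction reaches the plan's target.
#' @return an object of class `egt_species_tree`: a list with `tree` (a
#'   rooted, binary, ultrametric `phylo` with internal node labels
#'   `N1, N2, ...`) and `taxonomy` (tibble: `species_id`, `domain_of_life`,
#'   `clade`, `genus`, `resistant`).
#' @examples
#' plan <- tibble::tibble(
#'   clade = c("alpha", "plants"),
#'   domain_of_life = c("Bacteria", "Eukaryota"),
#'   n_species = c(4, 3),
#'   resistant_fraction = c(0.5, 0)
#' )
#' st <- simulate_species_tree(plan, seed = 1)
#' st$taxonomy
#' @export
simulate_species_tree <- function(clade_plan, seed = 1, genus_size = 3) {
  clade_plan <- as_tibble(clade_plan)
  if (!all(c("clade", "domain_of_life", "n_species") %in% names(clade_plan))) {
    stop("`clade_plan` needs columns clade, domain_of_life, n_species")
  }
  if (!"resistant_fraction" %in% names(clade_plan)) {
    clade_plan$resistant_fraction <- 0
  }
  if (any(clade_plan$n_species < 1)) {
    stop("every clade must contain at least one species")
  }
  if (any(clade_plan$resistant_fraction < 0 | clade_plan$resistant_fraction > 1)) {
    stop("resistant_fraction must lie in [0, 1]")
  }
  bad <- clade_plan$resistant_fraction > 0 & clade_plan$domain_of_life != "Bacteria"
  if (any(bad)) {
    stop(
      "resistant_fraction must be 0 outside Bacteria (offending clade: ",
      clade_plan$clade[which(bad)[1]], ")"
    )
  }
  if (anyDuplicated(clade_plan$clade)) stop("clade names must be unique")

  with_seed(derive_seed(seed, "species_tree"), {
    sub <- purrr::pmap(clade_plan, function(clade, domain_of_life, n_species, ...) {
      clade_subtree(clade, n_species)
    })
    names(sub) <- clade_plan$clade

    # join clades within each domain, then domains on a fixed backbone
    domains <- split(sub, clade_plan$domain_of_life)
    dom_heights <- function(k) sort(runif(k, 0.40, 0.70))
    joined <- purrr::map(domains, function(xs) coalesce_subtrees(xs, dom_heights))
    order_pref <- intersect(c("Bacteria", "Archaea", "Eukaryota"), names(joined))
    joined <- joined[order_pref]
    if (length(joined) == 3) {
      ae <- merge_two(joined[["Archaea"]], joined[["Eukaryota"]], 0.85)
      root <- merge_two(joined[["Bacteria"]], ae, 1.0)
    } else if (length(joined) == 2) {
      root <- merge_two(joined[[1]], joined[[2]], 1.0)
    } else {
      root <- joined[[1]]
    }

    tree <- ape::read.tree(text = paste0(root$nwk, ";"))
    # unit depth
    d <- node_depths(tree)
    tree$edge.length <- tree$edge.length / max(d[seq_along(tree$tip.label)])
    tree <- ape::makeNodeLabel(tree, method = "number", prefix = "N")

    taxonomy <- purrr::pmap_dfr(
      clade_plan,
      function(clade, domain_of_life, n_species, resistant_fraction, ...) {
        ids <- species_ids(clade, n_species)
        genus <- sprintf("%s_gen%d", clade, ((seq_len(n_species) - 1L) %/% genus_size) + 1L)
        resistant <- rep(0L, n_species)
        target <- round(resistant_fraction * n_species)
        if (target > 0) {
          for (g in sample(unique(genus))) {
            if (sum(resistant) >= target) break
            resistant[genus == g] <- 1L
          }
        }
        tibble(
          species_id = ids, domain_of_life = domain_of_life,
          clade = clade, genus = genus, resistant = resistant
        )
      }
    )
    structure(list(tree = tree, taxonomy = taxonomy), class = "egt_species_tree")
  })
}

species_ids <- function(clade, n) sprintf("%s_%02d", clade, seq_len(n))

# returns list(nwk = newick string without ";", height = subtree height)
clade_subtree <- function(clade, n) {
  ids <- species_ids(clade, n)
  if (n == 1) {
    return(list(nwk = ids, height = 0))
  }
  t <- ape::rphylo(n, birth = 1, death = 0)
  d <- node_depths(t)
  t$edge.length <- t$edge.length * CLADE_HEIGHT / max(d[seq_len(n)])
  t$tip.label <- ids[as.integer(sub("^t", "", t$tip.label))]
  list(nwk = sub(";$", "", ape::write.tree(t)), height = CLADE_HEIGHT)
}

merge_two <- function(a, b, h) {
  list(
    nwk = sprintf("(%s:%s,%s:%s)", a$nwk, format(h - a$height, digits = 15),
                  b$nwk, format(h - b$height, digits = 15)),
    height = h
  )
}

# random sequential coalescence of subtrees at increasing heights
coalesce_subtrees <- function(xs, height_fun) {
  while (length(xs) > 1) {
    hs <- height_fun(length(xs) - 1)
    for (h in hs) {
      pick <- sample(length(xs), 2)
      merged <- merge_two(xs[[pick[1]]], xs[[pick[2]]], max(h, max(
        xs[[pick[1]]]$height, xs[[pick[2]]]$height
      ) + 1e-6))
      xs <- c(xs[-pick], list(merged))
    }
  }
  xs[[1]]
}

#' @export
print.egt_species_tree <- function(x, ...) {
  tax <- x$taxonomy
  cat(
    "Simulated species tree: ", nrow(tax), " species (",
    sum(tax$domain_of_life == "Bacteria"), " bacteria, ",
    sum(tax$domain_of_life == "Eukaryota"), " eukaryotes, ",
    sum(tax$domain_of_life == "Archaea"), " archaea), ",
    dplyr::n_distinct(tax$clade), " clades, ",
    sum(tax$resistant), " AMP-resistant species\n",
    sep = ""
  )
  invisible(x)
}
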