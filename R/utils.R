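# Shared helpers: amino-acid alphabet, derived RNG streams, tree bookkeeping.

AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Derive a reproducible child seed from a root seed and a label
#'
#' One root seed drives the whole simulation; each family / stage hashes its
#' label into an independent stream so adding a family never perturbs the
#' streams of the others. Kept below 2^31 - 1 so it is always a valid R seed.
#'
#' @param seed integer root seed.
#' @param label character scalar naming the stream.
#' @return integer seed.
#' @keywords internal
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 131 + 17) %% 2147483647L)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_aa <- function(n) {
  paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
}

#' Node depths (time from the root) for every node of a rooted tree
#' @keywords internal
node_depths <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  depth <- numeric(n_tip + tree$Nnode)
  edge <- tree$edge
  # edges of a phylo are not guaranteed preorder; iterate until stable
  ord <- order(match(edge[, 1], c(root, sort(unique(edge[, 2])))))
  remaining <- seq_len(nrow(edge))
  done <- rep(FALSE, n_tip + tree$Nnode)
  done[root] <- TRUE
  while (length(remaining) > 0) {
    ready <- remaining[done[edge[remaining, 1]]]
    if (length(ready) == 0) stop("tree edges do not form a rooted tree")
    depth[edge[ready, 2]] <- depth[edge[ready, 1]] + tree$edge.length[ready]
    done[edge[ready, 2]] <- TRUE
    remaining <- setdiff(remaining, ready)
  }
  depth
}

#' Path between two leaves as a vector of node ids (inclusive)
#' @keywords internal
leaf_path_nodes <- function(tree, a, b) {
  n_tip <- length(tree$tip.label)
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  if (is.na(ia) || is.na(ib)) {
    stop("leaf not in tree: ", paste(setdiff(c(a, b), tree$tip.label), collapse = ", "))
  }
  parent <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  anc <- function(i) {
    out <- i
    while (parent[i] != 0) {
      i <- parent[i]
      out <- c(out, i)
    }
    out
  }
  pa <- anc(ia)
  pb <- anc(ib)
  mrca <- pa[pa %in% pb][1]
  c(pa[seq_len(match(mrca, pa))], rev(pb[seq_len(match(mrca, pb) - 1L)]))
}

assert_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x != round(x)) {
    stop("`", name, "` must be a single non-negative integer", call. = FALSE)
  }
}
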