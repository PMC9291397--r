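# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_species_tree <- function() {
  cached("species_tree", simulate_species_tree(default_clade_plan(), seed = 1))
}

# noisy default fixture (0.3 subst/site, 5% block loss), seed 42
noisy_fixture <- function() {
  cached("noisy_fixture", suppressWarnings(simulate_fixture(seed = 42)))
}

# zero-divergence fixture: no substitutions, no block loss
clean_fixture <- function() {
  cached("clean_fixture", suppressWarnings(simulate_fixture(
    seed = 42, subst_rate = 0,
    family_specs = default_family_specs(block_loss_prob = 0)
  )))
}

noisy_reconstruction <- function() {
  cached("noisy_reconstruction", {
    fx <- noisy_fixture()
    reconstruct_families(fx$proteome, fx$references, fx$species_tree,
                         fx$motif_models, fx$compositions)
  })
}

clean_reconstruction <- function() {
  cached("clean_reconstruction", {
    fx <- clean_fixture()
    reconstruct_families(fx$proteome, fx$references, fx$species_tree,
                         fx$motif_models, fx$compositions)
  })
}

# random amino-acid sequence
rand_seq <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), n, replace = TRUE),
        collapse = "")
}

# random tree with positive branch lengths and unique labels
rand_tree <- function(n_leaves) {
  tr <- ape::rtree(n_leaves)
  tr$tip.label <- sprintf("t%03d", seq_len(n_leaves))
  tr
}

# breadth-first path-sum oracle for leaf-to-leaf distances on a phylo
path_oracle <- function(tree, a, b, weights = tree$edge.length) {
  g <- tree_graph_paths(tree, weights)
  n_tip <- length(tree$tip.label)
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  path <- g$paths[[ia]][[ib]]
  list(nodes = path, length = g$dist[ia, ib])
}

# all-pairs shortest paths over the tree seen as an undirected graph,
# computed by brute-force breadth-first search (independent of the
# implementation under test)
tree_graph_paths <- function(tree, weights) {
  n <- length(tree$tip.label) + tree$Nnode
  adj <- vector("list", n)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; c <- tree$edge[i, 2]; w <- weights[i]
    adj[[p]] <- rbind(adj[[p]], c(c, w))
    adj[[c]] <- rbind(adj[[c]], c(p, w))
  }
  n_tip <- length(tree$tip.label)
  dist <- matrix(NA_real_, n_tip, n_tip)
  paths <- vector("list", n_tip)
  for (s in seq_len(n_tip)) {
    d <- rep(Inf, n); d[s] <- 0
    prev <- rep(NA_integer_, n)
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.null(adj[[v]])) for (k in seq_len(nrow(adj[[v]]))) {
        u <- adj[[v]][k, 1]; w <- adj[[v]][k, 2]
        if (d[v] + w < d[u] - 1e-12) {
          d[u] <- d[v] + w
          prev[u] <- v
          queue <- c(queue, u)
        }
      }
    }
    dist[s, ] <- d[seq_len(n_tip)]
    paths[[s]] <- lapply(seq_len(n_tip), function(t) {
      p <- t
      while (!is.na(prev[p[1]])) p <- c(prev[p[1]], p)
      p
    })
  }
  list(dist = dist, paths = paths)
}
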