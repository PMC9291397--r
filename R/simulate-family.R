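# Gene-family evolution along a species tree.
#
# A family starts as a single lineage on the stem edge of its origin group
# (by default Bacteria, so eukaryotes can only acquire it through a scripted
# endosymbiotic transfer). Lineages then evolve by a Gillespie process:
# duplication and loss anywhere, horizontal transfer restricted to
# bacteria -> bacteria, plus scripted EGT events (donor clade, recipient
# stem, absolute time). The full lineage genealogy is kept as time-stamped
# segments, so the extant gene tree, the event log and every downstream
# ground truth (EGT monophyly, copy-number expectations) drop out exactly.

#' Describe a peptidase family for simulation
#'
#' @param family_name one of the catalogued families (conventionally
#'   `"MPP"`, `"SPP"`, `"PreP"`, `"OOP"`, but any name is accepted).
#' @param domain_blocks ordered character vector of motif ids making up the
#'   protein (repeats allowed: the stromal processing peptidase carries its
#'   M16C-like block twice).
#' @param dup_rate,loss_rate duplication / loss events per unit branch length.
#' @param hgt_rate bacteria-to-bacteria transfer events per unit branch length.
#' @param egt_events data frame of scripted endosymbiotic transfers:
#'   `donor_clade`, `recipient` (clade name, domain of life or species id —
#'   the transfer lands on the stem edge above that group), `time` (absolute,
#'   root = 0; `NA` = midpoint of the recipient edge).
#' @param origin clade name or domain of life initially carrying the family.
#' @param core_rate_multiplier substitution-rate multiplier inside domain
#'   blocks, in `[0, 1]` relative to the base rate (conserved cores;
#'   0 freezes them completely).
#' @param linker_rate_multiplier multiplier (>= 1) in inter-block linkers.
#' @param block_loss_prob per-extant-gene, per-block probability that a
#'   domain block has been deleted (yields composition-filter negatives).
#' @return a `family_spec` list, validated.
#' @export
family_spec <- function(family_name, domain_blocks,
                        dup_rate = 0, loss_rate = 0, hgt_rate = 0,
                        egt_events = NULL, origin = "Bacteria",
                        core_rate_multiplier = 0.5,
                        linker_rate_multiplier = 1.5,
                        block_loss_prob = 0) {
  stopifnot(is.character(family_name), length(family_name) == 1)
  if (length(domain_blocks) == 0) stop("domain_blocks must be nonempty")
  if (any(c(dup_rate, loss_rate, hgt_rate) < 0)) stop("rates must be >= 0")
  if (core_rate_multiplier < 0 || core_rate_multiplier > 1) {
    stop("core_rate_multiplier must lie in [0, 1]")
  }
  if (linker_rate_multiplier < 1) stop("linker_rate_multiplier must be >= 1")
  if (core_rate_multiplier > linker_rate_multiplier) {
    stop("core_rate_multiplier must not exceed linker_rate_multiplier")
  }
  if (block_loss_prob < 0 || block_loss_prob > 1) stop("block_loss_prob in [0,1]")
  if (!is.null(egt_events)) {
    egt_events <- as_tibble(egt_events)
    stopifnot(all(c("donor_clade", "recipient") %in% names(egt_events)))
    if (!"time" %in% names(egt_events)) egt_events$time <- NA_real_
  }
  structure(
    list(
      family_name = family_name, domain_blocks = domain_blocks,
      dup_rate = dup_rate, loss_rate = loss_rate, hgt_rate = hgt_rate,
      egt_events = egt_events, origin = origin,
      core_rate_multiplier = core_rate_multiplier,
      linker_rate_multiplier = linker_rate_multiplier,
      block_loss_prob = block_loss_prob
    ),
    class = "family_spec"
  )
}

# species-tree bookkeeping shared by the simulator -------------------------

species_edge_table <- function(st) {
  tree <- st$tree
  n_tip <- length(tree$tip.label)
  d <- node_depths(tree)
  lab <- c(tree$tip.label, tree$node.label)
  desc <- phangorn::Descendants(tree, seq_len(n_tip + tree$Nnode), "tips")
  dom <- st$taxonomy$domain_of_life[match(tree$tip.label, st$taxonomy$species_id)]
  bacterial <- vapply(desc, function(t) all(dom[t] == "Bacteria"), logical(1))
  tibble(
    node = tree$edge[, 2],
    parent = tree$edge[, 1],
    t0 = d[tree$edge[, 1]],
    t1 = d[tree$edge[, 2]],
    label = lab[tree$edge[, 2]],
    is_tip = tree$edge[, 2] <= n_tip,
    bacterial = bacterial[tree$edge[, 2]]
  )
}

# species set named by a clade, domain of life, or single species id
resolve_species_set <- function(taxonomy, name) {
  if (name %in% taxonomy$clade) {
    taxonomy$species_id[taxonomy$clade == name]
  } else if (name %in% taxonomy$domain_of_life) {
    taxonomy$species_id[taxonomy$domain_of_life == name]
  } else if (name %in% taxonomy$species_id) {
    name
  } else {
    stop("unknown clade/domain/species: ", name, call. = FALSE)
  }
}

# the stem edge above the MRCA of a named group (edge id = child node id)
resolve_stem_edge <- function(st, name) {
  sp <- resolve_species_set(st$taxonomy, name)
  tree <- st$tree
  node <- if (length(sp) == 1) {
    match(sp, tree$tip.label)
  } else {
    ape::getMRCA(tree, sp)
  }
  if (node == length(tree$tip.label) + 1L) {
    stop("group '", name, "' spans the root and has no stem edge", call. = FALSE)
  }
  node
}

#' Simulate one gene family along a labeled species tree
#'
#' @param species_tree an `egt_species_tree` from [simulate_species_tree()].
#' @param fspec a [family_spec()].
#' @param seed integer seed.
#' @return an `egt_gene_family` list: `tree` (extant gene tree, `phylo`, or
#'   `NULL` if fewer than two genes survive), `genes` (tibble `gene_id`,
#'   `species_id`, `lineage`), `events` (the event log: `event_id`, `kind`
#'   in duplication/loss/hgt/egt/origin, `time`, `edge`, `donor_gene`,
#'   `donor_clade`, `new_genes`), and the spec itself.
#' @export
simulate_family <- function(species_tree, fspec, seed = 1) {
  stopifnot(inherits(species_tree, "egt_species_tree"), inherits(fspec, "family_spec"))
  edges <- species_edge_table(species_tree)
  origin_edge <- resolve_stem_edge(species_tree, fspec$origin)

  # validate scripted transfers up front
  egt <- fspec$egt_events
  if (!is.null(egt) && nrow(egt) > 0) {
    for (dc in egt$donor_clade) resolve_species_set(species_tree$taxonomy, dc)
    egt$edge <- vapply(egt$recipient, function(r) resolve_stem_edge(species_tree, r), integer(1))
    e0 <- edges$t0[match(egt$edge, edges$node)]
    e1 <- edges$t1[match(egt$edge, edges$node)]
    # default time: midpoint of the window where the recipient edge overlaps
    # the donor clade's existence (donor stem start .. present)
    d0 <- vapply(egt$donor_clade, function(dc) {
      stem <- resolve_stem_edge(species_tree, dc)
      edges$t0[match(stem, edges$node)]
    }, numeric(1))
    lo <- pmax(e0, d0)
    if (any(is.na(egt$time) & lo >= e1)) {
      stop("recipient edge ends before the donor clade exists; give an explicit EGT time")
    }
    egt$time <- ifelse(is.na(egt$time), (lo + e1) / 2, egt$time)
    if (any(egt$time <= e0 | egt$time >= e1)) {
      stop("scripted EGT time falls outside its recipient edge")
    }
    egt <- egt[order(egt$time), ]
  }

  with_seed(derive_seed(seed, paste0("family_", fspec$family_name)), {
    sim <- new.env(parent = emptyenv())
    sim$seg <- list()
    sim$events <- list()

    new_seg <- function(parent, t0, edge) {
      id <- length(sim$seg) + 1L
      sim$seg[[id]] <- list(
        parent = parent, t0 = t0, t1 = NA_real_, edge = edge,
        fate = NA_character_, children = integer()
      )
      id
    }
    log_event <- function(kind, time, edge, donor_gene = NA, donor_clade = NA, new_genes = integer()) {
      sim$events[[length(sim$events) + 1L]] <- list(
        kind = kind, time = time,
        edge = edges$label[match(edge, edges$node)],
        donor_gene = donor_gene, donor_clade = donor_clade,
        new_genes = new_genes
      )
    }

    child_edges <- function(node) edges$node[edges$parent == node]

    # run one segment forward from its start until loss, event split, or the
    # end of its species-tree edge; pushes continuation segments onto `todo`
    extend <- function(id, todo) {
      s <- sim$seg[[id]]
      row <- match(s$edge, edges$node)
      on_bact <- edges$bacterial[row]
      rate <- fspec$dup_rate + fspec$loss_rate + if (on_bact) fspec$hgt_rate else 0
      t <- s$t0
      repeat {
        dt <- if (rate > 0) rexp(1, rate) else Inf
        if (t + dt >= edges$t1[row]) {
          # reached the end of the species-tree edge
          sim$seg[[id]]$t1 <- edges$t1[row]
          if (edges$is_tip[row]) {
            sim$seg[[id]]$fate <- "leaf"
          } else {
            sim$seg[[id]]$fate <- "speciation"
            kids <- vapply(child_edges(edges$node[row]), function(e) {
              new_seg(id, edges$t1[row], e)
            }, integer(1))
            sim$seg[[id]]$children <- kids
            todo <- c(todo, kids)
          }
          return(todo)
        }
        t <- t + dt
        p_hgt <- if (on_bact) fspec$hgt_rate / rate else 0
        u <- runif(1)
        if (u < fspec$loss_rate / rate) {
          sim$seg[[id]]$t1 <- t
          sim$seg[[id]]$fate <- "loss"
          log_event("loss", t, s$edge, donor_gene = id)
          return(todo)
        } else if (u < (fspec$loss_rate + fspec$dup_rate) / rate) {
          sim$seg[[id]]$t1 <- t
          sim$seg[[id]]$fate <- "duplication"
          kids <- c(new_seg(id, t, s$edge), new_seg(id, t, s$edge))
          sim$seg[[id]]$children <- kids
          log_event("duplication", t, s$edge, donor_gene = id, new_genes = kids)
          return(c(todo, kids))
        } else {
          # horizontal transfer: pick a contemporaneous bacterial edge
          alive <- edges$bacterial & edges$t0 < t & edges$t1 > t & edges$node != s$edge
          if (any(alive)) {
            rec <- edges$node[sample(rep(which(alive), 2), 1)]
            sim$seg[[id]]$t1 <- t
            sim$seg[[id]]$fate <- "hgt"
            kids <- c(new_seg(id, t, s$edge), new_seg(id, t, rec))
            sim$seg[[id]]$children <- kids
            log_event("hgt", t, s$edge, donor_gene = id, new_genes = kids)
            return(c(todo, kids))
          }
          # no eligible recipient: the event is dropped, lineage continues
        }
      }
    }

    run_todo <- function(todo) {
      while (length(todo) > 0) {
        id <- todo[length(todo)]
        todo <- extend(id, todo[-length(todo)])
      }
    }

    root_id <- new_seg(NA_integer_, edges$t0[match(origin_edge, edges$node)], origin_edge)
    log_event("origin", sim$seg[[root_id]]$t0, origin_edge, new_genes = root_id)
    run_todo(root_id)

    # scripted EGT events, in time order, splitting a live donor segment
    if (!is.null(egt) && nrow(egt) > 0) {
      for (k in seq_len(nrow(egt))) {
        t <- egt$time[k]
        donor_sp <- resolve_species_set(species_tree$taxonomy, egt$donor_clade[k])
        donor_rows <- which(vapply(seq_along(edges$node), function(i) {
          tips <- phangorn::Descendants(species_tree$tree, edges$node[i], "tips")[[1]]
          all(species_tree$tree$tip.label[tips] %in% donor_sp)
        }, logical(1)))
        donor_edges <- edges$node[donor_rows]
        live <- which(vapply(sim$seg, function(s) {
          s$edge %in% donor_edges && s$t0 <= t && !is.na(s$t1) && s$t1 > t
        }, logical(1)))
        if (length(live) == 0) {
          warning("no gene lineage alive in donor clade '", egt$donor_clade[k],
                  "' at time ", signif(t, 3), "; EGT event skipped")
          next
        }
        don <- live[sample(rep(seq_along(live), 2), 1)]
        s <- sim$seg[[don]]
        cont <- new_seg(don, t, s$edge)
        sim$seg[[cont]]$t1 <- s$t1
        sim$seg[[cont]]$fate <- s$fate
        sim$seg[[cont]]$children <- s$children
        for (ch in s$children) sim$seg[[ch]]$parent <- cont
        xfer <- new_seg(don, t, egt$edge[k])
        sim$seg[[don]]$t1 <- t
        sim$seg[[don]]$fate <- "egt"
        sim$seg[[don]]$children <- c(cont, xfer)
        log_event("egt", t, egt$edge[k], donor_gene = don,
                  donor_clade = egt$donor_clade[k], new_genes = xfer)
        run_todo(xfer)
      }
    }

    assemble_family(sim, species_tree, fspec)
  })
}

assemble_family <- function(sim, species_tree, fspec) {
  seg <- sim$seg
  n <- length(seg)
  lineage_id <- sprintf("%s_L%04d", fspec$family_name, seq_len(n))

  surv <- logical(n)
  ord <- order(vapply(seg, function(s) s$t0, numeric(1)), decreasing = TRUE)
  for (i in ord) {
    s <- seg[[i]]
    surv[i] <- identical(s$fate, "leaf") || any(surv[s$children])
  }

  tip_rows <- which(vapply(seg, function(s) identical(s$fate, "leaf"), logical(1)))
  tip_species <- vapply(tip_rows, function(i) {
    species_tree$tree$tip.label[seg[[i]]$edge]
  }, character(1))
  o <- order(tip_species, tip_rows)
  tip_rows <- tip_rows[o]
  tip_species <- tip_species[o]
  gene_id <- character(n)
  copy_idx <- stats::ave(seq_along(tip_rows), tip_species, FUN = seq_along)
  gene_id[tip_rows] <- sprintf("%s_%s_g%d", tolower(fspec$family_name), tip_species, copy_idx)

  genes <- tibble(
    gene_id = gene_id[tip_rows],
    species_id = tip_species,
    lineage = lineage_id[tip_rows]
  )

  events <- purrr::map_dfr(sim$events, function(e) {
    tibble(
      kind = e$kind, time = e$time, edge = e$edge,
      donor_gene = if (is.na(e$donor_gene)) NA_character_ else lineage_id[e$donor_gene],
      donor_clade = as.character(e$donor_clade),
      new_genes = paste(lineage_id[e$new_genes], collapse = ",")
    )
  })
  events$event_id <- seq_len(nrow(events))
  events <- events[, c("event_id", "kind", "time", "edge", "donor_gene", "donor_clade", "new_genes")]

  tree <- NULL
  roots <- which(vapply(seg, function(s) is.na(s$parent), logical(1)))
  root <- roots[1]
  if (sum(gene_id != "") >= 2 && surv[root]) {
    nwk <- function(id, acc) {
      s <- seg[[id]]
      len <- acc + (s$t1 - s$t0)
      kids <- s$children[surv[s$children]]
      if (identical(s$fate, "leaf")) {
        sprintf("%s:%s", gene_id[id], format(len, digits = 12))
      } else if (length(kids) == 1) {
        nwk(kids, len)
      } else {
        sprintf("(%s):%s", paste(vapply(kids, nwk, character(1), acc = 0), collapse = ","),
                format(len, digits = 12))
      }
    }
    tree <- ape::read.tree(text = paste0(sub(":[0-9.eE+-]+$", "", nwk(root, 0)), ";"))
    tree <- ape::collapse.singles(tree)
    if (!is.null(tree) && length(tree$tip.label) != nrow(genes)) {
      stop("internal error: gene tree leaves != extant genes")
    }
  }

  structure(
    list(
      family = fspec$family_name, tree = tree, genes = genes,
      events = events, fspec = fspec
    ),
    class = "egt_gene_family"
  )
}

#' @export
print.egt_gene_family <- function(x, ...) {
  cat(
    "Gene family ", x$family, ": ", nrow(x$genes), " extant genes in ",
    dplyr::n_distinct(x$genes$species_id), " species; events: ",
    paste(names(table(x$events$kind)), table(x$events$kind), sep = "=", collapse = ", "),
    "\n", sep = ""
  )
  invisible(x)
}
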