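# Domain-structured sequence evolution along a gene tree.
#
# A protein is a concatenation of conserved domain blocks separated by
# linkers (leading and trailing linkers included). Sites substitute with
# probability 1 - exp(-rate * branch_length * multiplier), the replacement
# drawn uniformly from the 20 amino acids; blocks use the (<= 1) core
# multiplier, linkers the (>= 1) linker multiplier, so cores stay more
# conserved. Linker lengths drift along divergent branches (redrawn from a
# Poisson at branch-length-dependent rate), which is what creates alignment
# gaps downstream. Blocks never gain
# or lose sites; a whole block can be deleted at the tips (composition-
# filter negatives), and that deletion is recorded in the returned truth.

#' Generate the fixture's motif models
#'
#' One fixed random amino-acid sequence per motif id. The M16-like model
#' embeds the zinc-binding catalytic pattern (H-x-x-E-H, then 76 residues,
#' then E) starting at model position 5, as carried by the catalytic
#' subunit of the mitochondrial processing peptidase.
#'
#' @param seed integer seed.
#' @param lengths named integer vector of model lengths.
#' @return named character vector of model sequences, with attribute
#'   `catalytic` = c(motif = "M16", offset = 5).
#' @export
generate_motif_models <- function(seed = 1,
                                  lengths = c(M16 = 90, M16C = 70,
                                              M16C_assoc = 60, M3 = 80,
                                              TPR = 50)) {
  stopifnot(!is.null(names(lengths)))
  if ("M16" %in% names(lengths) && lengths[["M16"]] < 86) {
    stop("the M16-like model must have >= 86 positions to hold the catalytic pattern")
  }
  with_seed(derive_seed(seed, "motif_models"), {
    models <- vapply(lengths, random_aa, character(1))
    if ("M16" %in% names(models)) {
      m <- strsplit(models[["M16"]], "")[[1]]
      m[5] <- "H"; m[6] <- "A"; m[7] <- "A"; m[8] <- "E"; m[9] <- "H"
      m[86] <- "E"
      # keep the catalytic pattern unique within the model
      m[setdiff(which(m == "H"), c(5, 9))] <- "K"
      models[["M16"]] <- paste(m, collapse = "")
    }
    attr(models, "catalytic") <- c(motif = "M16", offset = 5)
    models
  })
}

mutate_sites <- function(chars, p) {
  if (length(chars) == 0 || p <= 0) return(chars)
  hit <- runif(length(chars)) < p
  if (any(hit)) chars[hit] <- sample(AA_ALPHABET, sum(hit), replace = TRUE)
  chars
}

#' Evolve domain-structured sequences along a gene tree
#'
#' @param gene_tree rooted `phylo` with branch lengths (typically the `tree`
#'   of [simulate_family()]).
#' @param fspec the [family_spec()] (domain blocks, rate multipliers, block
#'   loss probability).
#' @param motif_models named character vector from [generate_motif_models()].
#' @param root_linker_length mean linker length (Poisson), residues.
#' @param subst_rate expected substitutions per site per unit branch length
#'   before multipliers.
#' @param seed integer seed.
#' @return list with `sequences` (tibble `gene_id`, `sequence`, `length`),
#'   `blocks` (tibble `gene_id`, `block_index`, `motif_id`, `start`, `end` —
#'   1-based inclusive coordinates of the blocks surviving in that gene),
#'   `root_sequence`, and `root_blocks` (same schema for the root).
#' @export
evolve_sequences <- function(gene_tree, fspec, motif_models,
                             root_linker_length = 15, subst_rate = 0.3,
                             seed = 1) {
  stopifnot(inherits(gene_tree, "phylo"), inherits(fspec, "family_spec"))
  if (is.null(gene_tree$edge.length)) stop("gene tree must have branch lengths")
  missing <- setdiff(fspec$domain_blocks, names(motif_models))
  if (length(missing) > 0) {
    stop("no motif model for block(s): ", paste(missing, collapse = ", "))
  }

  with_seed(derive_seed(seed, paste0("seq_", fspec$family_name)), {
    k <- length(fspec$domain_blocks)
    root_pieces <- vector("list", 2 * k + 1)
    types <- rep(c("linker", "block"), length.out = 2 * k + 1)
    bi <- 0L
    for (i in seq_along(root_pieces)) {
      if (types[i] == "block") {
        bi <- bi + 1L
        root_pieces[[i]] <- list(
          type = "block", motif = fspec$domain_blocks[bi], block_index = bi,
          chars = strsplit(motif_models[[fspec$domain_blocks[bi]]], "")[[1]]
        )
      } else {
        len <- rpois(1, root_linker_length)
        root_pieces[[i]] <- list(
          type = "linker",
          chars = if (len > 0) sample(AA_ALPHABET, len, replace = TRUE) else character()
        )
      }
    }

    n_tip <- length(gene_tree$tip.label)
    children <- split(
      seq_len(nrow(gene_tree$edge)),
      factor(gene_tree$edge[, 1], levels = seq_len(n_tip + gene_tree$Nnode))
    )
    leaf_pieces <- vector("list", n_tip)

    evolve_edge <- function(pieces, len) {
      p_core <- 1 - exp(-subst_rate * fspec$core_rate_multiplier * len)
      p_link <- 1 - exp(-subst_rate * fspec$linker_rate_multiplier * len)
      lapply(pieces, function(pc) {
        if (pc$type == "block") {
          pc$chars <- mutate_sites(pc$chars, p_core)
        } else {
          cur <- mutate_sites(pc$chars, p_link)
          # linker length drifts only when the branch carries divergence
          if (runif(1) < p_link) {
            new_len <- rpois(1, root_linker_length)
            cur <- if (new_len <= length(cur)) {
              cur[seq_len(new_len)]
            } else {
              c(cur, sample(AA_ALPHABET, new_len - length(cur), replace = TRUE))
            }
          }
          pc$chars <- cur
        }
        pc
      })
    }

    walk <- function(node, pieces) {
      for (e in children[[node]]) {
        child <- gene_tree$edge[e, 2]
        ev <- evolve_edge(pieces, gene_tree$edge.length[e])
        if (child <= n_tip) {
          leaf_pieces[[child]] <<- ev
        } else {
          walk(child, ev)
        }
      }
    }
    walk(n_tip + 1L, root_pieces)

    layout <- function(pieces) {
      pos <- 0L
      rows <- list()
      for (pc in pieces) {
        if (pc$type == "block") {
          rows[[length(rows) + 1L]] <- tibble(
            block_index = pc$block_index, motif_id = pc$motif,
            start = pos + 1L, end = pos + length(pc$chars)
          )
        }
        pos <- pos + length(pc$chars)
      }
      bind_rows(rows)
    }

    seqs <- character(n_tip)
    blocks <- vector("list", n_tip)
    for (i in seq_len(n_tip)) {
      pieces <- leaf_pieces[[i]]
      if (fspec$block_loss_prob > 0) {
        keep <- vapply(pieces, function(pc) {
          pc$type != "block" || runif(1) >= fspec$block_loss_prob
        }, logical(1))
        pieces <- pieces[keep]
      }
      seqs[i] <- paste(unlist(lapply(pieces, `[[`, "chars")), collapse = "")
      blocks[[i]] <- layout(pieces)
      blocks[[i]]$gene_id <- gene_tree$tip.label[i]
    }

    list(
      sequences = tibble(
        gene_id = gene_tree$tip.label, sequence = seqs, length = nchar(seqs)
      ),
      blocks = bind_rows(blocks) |>
        select("gene_id", "block_index", "motif_id", "start", "end"),
      root_sequence = paste(unlist(lapply(root_pieces, `[[`, "chars")), collapse = ""),
      root_blocks = layout(root_pieces)
    )
  })
}
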