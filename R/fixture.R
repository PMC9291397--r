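# End-to-end synthetic fixture: a labeled species tree, four peptidase
# families evolved with duplication/loss/HGT and one scripted endosymbiotic
# transfer each, and domain-structured sequences. This stands in for a
# reference-proteome collection and gives every downstream stage exact
# ground truth.

#' Default clade plan for the synthetic proteome collection
#'
#' Six bacterial clades of ten species (three carrying antimicrobial-peptide
#' resistant genera), twelve eukaryotes, two archaea.
#' @return tibble usable as `clade_plan` in [simulate_species_tree()].
#' @export
default_clade_plan <- function() {
  tibble(
    clade = c("alpha", "beta", "gamma", "delta", "epsilon", "zeta",
              "eukaryotes", "archaea"),
    domain_of_life = c(rep("Bacteria", 6), "Eukaryota", "Archaea"),
    n_species = c(rep(10L, 6), 12L, 2L),
    resistant_fraction = c(0.4, 0.2, 0.4, 0, 0, 0, 0, 0)
  )
}

#' Required motif composition of the four peptidase families
#'
#' The mitochondrial processing peptidase needs the M16 and M16C motifs;
#' the presequence protease additionally needs M16C_assoc; the stromal
#' processing peptidase needs M16C twice; the organellar oligo-peptidase
#' needs M3. Multiplicities are encoded as repeated rows.
#' @return tibble with columns `family`, `motif_id`.
#' @export
family_compositions <- function() {
  tibble(
    family = c("MPP", "MPP", "PreP", "PreP", "PreP", "SPP", "SPP", "SPP", "OOP"),
    motif_id = c("M16", "M16C", "M16", "M16C", "M16C_assoc",
                 "M16", "M16C", "M16C", "M3")
  )
}

#' Default simulation specs for the four families
#'
#' Each family originates in bacteria and reaches eukaryotes through one
#' scripted endosymbiotic transfer from a distinct donor clade, on top of
#' background duplication, loss and bacteria-to-bacteria transfer. The
#' organellar oligo-peptidase carries an extra TPR-like block beyond its
#' required composition, exercising the additional-domain catalog.
#'
#' @param block_loss_prob per-gene, per-block deletion probability.
#' @param dup_rate,loss_rate,hgt_rate shared event rates per unit branch
#'   length.
#' @return named list of [family_spec()] objects.
#' @export
default_family_specs <- function(block_loss_prob = 0.05,
                                 dup_rate = 0.1, loss_rate = 0.05,
                                 hgt_rate = 0.05) {
  donors <- c(MPP = "alpha", SPP = "beta", PreP = "gamma", OOP = "delta")
  blocks <- list(
    MPP = c("M16", "M16C"),
    SPP = c("M16", "M16C", "M16C"),
    PreP = c("M16", "M16C", "M16C_assoc"),
    OOP = c("M3", "TPR")
  )
  purrr::imap(blocks, function(b, fam) {
    family_spec(
      fam, b,
      dup_rate = dup_rate, loss_rate = loss_rate, hgt_rate = hgt_rate,
      egt_events = tibble(donor_clade = donors[[fam]],
                          recipient = "Eukaryota", time = NA_real_),
      block_loss_prob = block_loss_prob
    )
  })
}

#' Simulate the full synthetic fixture
#'
#' @param seed root seed; every stage derives its own stream from it, so
#'   identical arguments give a byte-identical fixture.
#' @param clade_plan see [simulate_species_tree()].
#' @param family_specs named list of [family_spec()]s.
#' @param subst_rate expected substitutions per site per unit branch length
#'   (tree depth is 1, so this is also the root-to-tip divergence).
#' @param root_linker_length mean inter-block linker length, residues.
#' @param family_divergence expected substitutions per site separating each
#'   family's root copy of a shared block from the ancestral motif model,
#'   so the subfamilies sharing M16-like blocks are distinct but alignable
#'   (the family carrying the catalytic pattern keeps it intact).
#' @return an `egt_fixture`: species tree + taxonomy, per-family gene trees,
#'   event logs, sequences and true block layouts, the pooled `proteome`
#'   tibble (`gene_id`, `species_id`, `family_truth`, `sequence`), family
#'   reference sequences (the root proteins), motif models, compositions.
#' @examples
#' fx <- simulate_fixture(seed = 1, subst_rate = 0)
#' fx$proteome
#' @export
simulate_fixture <- function(seed = 1,
                             clade_plan = default_clade_plan(),
                             family_specs = default_family_specs(),
                             subst_rate = 0.3,
                             root_linker_length = 15,
                             family_divergence = 0.4) {
  st <- simulate_species_tree(clade_plan, seed = seed)
  models <- generate_motif_models(seed = seed)

  families <- purrr::map(family_specs, function(fs) {
    fam <- simulate_family(st, fs, seed = seed)
    if (is.null(fam$tree)) {
      warning("family ", fs$family_name, " went extinct; excluded from fixture")
      return(NULL)
    }
    fam_models <- diverge_models(models, fs$family_name, family_divergence, seed)
    ev <- evolve_sequences(
      fam$tree, fs, fam_models,
      root_linker_length = root_linker_length,
      subst_rate = subst_rate, seed = seed
    )
    fam$sequences <- ev$sequences
    fam$blocks <- ev$blocks
    fam$root_sequence <- ev$root_sequence
    fam$root_blocks <- ev$root_blocks
    fam
  })
  families <- purrr::compact(families)

  proteome <- purrr::map_dfr(families, function(fam) {
    fam$genes |>
      left_join(fam$sequences, by = "gene_id") |>
      mutate(family_truth = fam$family) |>
      select("gene_id", "species_id", "family_truth", "sequence")
  })
  if (nrow(proteome) == 0) {
    proteome <- tibble(gene_id = character(), species_id = character(),
                       family_truth = character(), sequence = character())
  }

  structure(
    list(
      species_tree = st,
      taxonomy = st$taxonomy,
      families = families,
      proteome = proteome,
      references = purrr::map_chr(families, "root_sequence"),
      motif_models = models,
      compositions = family_compositions(),
      params = list(seed = seed, subst_rate = subst_rate,
                    root_linker_length = root_linker_length)
    ),
    class = "egt_fixture"
  )
}

#' @export
print.egt_fixture <- function(x, ...) {
  cat("Synthetic peptidase fixture: ", nrow(x$taxonomy), " species, ",
      length(x$families), " families, ", nrow(x$proteome), " proteins (",
      "subst_rate = ", x$params$subst_rate, ")\n", sep = "")
  invisible(x)
}

#' Write a fixture to plain-text files
#'
#' Emits the proteome FASTA (`gene_id|species_id|family_truth` headers),
#' species and true gene trees in newick, taxonomy TSV, motif models and
#' family references as FASTA, true block layouts TSV, compositions TSV and
#' the per-family event logs as JSON. Everything round-trips through
#' [read_fixture()].
#'
#' @param fixture an `egt_fixture`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
emit_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "egt_fixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)

  write_fasta(
    setNames(
      fixture$proteome$sequence,
      paste(fixture$proteome$gene_id, fixture$proteome$species_id,
            fixture$proteome$family_truth, sep = "|")
    ),
    file.path(dir, "proteomes.fasta")
  )
  ape::write.tree(fixture$species_tree$tree, file.path(dir, "species_tree.nwk"))
  readr::write_tsv(fixture$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_fasta(unclass(fixture$motif_models), file.path(dir, "motif_models.fasta"))
  write_fasta(fixture$references, file.path(dir, "references.fasta"))
  readr::write_tsv(fixture$compositions, file.path(dir, "compositions.tsv"))

  blocks <- purrr::imap_dfr(fixture$families, function(fam, nm) {
    mutate(fam$blocks, family = nm)
  })
  if (nrow(blocks) == 0) {
    blocks <- tibble(gene_id = character(), block_index = integer(),
                     motif_id = character(), start = integer(),
                     end = integer(), family = character())
  }
  readr::write_tsv(blocks, file.path(dir, "block_truth.tsv"))

  for (nm in names(fixture$families)) {
    ape::write.tree(fixture$families[[nm]]$tree,
                    file.path(dir, sprintf("gene_tree_%s.nwk", nm)))
  }
  events <- purrr::map(fixture$families, "events")
  jsonlite::write_json(events, file.path(dir, "events.json"),
                       dataframe = "rows", na = "null", digits = NA)
  invisible(dir)
}

#' Read back a fixture directory written by [emit_fixture()]
#'
#' @param dir directory produced by [emit_fixture()].
#' @return list with `proteome`, `taxonomy`, `species_tree` (`phylo`),
#'   `gene_trees` (named list of `phylo`), `motif_models`, `references`,
#'   `compositions`, `block_truth`, `events` (named list of tibbles).
#' @export
read_fixture <- function(dir) {
  fasta <- read_fasta(file.path(dir, "proteomes.fasta"))
  hdr <- stringr::str_split_fixed(names(fasta), stringr::fixed("|"), 3)
  proteome <- tibble(
    gene_id = hdr[, 1], species_id = hdr[, 2], family_truth = hdr[, 3],
    sequence = unname(fasta)
  )
  events <- jsonlite::read_json(file.path(dir, "events.json"), simplifyVector = TRUE)
  events <- purrr::map(events, as_tibble)
  gt_files <- list.files(dir, pattern = "^gene_tree_.*\\.nwk$", full.names = TRUE)
  gene_trees <- setNames(
    purrr::map(gt_files, ape::read.tree),
    sub("^gene_tree_(.*)\\.nwk$", "\\1", basename(gt_files))
  )
  list(
    proteome = proteome,
    taxonomy = readr::read_tsv(file.path(dir, "taxonomy.tsv"),
                               show_col_types = FALSE) |>
      mutate(resistant = as.integer(.data$resistant)),
    species_tree = ape::read.tree(file.path(dir, "species_tree.nwk")),
    gene_trees = gene_trees,
    motif_models = read_fasta(file.path(dir, "motif_models.fasta")),
    references = read_fasta(file.path(dir, "references.fasta")),
    compositions = readr::read_tsv(file.path(dir, "compositions.tsv"),
                                   show_col_types = FALSE),
    block_truth = readr::read_tsv(file.path(dir, "block_truth.tsv"),
                                  show_col_types = FALSE),
    events = events
  )
}

# family-specific root copies of the motif models: mutate each block by a
# fixed expected divergence, keeping the catalytic pattern pinned in the
# family that carries it (the mitochondrial processing peptidase)
diverge_models <- function(models, family, divergence, seed) {
  if (divergence <= 0) return(models)
  with_seed(derive_seed(seed, paste0("family_blocks_", family)), {
    cat_info <- attr(models, "catalytic")
    out <- vapply(names(models), function(m) {
      chars <- strsplit(models[[m]], "")[[1]]
      chars <- mutate_sites(chars, 1 - exp(-divergence))
      if (!is.null(cat_info) && family == "MPP" && m == cat_info[["motif"]]) {
        off <- as.integer(cat_info[["offset"]])
        ref <- strsplit(models[[m]], "")[[1]]
        pin <- c(off, off + 3L, off + 4L, off + 4L + 76L + 1L)
        chars[pin] <- ref[pin]
      }
      paste(chars, collapse = "")
    }, character(1))
    attr(out, "catalytic") <- cat_info
    out
  })
}

write_fasta <- function(seqs, path) {
  if (length(seqs) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(seqs), path, width = 80
  )
  invisible(path)
}

read_fasta <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) return(setNames(character(), character()))
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}
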