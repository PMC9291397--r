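# Species x family presence matrix and co-occurrence enrichment between
# antimicrobial-peptide-resistant and other bacteria.

#' Build the species-by-family presence matrix
#'
#' One row per species in the taxonomy (species without any homolog appear
#' as all-false rows); one logical column per family, true iff the species
#' carries at least one homolog. Duplicated homolog rows are harmless.
#'
#' @param homologs tibble `gene_id`, `species_id`, `family` (typically the
#'   primary assignments of [filter_by_composition()]).
#' @param taxonomy tibble `species_id`, `clade`, `genus`, `resistant`.
#' @param families column set; defaults to the families seen in `homologs`.
#' @return tibble: `species_id`, `clade`, `genus`, `resistant`, then one
#'   logical column per family.
#' @export
build_presence <- function(homologs, taxonomy, families = NULL) {
  taxonomy <- as_tibble(taxonomy)
  homologs <- as_tibble(homologs)
  unknown <- setdiff(unique(homologs$species_id), taxonomy$species_id)
  if (length(unknown) > 0) {
    stop("homolog species missing from taxonomy: ",
         paste(unknown, collapse = ", "))
  }
  families <- families %||% sort(unique(homologs$family))
  out <- select(taxonomy, "species_id", dplyr::any_of(c("clade", "genus", "resistant")))
  for (fam in families) {
    out[[fam]] <- out$species_id %in%
      homologs$species_id[homologs$family == fam]
  }
  out
}

#' 2x2 co-occurrence counts for a family pair
#'
#' @param presence output of [build_presence()].
#' @param pair character vector of two distinct family names.
#' @param species optional species subset (default: all rows).
#' @return one-row tibble `both`, `only_first`, `only_second`, `neither`;
#'   the four cells always sum to the subset size.
#' @export
pair_counts <- function(presence, pair, species = NULL) {
  stopifnot(length(pair) == 2, pair[1] != pair[2],
            all(pair %in% names(presence)))
  rows <- if (is.null(species)) presence else
    presence[presence$species_id %in% species, ]
  a <- rows[[pair[1]]]
  b <- rows[[pair[2]]]
  tibble(
    both = sum(a & b), only_first = sum(a & !b),
    only_second = sum(!a & b), neither = sum(!a & !b)
  )
}

# exact conditional test on a 2x2 table; degenerate margins give p = 1 and
# an undefined (NA) odds ratio
exact_table_test <- function(tab, alternative = "two.sided") {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(p = 1, or = NA_real_))
  }
  ft <- fisher.test(tab, alternative = alternative)
  list(p = ft$p.value, or = unname(ft$estimate))
}

#' Co-occurrence enrichment between resistant and other bacteria
#'
#' Exact conditional (Fisher-type) test on the 2x2 table (pair co-occurs?)
#' x (resistant?), within a clade or across all rows. The default contrast
#' is exclusive — resistant vs non-resistant species; the co-occurrence
#' rate over the whole (sub)set is also reported so the inclusive
#' comparison can be read off. Degenerate margins give p = 1 and an
#' undefined odds ratio.
#'
#' @param presence output of [build_presence()] (needs `resistant`).
#' @param pair two distinct family names.
#' @param clade restrict to one clade (default: all rows).
#' @param alternative `"two.sided"` (default), `"greater"` (co-occurrence
#'   enriched in resistant) or `"less"`.
#' @return one-row tibble: `clade`, `family_a`, `family_b`, the four cells
#'   (`co_resistant`, `co_other`, `nonco_resistant`, `nonco_other`),
#'   `co_rate_resistant`, `co_rate_other`, `co_rate_all`, `odds_ratio`,
#'   `p_value`, `direction`, `alternative`.
#' @export
cooccurrence_enrichment <- function(presence, pair, clade = NULL,
                                    alternative = "two.sided") {
  stopifnot(length(pair) == 2, pair[1] != pair[2])
  rows <- if (is.null(clade)) presence else presence[presence$clade == clade, ]
  if (!all(c(pair, "resistant") %in% names(rows))) {
    stop("presence matrix lacks required columns")
  }
  co <- rows[[pair[1]]] & rows[[pair[2]]]
  res <- rows$resistant == 1
  if (sum(res) == 0 || sum(!res) == 0) {
    stop("both partition cells (resistant / other) must be nonempty")
  }
  tab <- matrix(c(sum(co & res), sum(co & !res),
                  sum(!co & res), sum(!co & !res)), nrow = 2, byrow = TRUE)
  tt <- exact_table_test(tab, alternative)
  or <- tt$or
  p <- tt$p
  r_res <- sum(co & res) / sum(res)
  r_oth <- sum(co & !res) / sum(!res)
  tibble(
    clade = clade %||% NA_character_,
    family_a = pair[1], family_b = pair[2],
    co_resistant = sum(co & res), co_other = sum(co & !res),
    nonco_resistant = sum(!co & res), nonco_other = sum(!co & !res),
    co_rate_resistant = r_res, co_rate_other = r_oth,
    co_rate_all = mean(co),
    odds_ratio = or, p_value = p,
    direction = dplyr::case_when(
      is.na(or) ~ "undefined",
      r_res > r_oth ~ "resistant_higher",
      r_res < r_oth ~ "resistant_lower",
      TRUE ~ "equal"
    ),
    alternative = alternative
  )
}
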