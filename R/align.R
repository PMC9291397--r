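# Local similarity search and reference-anchored alignment.
#
# The search engine is Smith-Waterman with BLOSUM62 scoring (gap open 11,
# extend 1) and a Karlin-Altschul style E-value approximation
# E = K * m * n * exp(-lambda * S) with the usual gapped-BLOSUM62 constants
# lambda = 0.267, K = 0.041. E-values are computed per pair (m, n = the two
# sequence lengths), which is what the threshold contracts below expect.

KA_LAMBDA <- 0.267
KA_K <- 0.041

blosum62 <- function() {
  # lazy-load once per session
  if (is.null(.egt_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .egt_env$blosum62 <- e$BLOSUM62
  }
  .egt_env$blosum62
}

.egt_env <- new.env(parent = emptyenv())

karlin_altschul_evalue <- function(score, m, n) {
  KA_K * m * n * exp(-KA_LAMBDA * score)
}

#' Local similarity search of one query against a sequence set
#'
#' Smith-Waterman alignment of `query` against every sequence in `subjects`,
#' with per-pair E-values. This is the engine behind [seed_search()],
#' [profile_scan()], [annotate_domains()] and [similarity_distance()].
#'
#' @param query amino-acid string (the reference; "query coverage" is
#'   measured on it).
#' @param subjects named character vector of amino-acid sequences.
#' @return tibble with one row per subject: `subject_id`, `score`, `evalue`,
#'   `query_cov` (fraction of the query covered by the local alignment),
#'   `s_start`, `s_end` (1-based inclusive coordinates on the subject).
#' @keywords internal
sw_hits <- function(query, subjects) {
  if (length(subjects) == 0) {
    return(tibble(
      subject_id = character(), score = numeric(), evalue = numeric(),
      query_cov = numeric(), s_start = integer(), s_end = integer()
    ))
  }
  stopifnot(!is.null(names(subjects)))
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(unname(subjects)),
    subject = Biostrings::AAString(query),
    type = "local",
    substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1
  )
  sc <- Biostrings::score(pa)
  # subject() holds the query here; its aligned range = query coverage span
  qr <- as.data.frame(Biostrings::subject(pa)@range)
  pr <- as.data.frame(Biostrings::pattern(pa)@range)
  tibble(
    subject_id = names(subjects),
    score = sc,
    evalue = karlin_altschul_evalue(sc, nchar(query), nchar(unname(subjects))),
    query_cov = (qr$end - qr$start + 1) / nchar(query),
    s_start = as.integer(pr$start),
    s_end = as.integer(pr$end)
  )
}

#' Reference-anchored multiple alignment
#'
#' Globally aligns each sequence to a reference and reports it in reference
#' coordinates: one aligned row per input sequence, every row exactly
#' `nchar(reference)` columns, positions deleted relative to the reference
#' shown as `-`, insertions relative to the reference dropped.
#'
#' @param seqs named character vector.
#' @param reference amino-acid string defining the column space.
#' @return named character vector of gapped rows, all the same width.
#' @keywords internal
align_to_reference <- function(seqs, reference) {
  if (length(seqs) == 0) return(setNames(character(), character()))
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(unname(seqs)),
    subject = Biostrings::AAString(reference),
    type = "global",
    substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1
  )
  rows <- as.character(Biostrings::aligned(pa))
  setNames(rows, names(seqs))
}
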