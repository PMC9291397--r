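# Sequence-logo statistics and the catalytic zinc-binding motif scanner.

#' Per-column logo statistics of a multiple alignment
#'
#' For each column: residue frequencies over the 20 amino acids among
#' non-gap symbols (`X` counted as missing and excluded), the gap
#' fraction, and the information content in bits relative to a uniform
#' background, `log2(20) - H(column)`. A residue's logo height is its
#' frequency times the column information, and the stack width is
#' `1 - gap_fraction` (all-gap columns: information 0, width 0).
#'
#' @param alignment named character vector of equal-width aligned rows, or
#'   a character matrix (rows = sequences).
#' @param small_sample_correction subtract the small-sample bias term
#'   `(20 - 1) / (2 ln 2 n)` from the information (off by default so the
#'   analytic identities hold exactly).
#' @return tibble: `position`, `gap_fraction`, `width`, `information`,
#'   `top_residue`, `top_freq`, `n_residues`, and a list-column `freqs`
#'   (named numeric over the 20 amino acids).
#' @export
logo_stats <- function(alignment, small_sample_correction = FALSE) {
  mat <- if (is.matrix(alignment)) alignment else {
    if (length(unique(nchar(alignment))) != 1) {
      stop("alignment rows must have equal width")
    }
    do.call(rbind, strsplit(unname(alignment), ""))
  }
  n_rows <- nrow(mat)
  purrr::map_dfr(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    gap_fraction <- mean(col == "-")
    res <- col[col %in% AA_ALPHABET]
    if (length(res) == 0) {
      return(tibble(
        position = j, gap_fraction = gap_fraction, width = 0,
        information = 0, top_residue = NA_character_, top_freq = NA_real_,
        n_residues = 0L,
        freqs = list(setNames(rep(0, 20), AA_ALPHABET))
      ))
    }
    f <- tabulate(factor(res, levels = AA_ALPHABET), nbins = 20) / length(res)
    names(f) <- AA_ALPHABET
    ent <- -sum(ifelse(f > 0, f * log2(f), 0))
    info <- log2(20) - ent
    if (small_sample_correction) {
      info <- max(0, info - 19 / (2 * log(2) * length(res)))
    }
    top <- which.max(f)
    tibble(
      position = j, gap_fraction = gap_fraction, width = 1 - gap_fraction,
      information = info, top_residue = AA_ALPHABET[top],
      top_freq = unname(f[top]), n_residues = length(res), freqs = list(f)
    )
  })
}

#' Locate the catalytic zinc-binding motif
#'
#' Scans for the pattern of the catalytic subunit of the mitochondrial
#' processing peptidase: H at position i, E at i+3, H at i+4, and a
#' downstream E separated from the second H by `spacing` residues
#' (HxxEH, 76 residues, E). A spacing tolerance admits alignment-derived
#' sequences carrying small indels near the motif.
#'
#' @param sequence amino-acid string.
#' @param spacing canonical separation (default 76).
#' @param tolerance allowed deviation `|s - spacing|` (default 0).
#' @return integer vector of 1-based match start positions (empty if the
#'   sequence is shorter than the motif span).
#' @export
find_catalytic_motif <- function(sequence, spacing = 76, tolerance = 0) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  span_min <- 4 + (spacing - tolerance) + 2
  if (n < span_min) return(integer())
  starts <- which(chars == "H")
  keep <- starts[starts + 4 <= n &
                   chars[pmin(starts + 3, n)] == "E" &
                   chars[pmin(starts + 4, n)] == "H"]
  found <- vapply(keep, function(i) {
    offs <- i + 4 + (spacing - tolerance):(spacing + tolerance) + 1
    offs <- offs[offs <= n]
    any(chars[offs] == "E")
  }, logical(1))
  as.integer(keep[found])
}

#' Compare two column-wise logo profiles
#'
#' Position-by-position comparison of two alignments built over the same
#' motif coordinates: top residue of each set, agreement flag, and the
#' information difference (a - b).
#'
#' @param stats_a,stats_b outputs of [logo_stats()] with equal column
#'   counts.
#' @return tibble `position`, `top_a`, `top_b`, `agree`, `info_diff`;
#'   attribute `agreement` = fraction of positions with agreeing top
#'   residues (positions where either top is undefined are excluded from
#'   the fraction).
#' @export
compare_logos <- function(stats_a, stats_b) {
  if (nrow(stats_a) != nrow(stats_b)) {
    stop("column counts differ: ", nrow(stats_a), " vs ", nrow(stats_b))
  }
  out <- tibble(
    position = stats_a$position,
    top_a = stats_a$top_residue,
    top_b = stats_b$top_residue,
    agree = !is.na(stats_a$top_residue) & !is.na(stats_b$top_residue) &
      stats_a$top_residue == stats_b$top_residue,
    info_diff = stats_a$information - stats_b$information
  )
  defined <- !is.na(out$top_a) & !is.na(out$top_b)
  attr(out, "agreement") <- if (any(defined)) mean(out$agree[defined]) else NA_real_
  out
}
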