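#' The two illustrative toy alignments
#'
#' Deterministic constructions of the two 1000 x 5 nucleotide alignments
#' used to contrast bundles with aggregative logos: both have identical
#' per-column nucleotide frequencies (500 A / 500 T at every site) but
#' completely different row-level motifs. `make_fig1a()` holds 500
#' copies of AAAAA (labels A0001..A0500) and 500 of TTTTT (T0001..
#' T0500); `make_fig1b()` 500 copies of AATTT and 500 of TTAAA under
#' the same label scheme.
#'
#' @return An `msa`.
#' @export
make_fig1a <- function() {
  two_motif_msa("AAAAA", "TTTTT")
}

#' @rdname make_fig1a
#' @export
make_fig1b <- function() {
  two_motif_msa("AATTT", "TTAAA")
}

two_motif_msa <- function(motif_a, motif_t, n_each = 500L) {
  labels <- c(sprintf("A%04d", seq_len(n_each)),
              sprintf("T%04d", seq_len(n_each)))
  rows <- c(rep(motif_a, n_each), rep(motif_t, n_each))
  msa(labels, rows, builtin_alphabets()$dna)
}

# The canonical two-group assignment of the toy alignments: first-motif
# rows vs second-motif rows.
two_motif_groups <- function(x) {
  g <- ifelse(startsWith(x$labels, "A"), "motifA", "motifT")
  group_assignment(stats::setNames(g, x$labels))
}

#' Specification for a planted-structure alignment
#'
#' Describes a grouped synthetic alignment at desk scale emulating the
#' structure of real specificity-determining-site studies: a background
#' of independently drawn symbols, planted columns whose symbol is
#' fixed per group (the ground-truth specificity-determining sites),
#' and covariant column pairs jointly overwritten in a seeded random
#' half of the rows.
#'
#' @param group_sizes Named integer vector (group name -> size), every
#'   size >= 2.
#' @param n_col Number of alignment columns.
#' @param alphabet A `bk_alphabet` (default protein).
#' @param planted_sites List of `list(column =, symbols =)` where
#'   `symbols` is a named character vector (group -> symbol).
#' @param covariant_pairs List of `list(col_a =, sym_a =, col_b =,
#'   sym_b =)`.
#' @param background Named probability vector over symbols (default
#'   uniform over the alphabet).
#' @param seed Integer seed; the single source of randomness.
#' @return Object of class `planted_msa_spec`.
#' @export
planted_msa_spec <- function(group_sizes, n_col,
                             alphabet = builtin_alphabets()$protein,
                             planted_sites = list(),
                             covariant_pairs = list(),
                             background = NULL, seed = 1L) {
  if (is.null(names(group_sizes)) || any(group_sizes < 2L))
    bk_stop("config_error",
            "group_sizes must be a named vector with every size >= 2")
  planted_cols <- vapply(planted_sites, function(s) as.integer(s$column),
                         integer(1))
  cov_cols <- unlist(lapply(covariant_pairs,
                            function(p) c(p$col_a, p$col_b)))
  all_special <- c(planted_cols, cov_cols)
  if (anyDuplicated(all_special))
    bk_stop("config_error",
            "planted and covariant columns must be disjoint")
  if (length(all_special) && (min(all_special) < 1L ||
                              max(all_special) > n_col))
    bk_stop("config_error", "planted column out of range [1, %d]", n_col)
  for (s in planted_sites)
    if (!setequal(names(s$symbols), names(group_sizes)))
      bk_stop("config_error",
              "planted site at column %d must name every group", s$column)
  if (is.null(background))
    background <- stats::setNames(
      rep(1 / length(alphabet$symbols), length(alphabet$symbols)),
      alphabet$symbols)
  structure(list(group_sizes = group_sizes, n_col = as.integer(n_col),
                 alphabet = alphabet, planted_sites = planted_sites,
                 covariant_pairs = covariant_pairs,
                 background = background / sum(background),
                 seed = as.integer(seed)),
            class = "planted_msa_spec")
}

#' Generate a planted-structure alignment
#'
#' @param spec A `planted_msa_spec`.
#' @return List: `msa`, `groups` (a `group_assignment`), `truth_sites`
#'   (planted column indices), `covariant_rows` (row indices where each
#'   covariant pair was enforced).
#' @export
make_planted_msa <- function(spec) {
  with_seed(spec$seed, {
    n_seq <- sum(spec$group_sizes)
    gnames <- names(spec$group_sizes)
    g <- rep(gnames, times = spec$group_sizes)
    labels <- sprintf("%s_%03d", g, unlist(lapply(spec$group_sizes,
                                                  seq_len)))
    m <- matrix(sample(names(spec$background), n_seq * spec$n_col,
                       replace = TRUE, prob = spec$background),
                nrow = n_seq, ncol = spec$n_col)
    for (s in spec$planted_sites)
      m[, s$column] <- unname(s$symbols[g])
    cov_rows <- lapply(spec$covariant_pairs, function(p) {
      rows <- sort(sample(n_seq, floor(n_seq / 2)))
      m[rows, p$col_a] <<- p$sym_a
      m[rows, p$col_b] <<- p$sym_b
      rows
    })
    out <- msa(labels, apply(m, 1, paste, collapse = ""), spec$alphabet)
    groups <- group_assignment(stats::setNames(g, labels))
    list(msa = out, groups = groups,
         truth_sites = vapply(spec$planted_sites,
                              function(s) as.integer(s$column), integer(1)),
         covariant_rows = cov_rows)
  })
}
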