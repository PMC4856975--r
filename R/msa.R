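#' Multiple sequence alignment container
#'
#' The central data structure: a rectangular block of aligned symbols over
#' an alphabet, with unique sequence labels. All invariants (equal row
#' lengths, alphabet membership, label uniqueness) are enforced here, at
#' construction time. Column addressing is 1-based everywhere.
#'
#' @param labels Character vector of unique sequence identifiers.
#' @param rows Character vector of aligned symbol strings, all same length.
#' @param alphabet A `bk_alphabet` (see [builtin_alphabets()]).
#' @param descriptions Optional per-sequence free-text metadata.
#' @return An object of class `msa` with fields `labels`, `rows`,
#'   `alphabet`, `n_seq`, `n_col`, `descriptions`.
#' @export
msa <- function(labels, rows, alphabet, descriptions = NULL) {
  labels <- as.character(labels)
  rows <- toupper(as.character(rows))
  if (length(labels) != length(rows))
    bk_stop("identity_error", "got %d labels for %d rows",
            length(labels), length(rows))
  if (length(rows) == 0L)
    bk_stop("alignment_shape_error", "alignment has no sequences")
  dup <- labels[duplicated(labels)]
  if (length(dup))
    bk_stop("identity_error", "duplicate sequence label(s): %s",
            paste(unique(dup), collapse = ", "))
  lens <- nchar(rows)
  if (lens[1] == 0L)
    bk_stop("alignment_shape_error", "alignment has zero columns")
  if (any(lens != lens[1])) {
    bad <- which(lens != lens[1])[1]
    bk_stop("alignment_shape_error",
            "ragged alignment: record '%s' has length %d, expected %d",
            labels[bad], lens[bad], lens[1])
  }
  # '.' (Stockholm insert gap) is normalized to the gap symbol on input
  rows <- gsub(".", alphabet$gap_symbol, rows, fixed = TRUE)
  ok <- c(alphabet$symbols, alphabet$gap_symbol)
  for (i in seq_along(rows)) {
    ch <- strsplit(rows[i], "", fixed = TRUE)[[1]]
    bad <- which(!(ch %in% ok))
    if (length(bad))
      bk_stop("alphabet_error",
              "symbol '%s' in record '%s' column %d is not in alphabet '%s'",
              ch[bad[1]], labels[i], bad[1], alphabet$name)
  }
  structure(list(labels = labels, rows = rows, alphabet = alphabet,
                 n_seq = length(rows), n_col = lens[1],
                 descriptions = descriptions),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("MSA: %d sequences x %d columns (alphabet '%s')\n",
              x$n_seq, x$n_col, x$alphabet$name))
  n <- min(x$n_seq, 6L)
  w <- min(x$n_col, 60L)
  for (i in seq_len(n))
    cat(sprintf("  %-12s %s\n", x$labels[i], substr(x$rows[i], 1, w)))
  if (x$n_seq > n) cat(sprintf("  ... %d more\n", x$n_seq - n))
  invisible(x)
}

#' Character matrix view of an MSA
#'
#' @param x An `msa`.
#' @return `n_seq x n_col` character matrix, rownames = labels.
#' @export
msa_matrix <- function(x) {
  m <- matrix(unlist(strsplit(x$rows, "", fixed = TRUE), use.names = FALSE),
              nrow = x$n_seq, ncol = x$n_col, byrow = TRUE)
  rownames(m) <- x$labels
  m
}

#' Symbol counts in one alignment column
#'
#' Counts every symbol present in the column, gap included; counts always
#' sum to the number of sequences.
#'
#' @param x An `msa`.
#' @param col 1-based column index.
#' @return Named integer vector of counts.
#' @export
column_stats <- function(x, col) {
  col <- check_col(x, col)
  ch <- substr(x$rows, col, col)
  tab <- table(ch)
  stats::setNames(as.integer(tab), names(tab))
}

check_col <- function(x, col) {
  if (length(col) != 1L || is.na(col) || col != as.integer(col) ||
      col < 1L || col > x$n_col)
    bk_stop("bounds_error", "column index %s out of range [1, %d]",
            as.character(col), x$n_col)
  as.integer(col)
}

#' Sequence/site selection
#'
#' @param seq_indices Integer set of selected sequence (row) indices.
#' @param site_indices Integer set of selected column indices.
#' @param msa The `msa` the indices refer to (bounds check).
#' @return Object of class `bk_selection`.
#' @export
selection <- function(seq_indices = integer(), site_indices = integer(),
                      msa = NULL) {
  seq_indices <- sort(unique(as.integer(seq_indices)))
  site_indices <- sort(unique(as.integer(site_indices)))
  if (!is.null(msa)) {
    if (length(seq_indices) && (min(seq_indices) < 1L ||
                                max(seq_indices) > msa$n_seq))
      bk_stop("bounds_error", "sequence index out of range [1, %d]", msa$n_seq)
    if (length(site_indices) && (min(site_indices) < 1L ||
                                 max(site_indices) > msa$n_col))
      bk_stop("bounds_error", "site index out of range [1, %d]", msa$n_col)
  }
  structure(list(seq_indices = seq_indices, site_indices = site_indices),
            class = "bk_selection")
}

#' Sequence group assignment
#'
#' Maps sequence labels to named groups, each with a display colour.
#' Membership is partial: ungrouped sequences are allowed and excluded
#' from supervised analyses.
#'
#' @param membership Named character vector: names are sequence labels,
#'   values are group names.
#' @param colors Optional named vector of RGB hex colours per group;
#'   missing groups get palette defaults.
#' @return Object of class `group_assignment`.
#' @export
group_assignment <- function(membership, colors = NULL) {
  membership <- unlist(membership)
  if (is.null(names(membership)) || any(names(membership) == ""))
    bk_stop("grouping_error", "membership must be a named vector (label -> group)")
  if (anyDuplicated(names(membership)))
    bk_stop("grouping_error", "duplicate label in group membership")
  group_names <- unique(unname(membership))
  pal <- default_group_colors(length(group_names))
  cols <- stats::setNames(pal, group_names)
  if (!is.null(colors)) {
    unknown <- setdiff(names(colors), group_names)
    if (length(unknown))
      bk_stop("grouping_error", "colour given for undeclared group '%s'",
              unknown[1])
    cols[names(colors)] <- unname(colors)
  }
  structure(list(group_names = group_names, colors = cols,
                 membership = membership),
            class = "group_assignment")
}

default_group_colors <- function(k) {
  if (k == 0L) return(character())
  base <- c("#1F77B4", "#FF7F0E", "#2CA02C", "#D62728", "#9467BD",
            "#8C564B", "#E377C2", "#7F7F7F", "#BCBD22", "#17BECF")
  if (k <= length(base)) base[seq_len(k)]
  else substr(grDevices::hcl.colors(k, "Dark 3"), 1, 7)
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf("Groups (%d): %s\n", length(x$group_names),
              paste(x$group_names, collapse = ", ")))
  cat(sprintf("%d sequences assigned\n", length(x$membership)))
  invisible(x)
}

# Resolve membership against an MSA: character vector of length n_seq,
# NA for ungrouped; errors on labels absent from the MSA.
group_vector <- function(groups, msa) {
  miss <- setdiff(names(groups$membership), msa$labels)
  if (length(miss))
    bk_stop("grouping_error", "grouped label '%s' not present in MSA", miss[1])
  g <- rep(NA_character_, msa$n_seq)
  g[match(names(groups$membership), msa$labels)] <- unname(groups$membership)
  g
}

#' Read / write group assignments as TSV
#'
#' Three tab-separated columns: `label`, `group`, `color` (hex; may repeat
#' per group; first occurrence wins).
#'
#' @param path File path.
#' @return [read_groups()]: a `group_assignment`.
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) bk_stop("io_error", "no such file: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "group")
  if (!all(need %in% names(df)))
    bk_stop("io_error", "group TSV must have columns label, group[, color]")
  cols <- NULL
  if ("color" %in% names(df)) {
    keep <- !duplicated(df$group) & !is.na(df$color) & df$color != ""
    if (any(keep)) cols <- stats::setNames(df$color[keep], df$group[keep])
  }
  group_assignment(stats::setNames(df$group, df$label), colors = cols)
}

#' @rdname read_groups
#' @param groups A `group_assignment`.
#' @export
write_groups <- function(groups, path) {
  df <- data.frame(label = names(groups$membership),
                   group = unname(groups$membership),
                   color = unname(groups$colors[groups$membership]),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
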