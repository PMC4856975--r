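#' Indicator (one-hot) coding of an alignment
#'
#' Builds the 0/1 sequence-by-category matrix underlying the joint
#' ordination of sequences and sites: one category per (column, observed
#' symbol) pair, the gap counting as a symbol when
#' `include_gap_category`. Constant columns (a single observed category)
#' carry no inertia under the chi-square metric and are dropped with a
#' notice.
#'
#' @param x An `msa` with at least 2 sequences.
#' @param include_gap_category Treat the gap as a category of its own
#'   (default TRUE); if FALSE, gap cells contribute no category hit.
#' @return Object of class `indicator_matrix`: 0/1 matrix with a
#'   `col_info` attribute (data.frame column, symbol) and an
#'   `included_columns` attribute.
#' @export
build_indicator <- function(x, include_gap_category = TRUE) {
  if (x$n_seq < 2L)
    bk_stop("ordination_error", "need at least 2 sequences")
  m <- msa_matrix(x)
  gap <- x$alphabet$gap_symbol
  blocks <- list()
  info <- list()
  included <- integer()
  for (j in seq_len(x$n_col)) {
    ch <- m[, j]
    symbols <- sort(unique(ch))
    if (!include_gap_category) symbols <- setdiff(symbols, gap)
    if (length(symbols) < 2L) next       # constant: zero inertia
    b <- vapply(symbols, function(s) as.integer(ch == s),
                integer(x$n_seq))
    blocks[[length(blocks) + 1L]] <- b
    info[[length(info) + 1L]] <- data.frame(column = j, symbol = symbols,
                                            stringsAsFactors = FALSE)
    included <- c(included, j)
  }
  n_dropped <- x$n_col - length(included)
  if (n_dropped > 0L)
    bk_log("info", "ordination_ca",
           "dropped %d constant column(s) from the indicator matrix",
           n_dropped)
  if (!length(blocks))
    bk_stop("ordination_error", "no variation: all columns are constant")
  ind <- do.call(cbind, blocks)
  col_info <- do.call(rbind, info)
  colnames(ind) <- paste0("col", col_info$column, ":", col_info$symbol)
  rownames(ind) <- x$labels
  structure(ind, col_info = col_info, included_columns = included,
            class = c("indicator_matrix", "matrix"))
}

#' Correspondence analysis
#'
#' Classical CA of a nonnegative table N under the chi-square metric:
#' P = N / n; S = Dr^-1/2 (P - r c^T) Dc^-1/2; S = U Sigma V^T; row
#' principal coordinates F = Dr^-1/2 U Sigma, column principal
#' coordinates G = Dc^-1/2 V Sigma. Axes are sorted by descending
#' singular value and oriented so that the row coordinate of largest
#' magnitude on each axis is positive (a deterministic sign convention).
#' Total inertia equals the chi-square statistic of N divided by its
#' grand total, and also the sum of squared singular values.
#'
#' @param ind A nonnegative matrix, typically an `indicator_matrix`.
#' @param n_axes Number of axes to keep (truncated to the numerical rank,
#'   with a notice).
#' @return Object of class `ca_result`: `row_coords`, `col_coords`,
#'   `singular_values`, `total_inertia`, `row_masses`, `col_masses`,
#'   `col_info` (when the input carries one).
#' @export
correspondence_analysis <- function(ind, n_axes = 2L) {
  N <- unclass(ind)
  if (any(N < 0)) bk_stop("ordination_error", "table must be nonnegative")
  n <- sum(N)
  if (n <= 0) bk_stop("ordination_error", "table grand total must be positive")
  P <- N / n
  r <- rowSums(P)
  cc <- colSums(P)
  if (any(r == 0) || any(cc == 0))
    bk_stop("ordination_error", "zero row or column margin")
  S <- diag(1 / sqrt(r)) %*% (P - tcrossprod(r, cc)) %*% diag(1 / sqrt(cc))
  sv <- svd(S)
  total_inertia <- sum(sv$d^2)
  rank <- sum(sv$d > 1e-10)
  d <- min(n_axes, rank)
  if (n_axes > rank)
    bk_log("info", "ordination_ca",
           "requested %d axes but rank is %d; truncating", n_axes, rank)
  if (d == 0L) {
    # independence table: no structure, return a single axis of zeros
    F <- matrix(0, nrow(N), 1, dimnames = list(rownames(N), "axis1"))
    G <- matrix(0, ncol(N), 1, dimnames = list(colnames(N), "axis1"))
    res <- list(row_coords = F, col_coords = G, singular_values = numeric(),
                total_inertia = total_inertia, row_masses = r,
                col_masses = cc, col_info = attr(ind, "col_info"))
    return(structure(res, class = "ca_result"))
  }
  U <- sv$u[, seq_len(d), drop = FALSE]
  V <- sv$v[, seq_len(d), drop = FALSE]
  sig <- sv$d[seq_len(d)]
  F <- (U / sqrt(r)) %*% diag(sig, d)
  G <- (V / sqrt(cc)) %*% diag(sig, d)
  for (j in seq_len(d)) {            # sign convention: dominant row positive
    i <- which.max(abs(F[, j]))
    if (F[i, j] < 0) { F[, j] <- -F[, j]; G[, j] <- -G[, j] }
  }
  dimnames(F) <- list(rownames(N), paste0("axis", seq_len(d)))
  dimnames(G) <- list(colnames(N), paste0("axis", seq_len(d)))
  structure(list(row_coords = F, col_coords = G, singular_values = sig,
                 total_inertia = total_inertia, row_masses = r,
                 col_masses = cc, col_info = attr(ind, "col_info")),
            class = "ca_result")
}

#' @export
print.ca_result <- function(x, ...) {
  cat(sprintf("CA: %d rows x %d categories, %d axes kept\n",
              nrow(x$row_coords), nrow(x$col_coords),
              ncol(x$row_coords)))
  if (length(x$singular_values)) {
    expl <- x$singular_values^2 / x$total_inertia * 100
    cat(sprintf("singular values: %s (%% inertia: %s)\n",
                paste(signif(x$singular_values, 4), collapse = ", "),
                paste(sprintf("%.1f", expl), collapse = ", ")))
  }
  cat(sprintf("total inertia: %.6g\n", x$total_inertia))
  invisible(x)
}

#' Categories nearest to a set of sequence points
#'
#' Ranks (column, symbol) categories by Euclidean distance, in principal
#' coordinates, from the centroid of the selected sequence points — the
#' computational counterpart of selecting a cluster of sequences in the
#' CA scatterplot and reading off the co-located sites. Ties break by
#' (column, symbol) order.
#'
#' @param ca A `ca_result` from an indicator matrix.
#' @param rows Nonempty integer set of sequence (row) indices.
#' @param k Number of categories to return (k > m returns all m).
#' @return data.frame with columns `column`, `symbol`, `distance`, ranked
#'   ascending.
#' @export
nearest_categories <- function(ca, rows, k = 10L) {
  rows <- unique(as.integer(rows))
  if (!length(rows))
    bk_stop("bounds_error", "selection is empty")
  if (min(rows) < 1L || max(rows) > nrow(ca$row_coords))
    bk_stop("bounds_error", "row index out of range")
  if (k <= 0L) {
    return(data.frame(column = integer(), symbol = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  }
  centroid <- colMeans(ca$row_coords[rows, , drop = FALSE])
  dd <- sqrt(colSums((t(ca$col_coords) - centroid)^2))
  info <- ca$col_info
  if (is.null(info)) {
    info <- data.frame(column = seq_len(nrow(ca$col_coords)),
                       symbol = rownames(ca$col_coords),
                       stringsAsFactors = FALSE)
  }
  ord <- order(dd, info$column, info$symbol)
  take <- ord[seq_len(min(k, length(ord)))]
  data.frame(column = info$column[take], symbol = info$symbol[take],
             distance = unname(dd[take]), stringsAsFactors = FALSE)
}
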