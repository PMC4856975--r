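#' Train a profile HMM on an alignment
#'
#' With a fixed alignment the state path of every sequence is known, so
#' the model reduces to its match-state emission distributions. Match
#' columns are those whose gap fraction is at most `gap_threshold`
#' (HMMER-style heuristic). Emissions use symmetric Laplace pseudocounts:
#' e_k(b) = (n_k(b) + alpha) / (n_k + alpha * |A|), where n_k(b) counts
#' symbol b among the non-gap characters of match column k.
#'
#' @param x An `msa` with at least 2 sequences.
#' @param gap_threshold Maximum gap fraction for a column to be a match
#'   state, in [0, 1).
#' @param pseudocount Nonnegative pseudocount alpha (default 1, Laplace).
#' @return An object of class `profile_hmm` with fields `match_columns`,
#'   `emissions` (n_match x |alphabet| probability matrix), `pseudocount`,
#'   `alphabet`, `n_col`.
#' @export
train_profile_hmm <- function(x, gap_threshold = 0.5, pseudocount = 1.0) {
  if (x$n_seq < 2L)
    bk_stop("model_error", "need at least 2 sequences to train a profile HMM")
  if (gap_threshold < 0 || gap_threshold >= 1)
    bk_stop("model_error", "gap_threshold must be in [0, 1)")
  if (pseudocount < 0)
    bk_stop("model_error", "pseudocount must be nonnegative")
  m <- msa_matrix(x)
  gap <- x$alphabet$gap_symbol
  gap_frac <- colMeans(m == gap)
  match_cols <- which(gap_frac <= gap_threshold)
  if (!length(match_cols))
    bk_stop("model_error", "no match states: every column exceeds the gap threshold")
  syms <- x$alphabet$symbols
  S <- length(syms)
  em <- matrix(0, nrow = length(match_cols), ncol = S,
               dimnames = list(as.character(match_cols), syms))
  for (i in seq_along(match_cols)) {
    ch <- m[, match_cols[i]]
    ch <- ch[ch != gap]
    cnt <- table(factor(ch, levels = syms))
    em[i, ] <- (as.numeric(cnt) + pseudocount) /
      (length(ch) + pseudocount * S)
  }
  structure(list(match_columns = match_cols, emissions = em,
                 pseudocount = pseudocount, alphabet = x$alphabet,
                 n_col = x$n_col),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("Profile HMM: %d match columns of %d, alphabet '%s', alpha=%g\n",
              length(x$match_columns), x$n_col, x$alphabet$name,
              x$pseudocount))
  invisible(x)
}

#' Emission log-likelihood of one aligned row
#'
#' Sum over match columns of log e_k(row_k); gap positions contribute 0.
#'
#' @param hmm A `profile_hmm`.
#' @param row Aligned symbol string of the model's column count.
#' @return Log-likelihood (natural log).
#' @export
emission_loglik <- function(hmm, row) {
  row <- toupper(row)
  if (nchar(row) != hmm$n_col)
    bk_stop("alignment_shape_error",
            "row length %d does not match model columns %d",
            nchar(row), hmm$n_col)
  ch <- substring(row, hmm$match_columns, hmm$match_columns)
  gap <- hmm$alphabet$gap_symbol
  ll <- 0
  for (i in seq_along(ch)) {
    if (ch[i] == gap) next
    j <- match(ch[i], hmm$alphabet$symbols)
    if (is.na(j))
      bk_stop("alphabet_error", "symbol '%s' not in alphabet '%s'",
              ch[i], hmm$alphabet$name)
    ll <- ll + log(hmm$emissions[i, j])
  }
  ll
}

#' Fisher-score embedding of aligned sequences
#'
#' The gradient of each sequence's emission log-likelihood with respect
#' to the natural (softmax) parameters of the categorical match-state
#' emissions: for sequence x, match column k and symbol b,
#' u_kb(x) = 1[x_k = b] - e_k(b) * 1[x_k != gap]. Scores at a gap
#' position are all zero; at a non-gap position they sum to zero across
#' symbols. Rows follow the MSA order; columns are ordered (match column,
#' alphabet symbol) and labelled "col<k>:<b>".
#'
#' @param hmm A `profile_hmm` with strictly positive emissions.
#' @param x The `msa` to embed (same column count as the model).
#' @param normalize "none" (default) or "length": divide each row by its
#'   number of non-gap match positions.
#' @return Object of class `fisher_embedding`: a numeric matrix
#'   (n_seq x n_match*|A|) with a `col_info` attribute (column, symbol).
#' @export
fisher_scores <- function(hmm, x, normalize = c("none", "length")) {
  normalize <- match.arg(normalize)
  if (x$n_col != hmm$n_col)
    bk_stop("alignment_shape_error",
            "MSA has %d columns but model was trained on %d",
            x$n_col, hmm$n_col)
  if (any(hmm$emissions <= 0))
    bk_stop("numerical_error",
            "zero emission probability: retrain with pseudocount > 0")
  m <- msa_matrix(x)
  syms <- hmm$alphabet$symbols
  S <- length(syms)
  K <- length(hmm$match_columns)
  gap <- hmm$alphabet$gap_symbol
  emb <- matrix(0, nrow = x$n_seq, ncol = K * S)
  for (i in seq_len(K)) {
    ch <- m[, hmm$match_columns[i]]
    nongap <- ch != gap
    block <- -outer(as.numeric(nongap), hmm$emissions[i, ])
    idx <- match(ch, syms)
    sel <- which(nongap)
    block[cbind(sel, idx[sel])] <- block[cbind(sel, idx[sel])] + 1
    emb[, (i - 1L) * S + seq_len(S)] <- block
  }
  col_info <- data.frame(
    column = rep(hmm$match_columns, each = S),
    symbol = rep(syms, times = K), stringsAsFactors = FALSE)
  colnames(emb) <- paste0("col", col_info$column, ":", col_info$symbol)
  rownames(emb) <- x$labels
  if (normalize == "length") {
    len <- rowSums(m[, hmm$match_columns, drop = FALSE] != gap)
    emb <- emb / pmax(len, 1L)
  }
  structure(emb, col_info = col_info, class = c("fisher_embedding", "matrix"))
}

#' Export a Fisher-score embedding as TSV
#'
#' Header row of "col<k>:<symbol>" labels, one data row per sequence
#' (label in the first column). Re-reading reproduces the matrix.
#'
#' @param emb A `fisher_embedding`.
#' @param path Output TSV path.
#' @export
export_embedding <- function(emb, path) {
  df <- data.frame(label = rownames(emb), unclass(emb)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) bk_stop("io_error", "cannot write embedding to '%s'", path)
  invisible(path)
}

#' @rdname export_embedding
#' @export
read_embedding <- function(path) {
  if (!file.exists(path)) bk_stop("io_error", "no such file: %s", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
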