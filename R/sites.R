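#' Per-site classifier screen for specificity-determining sites
#'
#' Trains one linear support-vector machine per alignment column on the
#' one-hot coding of the column's symbol (gap included as a category) and
#' scores each column by leave-one-out cross-validation error against a
#' user-supplied grouping. Columns whose residue cleanly separates the
#' groups get error 0; uninformative columns stay at the majority-class
#' baseline. Only grouped sequences participate.
#'
#' Because the feature vector of a sequence at a column is determined by
#' its symbol alone, all held-out sequences sharing a (symbol, group)
#' pair see the identical training set and receive the identical
#' prediction; LOOCV is therefore computed exactly with one fit per
#' occupied (symbol, group) cell rather than one per sequence.
#'
#' @param x An `msa`.
#' @param groups A `group_assignment` with >= 2 groups of >= 2 members
#'   each (among sequences present in `x`).
#' @param C SVM cost parameter (default 1).
#' @return Object of class `site_scores`: data.frame with one row per
#'   column: `column`, `loocv_error`, `baseline_error`, `marker_opacity`,
#'   `n_used`.
#' @export
detect_sites <- function(x, groups, C = 1.0) {
  g <- group_vector(groups, x)
  used <- which(!is.na(g))
  g <- factor(g[used], levels = groups$group_names)
  tab <- table(g)
  if (length(tab) < 2L)
    bk_stop("grouping_error", "need at least 2 groups, got %d", length(tab))
  if (any(tab < 2L))
    bk_stop("grouping_error", "group '%s' has fewer than 2 members",
            names(tab)[which(tab < 2L)[1]])
  n_used <- length(used)
  m <- msa_matrix(x)[used, , drop = FALSE]
  base_err <- majority_loocv_error(g)
  res <- data.frame(column = seq_len(x$n_col), loocv_error = NA_real_,
                    baseline_error = base_err, marker_opacity = NA_real_,
                    n_used = n_used)
  for (j in seq_len(x$n_col))
    res$loocv_error[j] <- column_loocv_error(m[, j], g, C)
  res$marker_opacity <- opacity_from_errors(res$loocv_error,
                                            res$baseline_error)
  structure(res, class = c("site_scores", "data.frame"))
}

# Exact LOOCV error of leave-one-out majority vote (ties by factor
# level order, i.e. group declaration order).
majority_loocv_error <- function(g) {
  cnt <- table(g)
  err <- 0L
  for (lev in names(cnt)) {
    cl <- cnt
    cl[lev] <- cl[lev] - 1L
    pred <- names(cl)[which.max(cl)]
    if (pred != lev) err <- err + cnt[[lev]]
  }
  as.numeric(err) / length(g)
}

# LOOCV error of a one-vs-rest linear SVM on one-hot symbol features,
# deduplicated over (symbol, group) cells.
column_loocv_error <- function(ch, g, C) {
  symbols <- sort(unique(ch))
  feat <- vapply(symbols, function(s) as.numeric(ch == s),
                 numeric(length(ch)))
  if (!is.matrix(feat)) feat <- matrix(feat, ncol = length(symbols))
  cells <- interaction(ch, g, drop = TRUE)
  err <- 0L
  for (cell in levels(cells)) {
    idx <- which(cells == cell)
    i <- idx[1]
    pred <- svm_ovr_predict(feat[-i, , drop = FALSE], g[-i],
                            feat[i, , drop = FALSE], C)
    if (pred != as.character(g[i])) err <- err + length(idx)
  }
  as.numeric(err) / length(ch)
}

# One-vs-rest linear SVM with argmax over decision values; ties broken
# by group declaration order. Two-group case reduces to a single binary
# machine. Degenerate training sets (constant features) fall back to the
# training majority.
svm_ovr_predict <- function(train_x, train_y, test_x, C) {
  train_y <- droplevels(train_y)
  levs <- levels(train_y)
  if (length(levs) == 1L) return(levs)
  const <- all(apply(train_x, 2, function(v) length(unique(v)) == 1L))
  if (const) {
    cnt <- table(train_y)
    return(names(cnt)[which.max(cnt)])
  }
  scores <- vapply(levs, function(lev) {
    y <- factor(ifelse(train_y == lev, "pos", "neg"),
                levels = c("pos", "neg"))
    if (length(unique(y)) < 2L) return(if (y[1] == "pos") Inf else -Inf)
    fit <- e1071::svm(train_x, y, type = "C-classification",
                      kernel = "linear", cost = C, scale = FALSE)
    dv <- attr(stats::predict(fit, test_x, decision.values = TRUE),
               "decision.values")
    # orient so positive decision value favours 'pos'
    if (grepl("^pos/", colnames(dv)[1])) dv[1, 1] else -dv[1, 1]
  }, numeric(1))
  levs[which.max(scores)]
}

opacity_from_errors <- function(loocv, baseline) {
  ifelse(baseline > 0,
         pmin(1, pmax(0, (baseline - loocv) / baseline)),
         0)
}

#' Marker opacities from a site-score table
#'
#' Maps LOOCV errors to the opacity of the green site markers drawn
#' above a bundle: opacity = clamp((baseline - loocv) / baseline, 0, 1);
#' 1 for a perfectly discriminating site, 0 for one no better than the
#' majority-class baseline.
#'
#' @param table A `site_scores` data.frame.
#' @return Numeric vector of per-column opacities in [0, 1].
#' @export
marker_opacities <- function(table) {
  opacity_from_errors(table$loocv_error, table$baseline_error)
}

#' Exact binomial test of residue covariation
#'
#' Given a condition selection (e.g. "all sequences with Asp at site
#' 10"), tests whether the conditioned sequences carry `target_symbol`
#' at `target_col` more or less often than expected under the null
#' frequency of that symbol — estimated from all sequences (default) or
#' from the complement of the selection. Both one-sided tails and a
#' two-sided p-value are reported; the two-sided default is the minlike
#' convention (total probability of outcomes no more likely than the
#' one observed), with "central" (twice the smaller tail, capped at 1)
#' as an alternative.
#'
#' @param x An `msa`.
#' @param condition A `bk_selection` (or query string) defining the
#'   conditioned sequences; must select at least one.
#' @param target_col 1-based column index.
#' @param target_symbol Single symbol (gap allowed).
#' @param null_from "all_sequences" or "complement".
#' @param two_sided "minlike" or "central".
#' @return Object of class `binom_covariation`: list with `n_trials`,
#'   `n_success`, `null_p`, `p_value_one_sided_less`,
#'   `p_value_one_sided_greater`, `p_value_two_sided`.
#' @export
binomial_covariation_test <- function(x, condition, target_col,
                                      target_symbol,
                                      null_from = c("all_sequences",
                                                    "complement"),
                                      two_sided = c("minlike", "central")) {
  null_from <- match.arg(null_from)
  two_sided <- match.arg(two_sided)
  if (is.character(condition)) condition <- evaluate_query(condition, x)
  target_col <- check_col(x, target_col)
  target_symbol <- toupper(target_symbol)
  sel <- condition$seq_indices
  if (!length(sel)) bk_stop("grouping_error", "condition selects no sequences")
  ch <- substr(x$rows, target_col, target_col)
  k <- sum(ch[sel] == target_symbol)
  n <- length(sel)
  null_idx <- if (null_from == "all_sequences") seq_len(x$n_seq)
              else setdiff(seq_len(x$n_seq), sel)
  if (!length(null_idx))
    bk_stop("grouping_error",
            "complement null population is empty (all sequences selected)")
  p0 <- mean(ch[null_idx] == target_symbol)
  if (p0 %in% c(0, 1) && ((p0 == 0 && k > 0) || (p0 == 1 && k < n)))
    bk_log("warn", "site_detection",
           "degenerate null (p=%g) discordant with observation k=%d/%d",
           p0, k, n)
  p_less <- stats::pbinom(k, n, p0)
  p_greater <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  pk <- stats::dbinom(0:n, n, p0)
  p2 <- switch(two_sided,
    minlike = sum(pk[pk <= pk[k + 1] * (1 + 1e-07)]),
    central = min(1, 2 * min(p_less, p_greater)))
  p2 <- min(1, p2)
  structure(list(n_trials = n, n_success = k, null_p = p0,
                 null_from = null_from, two_sided_convention = two_sided,
                 target_col = target_col, target_symbol = target_symbol,
                 p_value_one_sided_less = p_less,
                 p_value_one_sided_greater = p_greater,
                 p_value_two_sided = p2),
            class = "binom_covariation")
}

#' @export
print.binom_covariation <- function(x, ...) {
  cat(sprintf("Binomial covariation test: %d/%d conditioned sequences carry '%s' at site %d\n",
              x$n_success, x$n_trials, x$target_symbol, x$target_col))
  cat(sprintf("null p = %.6g (%s)\n", x$null_p, x$null_from))
  cat(sprintf("P(<=k) = %.6g  P(>=k) = %.6g  two-sided (%s) = %.6g\n",
              x$p_value_one_sided_less, x$p_value_one_sided_greater,
              x$two_sided_convention, x$p_value_two_sided))
  invisible(x)
}
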