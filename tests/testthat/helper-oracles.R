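# Independent oracles and random generators shared across the suite.
# Everything here is deliberately naive (per-row loops, dense algebra,
# exhaustive enumeration) so it cannot share a code path with the
# implementation it checks.

random_msa <- function(n_seq, n_col, alphabet = builtin_alphabets()$dna,
                       gap_prob = 0) {
  syms <- alphabet$symbols
  pool <- c(syms, if (gap_prob > 0) alphabet$gap_symbol)
  probs <- c(rep((1 - gap_prob) / length(syms), length(syms)),
             if (gap_prob > 0) gap_prob)
  rows <- vapply(seq_len(n_seq), function(i)
    paste(sample(pool, n_col, replace = TRUE, prob = probs),
          collapse = ""), "")
  msa(sprintf("seq%03d", seq_len(n_seq)), rows, alphabet)
}

# naive per-row query interpreter: evaluates the AST on one row at a time
naive_eval_row <- function(node, x, i) {
  switch(node$kind,
    AND = all(vapply(node$children, naive_eval_row, TRUE, x = x, i = i)),
    OR  = any(vapply(node$children, naive_eval_row, TRUE, x = x, i = i)),
    NOT = !naive_eval_row(node$children[[1]], x, i),
    LABEL_MATCH = grepl(node$pattern, x$labels[i], perl = TRUE),
    SEQ_MATCH = {
      subj <- if (isTRUE(node$degap))
        gsub(x$alphabet$gap_symbol, "", x$rows[i], fixed = TRUE)
      else x$rows[i]
      grepl(node$pattern, subj, perl = TRUE)
    },
    SITE_EQ = substr(x$rows[i], node$col, node$col) == node$symbol)
}

naive_query_selection <- function(ast, x) {
  which(vapply(seq_len(x$n_seq), function(i) naive_eval_row(ast, x, i),
               TRUE))
}

random_query_ast <- function(x, depth = 3) {
  make_atom <- function() {
    kind <- sample(c("SEQ_MATCH", "LABEL_MATCH", "SITE_EQ"), 1)
    if (kind == "SITE_EQ") {
      col <- sample(x$n_col, 1)
      sym <- sample(c(x$alphabet$symbols, x$alphabet$gap_symbol), 1)
      sprintf("site(%d) = %s", col, sym)
    } else if (kind == "SEQ_MATCH") {
      sprintf("seq ~ /%s/", paste(sample(x$alphabet$symbols,
                                         sample(1:2, 1), replace = TRUE),
                                  collapse = ""))
    } else {
      sprintf("label ~ /%s/", sample(c("seq0", "1$", "a", "seq00"), 1))
    }
  }
  build <- function(d) {
    if (d == 0 || runif(1) < 0.35) return(make_atom())
    op <- sample(c("AND", "OR", "NOT"), 1)
    if (op == "NOT") sprintf("NOT (%s)", build(d - 1))
    else sprintf("(%s) %s (%s)", build(d - 1), op, build(d - 1))
  }
  build(depth)
}

# central finite differences of emission_loglik under the softmax
# reparameterization theta = log e (per match column)
fd_fisher_row <- function(hmm, row, eps = 1e-6) {
  K <- length(hmm$match_columns)
  S <- ncol(hmm$emissions)
  grad <- numeric(K * S)
  for (k in seq_len(K)) for (b in seq_len(S)) {
    perturb <- function(h) {
      theta <- log(hmm$emissions[k, ])
      theta[b] <- theta[b] + h
      e <- exp(theta) / sum(exp(theta))
      hp <- hmm
      hp$emissions[k, ] <- e
      emission_loglik(hp, row)
    }
    grad[(k - 1) * S + b] <- (perturb(eps) - perturb(-eps)) / (2 * eps)
  }
  grad
}

# dense brute-force CA singular values via the generalized SVD of the
# standardized residual matrix, built entry by entry
bruteforce_ca_sv <- function(N) {
  n <- sum(N)
  P <- N / n
  r <- rowSums(P); cc <- colSums(P)
  S <- matrix(0, nrow(N), ncol(N))
  for (i in seq_len(nrow(N))) for (j in seq_len(ncol(N)))
    S[i, j] <- (P[i, j] - r[i] * cc[j]) / sqrt(r[i] * cc[j])
  sqrt(pmax(0, eigen(t(S) %*% S, symmetric = TRUE)$values))
}

chisq_stat <- function(N) {
  n <- sum(N)
  E <- outer(rowSums(N), colSums(N)) / n
  sum((N - E)^2 / E)
}

# exhaustive binomial tails: sum the pmf term by term via choose()
enum_binom <- function(k, n, p) {
  pmf <- vapply(0:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i),
                numeric(1))
  list(less = sum(pmf[0:k + 1]),
       greater = sum(pmf[(k:n) + 1]),
       minlike = sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-07)]))
}

# nearest-centroid LOOCV on one-hot features: an independent check that
# a perfectly group-separated column yields zero error
nearest_centroid_loocv <- function(ch, g) {
  symbols <- sort(unique(ch))
  feat <- vapply(symbols, function(s) as.numeric(ch == s),
                 numeric(length(ch)))
  err <- 0
  for (i in seq_along(ch)) {
    cent <- lapply(levels(g), function(lev) {
      idx <- setdiff(which(g == lev), i)
      colMeans(feat[idx, , drop = FALSE])
    })
    dd <- vapply(cent, function(ce) sum((feat[i, ] - ce)^2), numeric(1))
    if (levels(g)[which.min(dd)] != as.character(g[i])) err <- err + 1
  }
  err / length(ch)
}

# exhaustive clade test: enumerate every edge bipartition by cutting the
# tree's edges one at a time and flooding the two components
bruteforce_is_split <- function(tree, carriers) {
  tips <- tree$tip.label
  target <- sort(match(carriers, tips))
  if (length(target) %in% c(1L, length(tips) - 1L)) return(TRUE)
  edges <- tree$edge
  n_node <- max(edges)
  for (e in seq_len(nrow(edges))) {
    adj <- lapply(seq_len(n_node), function(i) integer())
    for (r in seq_len(nrow(edges))[-e]) {
      adj[[edges[r, 1]]] <- c(adj[[edges[r, 1]]], edges[r, 2])
      adj[[edges[r, 2]]] <- c(adj[[edges[r, 2]]], edges[r, 1])
    }
    comp <- integer()
    queue <- edges[e, 2]
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      queue <- c(queue, adj[[v]])
    }
    side <- sort(intersect(comp, seq_along(tips)))
    if (identical(side, target) ||
        identical(sort(setdiff(seq_along(tips), side)), target))
      return(TRUE)
  }
  FALSE
}

random_additive_matrix <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, br = function(n) runif(n, 0.1, 2))
  tr$tip.label <- sprintf("L%02d", seq_len(n_leaves))
  D <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(D))
  list(tree = tr, d = D[ord, ord])
}
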