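#' Substitution-matrix sequence kernel
#'
#' Columnwise-mean substitution-score similarity between aligned rows:
#' s(x, y) = (1/n_col) * sum_i sigma(x_i, y_i), with sigma the
#' substitution score, gap-vs-residue scored `gap_score` and gap-vs-gap
#' `gap_gap_score` — gaps affect distances rather than being ignored.
#' Protein alignments use the named substitution matrix (BLOSUM/PAM
#' family); nucleotide alphabets use an identity matrix (match 1,
#' mismatch 0) regardless of `matrix_name`, with a notice.
#'
#' @param x An `msa`.
#' @param matrix_name Substitution matrix name ("BLOSUM62" default; any
#'   BLOSUM/PAM matrix shipped with Biostrings, or "identity").
#' @param gap_score Score for gap vs residue (default -4).
#' @param gap_gap_score Score for gap vs gap (default 0).
#' @return Symmetric similarity matrix with sequence labels as dimnames.
#' @export
kernel_matrix <- function(x, matrix_name = "BLOSUM62", gap_score = -4,
                          gap_gap_score = 0) {
  syms <- x$alphabet$symbols
  gap <- x$alphabet$gap_symbol
  sub <- substitution_scores(matrix_name, syms, x$alphabet$name)
  full <- c(syms, gap)
  sc <- matrix(gap_score, length(full), length(full),
               dimnames = list(full, full))
  sc[syms, syms] <- sub
  sc[gap, gap] <- gap_gap_score
  m <- msa_matrix(x)
  idx <- matrix(match(m, full), nrow = x$n_seq)
  n <- x$n_seq
  K <- matrix(0, n, n, dimnames = list(x$labels, x$labels))
  for (i in seq_len(n)) {
    for (j in i:n) {
      s <- mean(sc[cbind(idx[i, ], idx[j, ])])
      K[i, j] <- s
      K[j, i] <- s
    }
  }
  K
}

substitution_scores <- function(matrix_name, syms, alphabet_name) {
  if (alphabet_name %in% c("dna", "rna") && matrix_name != "identity") {
    bk_log("info", "phylo",
           "nucleotide alphabet: using identity scores instead of %s",
           matrix_name)
    matrix_name <- "identity"
  }
  if (matrix_name == "identity") {
    s <- diag(length(syms))
    dimnames(s) <- list(syms, syms)
    return(s)
  }
  known <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM100",
             "PAM30", "PAM40", "PAM70", "PAM120", "PAM250")
  if (!(matrix_name %in% known))
    bk_stop("config_error", "unknown substitution matrix '%s'", matrix_name)
  env <- new.env()
  utils::data(list = matrix_name, package = "Biostrings", envir = env)
  full <- get(matrix_name, envir = env)
  miss <- setdiff(syms, rownames(full))
  if (length(miss))
    bk_stop("config_error",
            "alphabet symbol '%s' not covered by %s", miss[1], matrix_name)
  full[syms, syms]
}

#' Kernel similarity to squared-norm distance
#'
#' d(x, y) = max(0, s(x,x) + s(y,y) - 2 s(x,y)): the squared feature-
#' space distance induced by the kernel. Negative values (possible for
#' an indefinite substitution-score kernel) are clamped to 0 and
#' counted in the `n_clamped` attribute.
#'
#' @param sim Symmetric similarity matrix.
#' @return Symmetric nonnegative distance matrix, zero diagonal,
#'   attributes `n_clamped` and `n_triangle_violations`.
#' @export
kernel_to_distance <- function(sim) {
  if (!isSymmetric(unname(sim), tol = 1e-08))
    bk_stop("config_error", "similarity matrix must be symmetric")
  d <- outer(diag(sim), diag(sim), `+`) - 2 * sim
  n_clamped <- sum(d < 0 & row(d) != col(d))
  if (n_clamped > 0L)
    bk_log("info", "phylo", "clamped %d negative distance entries to 0",
           n_clamped)
  d[d < 0] <- 0
  diag(d) <- 0
  d <- (d + t(d)) / 2
  dimnames(d) <- dimnames(sim)
  attr(d, "n_clamped") <- n_clamped
  attr(d, "n_triangle_violations") <- count_triangle_violations(d)
  d
}

count_triangle_violations <- function(d, tol = 1e-09) {
  n <- nrow(d)
  if (n > 40L) return(NA_integer_)     # O(n^3); only reported at desk scale
  v <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n))
    if (d[i, j] > d[i, k] + d[k, j] + tol) v <- v + 1L
  v
}

#' Neighbour joining
#'
#' Canonical Saitou-Nei neighbour joining: repeatedly join the pair
#' minimizing Q(i,j) = (n-2) d(i,j) - R_i - R_j (R = row sums), with
#' ties broken by lexicographic order of the pair's labels. Branch
#' lengths follow the standard formulas; negative estimates are clamped
#' to 0 with a notice. Returns an unrooted tree (trifurcating root for
#' n >= 3) as an \pkg{ape} `phylo` object.
#'
#' @param d Symmetric distance matrix with unique labels as dimnames.
#' @return An \pkg{ape} `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  labels <- rownames(d)
  n <- nrow(d)
  if (is.null(labels) || anyDuplicated(labels))
    bk_stop("input_error", "distance matrix needs unique row labels")
  if (n < 2L) bk_stop("input_error", "need at least 2 taxa")
  clamped <- 0L
  clamp <- function(v) {
    if (v < 0) clamped <<- clamped + 1L
    max(0, v)
  }
  if (n == 2L) {
    h <- clamp(d[1, 2]) / 2
    nwk <- sprintf("(%s:%.12g,%s:%.12g);", labels[1], h, labels[2], h)
    return(ape::read.tree(text = nwk))
  }
  # node subtrees held as newick fragments; sort key = smallest leaf label
  frag <- labels
  key <- labels
  D <- unname(d)
  active <- seq_len(n)
  while (length(active) > 3L) {
    m <- length(active)
    Dm <- D[active, active]
    R <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pick <- order(pmin(key[active[cand[, 1]]], key[active[cand[, 2]]]),
                  pmax(key[active[cand[, 1]]], key[active[cand[, 2]]]))[1]
    a <- cand[pick, 1]; b <- cand[pick, 2]
    i <- active[a]; j <- active[b]
    dij <- D[i, j]
    li <- clamp(dij / 2 + (R[a] - R[b]) / (2 * (m - 2)))
    lj <- clamp(dij - (dij / 2 + (R[a] - R[b]) / (2 * (m - 2))))
    new_frag <- sprintf("(%s:%.12g,%s:%.12g)", frag[i], li, frag[j], lj)
    new_key <- min(key[i], key[j])
    # distances from the new node u: d(u,k) = (d(i,k)+d(j,k)-d(i,j))/2
    dk <- (D[i, ] + D[j, ] - dij) / 2
    D <- rbind(cbind(D, dk), c(dk, 0))
    frag <- c(frag, new_frag)
    key <- c(key, new_key)
    u <- nrow(D)
    active <- c(setdiff(active, c(i, j)), u)
  }
  i <- active[1]; j <- active[2]; k <- active[3]
  vi <- clamp((D[i, j] + D[i, k] - D[j, k]) / 2)
  vj <- clamp((D[i, j] + D[j, k] - D[i, k]) / 2)
  vk <- clamp((D[i, k] + D[j, k] - D[i, j]) / 2)
  if (clamped > 0L)
    bk_log("info", "phylo", "clamped %d negative branch length(s) to 0",
           clamped)
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 frag[i], vi, frag[j], vj, frag[k], vk)
  ape::read.tree(text = nwk)
}

#' Read / write Newick trees
#'
#' Thin wrappers around \pkg{ape} with the package's error taxonomy;
#' round-trips topology, labels and branch lengths.
#'
#' @param path Newick file path.
#' @return [read_newick()]: an \pkg{ape} `phylo`.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) bk_stop("io_error", "no such file: %s", path)
  tr <- tryCatch(ape::read.tree(path), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr))
    bk_stop("io_error", "malformed Newick in '%s'", path)
  tr
}

#' @rdname read_newick
#' @param tree An \pkg{ape} `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Spectral clustering of sequences
#'
#' Ng-Jordan-Weiss normalized spectral clustering on the Gaussian
#' affinity A = exp(-d^2 / (2 sigma^2)) (zero diagonal): the rows of the
#' k bottom eigenvectors of the normalized Laplacian are unit-normalized
#' and partitioned by k-means (10 restarts, fixed seed). Clusters are
#' renumbered by first occurrence, so the assignment is deterministic
#' given the seed.
#'
#' @param d Symmetric distance matrix with labels.
#' @param k Number of clusters, 1 <= k <= n.
#' @param sigma Gaussian bandwidth; default the median off-diagonal
#'   distance.
#' @param seed Integer RNG seed for k-means.
#' @return A `group_assignment` with groups "cluster1".."clusterk".
#' @export
spectral_clustering <- function(d, k, sigma = NULL, seed = 1L) {
  n <- nrow(d)
  labels <- rownames(d)
  if (k < 1L || k > n)
    bk_stop("input_error", "k must be in [1, %d]", n)
  if (k == 1L) {
    return(group_assignment(stats::setNames(rep("cluster1", n), labels)))
  }
  if (k == n) {
    return(group_assignment(stats::setNames(paste0("cluster", seq_len(n)),
                                            labels)))
  }
  off <- d[row(d) != col(d)]
  if (is.null(sigma)) sigma <- stats::median(off)
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  A <- exp(-d^2 / (2 * sigma^2))
  diag(A) <- 0
  deg <- rowSums(A)
  deg[deg == 0] <- 1e-12
  Ls <- t(A / sqrt(deg)) / sqrt(deg)     # D^-1/2 A D^-1/2
  Ls <- (Ls + t(Ls)) / 2
  ev <- eigen(Ls, symmetric = TRUE)
  U <- ev$vectors[, seq_len(k), drop = FALSE]
  nrm <- sqrt(rowSums(U^2))
  nrm[nrm == 0] <- 1
  U <- U / nrm
  cl <- with_seed(seed, stats::kmeans(U, centers = k, nstart = 10L,
                                      iter.max = 100L)$cluster)
  relabel <- match(cl, unique(cl))       # renumber by first occurrence
  group_assignment(stats::setNames(paste0("cluster", relabel), labels))
}

# run expr under a local RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Motif-clade concordance (synapomorphy vs homoplasy)
#'
#' Classifies a sequence motif — a conjunction of (column, symbol)
#' requirements — against an unrooted tree: the carriers form a
#' SYNAPOMORPHY when they coincide with one side of some edge
#' bipartition (a monophyletic clade in the unrooted sense), HOMOPLASY
#' otherwise; ABSENT when no sequence carries the motif and UNIVERSAL
#' when all do. Also reports the smallest rooted clade spanning the
#' carriers.
#'
#' @param tree An \pkg{ape} `phylo` whose tip labels are MSA labels.
#' @param x The `msa`.
#' @param motif Nonempty list of `(column, symbol)` pairs, e.g.
#'   `list(c(241, "M"))` or a data.frame with columns column, symbol.
#' @return List: `status` (one of "SYNAPOMORPHY", "HOMOPLASY", "ABSENT",
#'   "UNIVERSAL"), `carriers` (labels), `spanning_clade` (labels of the
#'   minimal rooted clade containing all carriers, NULL when ABSENT).
#' @export
motif_clade_status <- function(tree, x, motif) {
  if (is.data.frame(motif))
    motif <- lapply(seq_len(nrow(motif)),
                    function(i) c(motif$column[i], motif$symbol[i]))
  if (!length(motif)) bk_stop("input_error", "motif must be nonempty")
  miss <- setdiff(tree$tip.label, x$labels)
  if (length(miss))
    bk_stop("input_error", "tree leaf '%s' not present in MSA", miss[1])
  mask <- rep(TRUE, x$n_seq)
  for (pr in motif) {
    col <- check_col(x, as.integer(pr[[1]]))
    sym <- toupper(as.character(pr[[2]]))
    mask <- mask & (substr(x$rows, col, col) == sym)
  }
  carriers <- intersect(x$labels[mask], tree$tip.label)
  tips <- tree$tip.label
  if (!length(carriers))
    return(list(status = "ABSENT", carriers = character(),
                spanning_clade = NULL))
  if (length(carriers) == length(tips))
    return(list(status = "UNIVERSAL", carriers = carriers,
                spanning_clade = tips))
  is_clade <- carriers_form_split(tree, carriers)
  status <- if (is_clade) "SYNAPOMORPHY" else "HOMOPLASY"
  span <- if (length(carriers) == 1L) carriers
          else ape::extract.clade(
            tree, ape::getMRCA(tree, carriers))$tip.label
  list(status = status, carriers = carriers, spanning_clade = span)
}

# TRUE iff the carrier set equals one side of some edge bipartition of
# the unrooted tree (trivial splits included: single tips always do).
carriers_form_split <- function(tree, carriers) {
  tips <- tree$tip.label
  target <- tips %in% carriers
  if (sum(target) == 1L || sum(!target) == 1L) return(TRUE)
  parts <- ape::prop.part(tree)          # tip sets of each internal node
  all_sets <- c(parts, as.list(seq_along(tips)))
  for (s in all_sets) {
    side <- seq_along(tips) %in% s
    if (all(side == target) || all(side == !target)) return(TRUE)
  }
  FALSE
}
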