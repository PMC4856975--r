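test_that("indicator coding has one category per observed (column, symbol)", {
  b <- make_fig1b()
  ind <- build_indicator(b)
  expect_equal(ncol(ind), 10L)            # 2 symbols x 5 columns
  expect_equal(unname(rowSums(unclass(ind))), rep(5, 1000))
  # constant columns are dropped; fully constant MSA is an error
  x <- msa(c("a", "b", "c"), c("AAC", "AAG", "AAG"),
           builtin_alphabets()$dna)
  ind2 <- build_indicator(x)
  expect_equal(attr(ind2, "included_columns"), 3L)
  y <- msa(c("a", "b"), c("AA", "AA"), builtin_alphabets()$dna)
  expect_error(build_indicator(y), class = "ordination_error")
})

test_that("gap handling in the indicator matrix is switchable", {
  x <- msa(c("a", "b", "c"), c("A-", "AC", "GC"),
           builtin_alphabets()$dna)
  with_gaps <- build_indicator(x, include_gap_category = TRUE)
  expect_equal(unname(rowSums(unclass(with_gaps))), rep(2, 3))
  without <- build_indicator(x, include_gap_category = FALSE)
  expect_true(any(rowSums(unclass(without)) < 2))
  expect_false("-" %in% attr(without, "col_info")$symbol)
})

test_that("CA satisfies the defining identities of the chi-square metric", {
  set.seed(7)
  for (rep in 1:20) {
    N <- matrix(rpois(48, 5) + 1, nrow = 8)
    ca <- correspondence_analysis(N, n_axes = 10)
    d <- length(ca$singular_values)
    # singular values descending, bounded by 1
    expect_true(all(diff(ca$singular_values) <= 1e-12))
    expect_true(all(ca$singular_values <= 1 + 1e-9))
    # total inertia = chi-square / grand total = sum of all sv^2
    expect_equal(ca$total_inertia, chisq_stat(N) / sum(N),
                 tolerance = 1e-9)
    # mass-weighted centering of row coordinates
    expect_equal(unname(colSums(ca$row_coords * ca$row_masses)),
                 rep(0, ncol(ca$row_coords)), tolerance = 1e-9)
    # transition formula: rows are weighted averages of column coords
    P <- N / sum(N)
    F_expected <- diag(1 / ca$row_masses) %*% P %*% ca$col_coords %*%
      diag(1 / ca$singular_values[seq_len(ncol(ca$col_coords))],
           ncol(ca$col_coords))
    expect_equal(unname(ca$row_coords), unname(F_expected),
                 tolerance = 1e-8)
  }
})

test_that("singular values match a dense brute-force generalized SVD", {
  set.seed(13)
  for (rep in 1:20) {
    nr <- sample(4:12, 1); nc <- sample(3:8, 1)
    N <- matrix(rpois(nr * nc, 4) + 1, nrow = nr)
    ca <- correspondence_analysis(N, n_axes = min(nr, nc))
    sv_oracle <- bruteforce_ca_sv(N)
    d <- length(ca$singular_values)
    expect_equal(ca$singular_values, sv_oracle[seq_len(d)],
                 tolerance = 1e-10)
  }
})

test_that("an independence table has zero inertia and zero coordinates", {
  N <- outer(c(2, 3, 5), c(1, 4, 2, 3))   # rank-1: perfectly independent
  expect_message(ca <- correspondence_analysis(N), "truncating")
  expect_length(ca$singular_values, 0L)
  expect_equal(ca$total_inertia, 0, tolerance = 1e-12)
  expect_true(all(ca$row_coords == 0))
  expect_true(all(ca$col_coords == 0))
})

test_that("axis 1 separates the two row motifs of the toy alignment", {
  b <- make_fig1b()
  ca <- correspondence_analysis(build_indicator(b), n_axes = 2)
  pts <- unique(round(ca$row_coords, 9))
  expect_equal(nrow(pts), 2L)
  aat <- which(b$rows == "AATTT")
  tta <- which(b$rows == "TTAAA")
  expect_true(all(ca$row_coords[aat, 1] * ca$row_coords[tta, 1] < 0))
  # deterministic sign convention: dominant row coordinate positive
  expect_true(max(ca$row_coords[, 1]) ==
              max(abs(ca$row_coords[, 1])))
})

test_that("duplicating rows of the indicator leaves column coords unchanged", {
  set.seed(19)
  x <- random_msa(10, 6, gap_prob = 0.1)
  ind <- build_indicator(x)
  ca1 <- correspondence_analysis(unclass(ind), n_axes = 2)
  ca2 <- correspondence_analysis(rbind(unclass(ind), unclass(ind)),
                                 n_axes = 2)
  expect_equal(unname(ca1$col_coords), unname(ca2$col_coords),
               tolerance = 1e-9)
})

test_that("nearest_categories finds a planted group marker", {
  spec <- planted_msa_spec(
    group_sizes = c(g1 = 8L, g2 = 8L), n_col = 10,
    planted_sites = list(list(column = 7,
                              symbols = c(g1 = "M", g2 = "L"))),
    seed = 5L)
  fx <- make_planted_msa(spec)
  ca <- correspondence_analysis(build_indicator(fx$msa), n_axes = 2)
  g1_rows <- which(startsWith(fx$msa$labels, "g1"))
  top <- nearest_categories(ca, g1_rows, k = 3)
  # exhaustive oracle: distances of every category to the g1 centroid
  centroid <- colMeans(ca$row_coords[g1_rows, ])
  dd <- apply(ca$col_coords, 1, function(p) sqrt(sum((p - centroid)^2)))
  expect_equal(top$distance[1], unname(min(dd)), tolerance = 1e-12)
  expect_equal(top$column[1], 7)
  expect_equal(top$symbol[1], "M")
  # selecting every row centres the selection at the origin
  all_rank <- nearest_categories(ca, seq_len(fx$msa$n_seq),
                                 k = nrow(ca$col_coords))
  norms <- sqrt(rowSums(ca$col_coords^2))
  expect_equal(all_rank$distance, unname(sort(norms)), tolerance = 1e-9)
  expect_equal(nrow(nearest_categories(ca, g1_rows, k = 0)), 0L)
  # k beyond m returns all m
  expect_equal(nrow(nearest_categories(ca, g1_rows, k = 1e6)),
               nrow(ca$col_coords))
})
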