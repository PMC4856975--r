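two_group_msa <- function(rows_a, rows_b,
                          alphabet = builtin_alphabets()$protein) {
  n <- length(rows_a) + length(rows_b)
  labels <- sprintf("s%02d", seq_len(n))
  g <- c(rep("ga", length(rows_a)), rep("gb", length(rows_b)))
  list(msa = msa(labels, c(rows_a, rows_b), alphabet),
       groups = group_assignment(stats::setNames(g, labels)))
}

test_that("perfectly separating columns reach LOOCV error 0", {
  b <- make_fig1b()
  tab <- detect_sites(b, bundlekit:::two_motif_groups(b))
  expect_equal(tab$loocv_error, rep(0, 5))
  expect_equal(tab$n_used, rep(1000L, 5))
  expect_equal(tab$marker_opacity, rep(1, 5))
  # cross-check one column against a nearest-centroid LOOCV oracle
  ch <- substr(b$rows, 1, 1)
  g <- factor(ifelse(b$rows == "AATTT", "ga", "gb"))
  expect_equal(nearest_centroid_loocv(ch[c(1:5, 501:505)],
                                      droplevels(g[c(1:5, 501:505)])), 0)
})

test_that("a constant column carries no information", {
  fx <- two_group_msa(c("AM", "AM", "AL"), c("AM", "AL", "AL"))
  tab <- detect_sites(fx$msa, fx$groups)
  expect_gte(tab$loocv_error[1], 0.5)     # column 1 constant 'A'
  expect_equal(tab$marker_opacity[1], 0)
})

test_that("the uniquely informative column is the error argmin", {
  set.seed(23)
  for (rep in 1:5) {
    spec <- planted_msa_spec(
      group_sizes = c(g1 = 8L, g2 = 8L), n_col = 12,
      planted_sites = list(list(column = 3,
                                symbols = c(g1 = "W", g2 = "P"))),
      seed = rep)
    fx <- make_planted_msa(spec)
    tab <- detect_sites(fx$msa, fx$groups)
    expect_equal(which.min(tab$loocv_error), 3L)
    expect_equal(tab$loocv_error[3], 0)
  }
})

test_that("detect_sites validates its grouping preconditions", {
  b <- make_fig1b()
  labels <- b$labels
  expect_error(
    detect_sites(b, group_assignment(stats::setNames("g1", labels[1]))),
    class = "grouping_error")
  one_small <- group_assignment(
    stats::setNames(c("g1", "g1", "g2"), labels[1:3]))
  expect_error(detect_sites(b, one_small), class = "grouping_error")
  expect_error(
    detect_sites(b, group_assignment(c(nosuch = "g1", nosuch2 = "g2"))),
    class = "grouping_error")
})

test_that("detect_sites is invariant to row order and group renaming", {
  spec <- planted_msa_spec(
    group_sizes = c(g1 = 6L, g2 = 6L, g3 = 6L), n_col = 8,
    planted_sites = list(list(column = 5,
                              symbols = c(g1 = "K", g2 = "E", g3 = "F"))),
    seed = 99L)
  fx <- make_planted_msa(spec)
  tab <- detect_sites(fx$msa, fx$groups)
  perm <- rev(seq_len(fx$msa$n_seq))
  xm <- msa(fx$msa$labels[perm], fx$msa$rows[perm], fx$msa$alphabet)
  tab_p <- detect_sites(xm, fx$groups)
  expect_equal(tab_p$loocv_error, tab$loocv_error)
  renamed <- group_assignment(stats::setNames(
    paste0("x_", unname(fx$groups$membership)),
    names(fx$groups$membership)))
  tab_r <- detect_sites(fx$msa, renamed)
  expect_equal(tab_r$loocv_error, tab$loocv_error)
})

test_that("three-group one-vs-rest screening recovers the planted site", {
  spec <- planted_msa_spec(
    group_sizes = c(g1 = 5L, g2 = 5L, g3 = 5L), n_col = 10,
    planted_sites = list(list(column = 9,
                              symbols = c(g1 = "H", g2 = "L", g3 = "D"))),
    seed = 7L)
  fx <- make_planted_msa(spec)
  tab <- detect_sites(fx$msa, fx$groups)
  expect_equal(tab$loocv_error[9], 0)
  expect_equal(which.min(tab$loocv_error), 9L)
})

test_that("marker opacity is the clamped baseline-relative improvement", {
  tab <- data.frame(loocv_error = c(0, 0.5, 0.25, 0.7, 0.2),
                    baseline_error = c(0.5, 0.5, 0.5, 0.5, 0))
  expect_equal(marker_opacities(tab), c(1, 0, 0.5, 0, 0))
})

test_that("the binomial test matches closed forms and the exhaustive oracle", {
  dna <- builtin_alphabets()$dna
  # k=0 of n=10 at p=0.5: lower tail is 0.5^10
  y <- msa(sprintf("s%02d", 1:20), c(rep("C", 10), rep("A", 10)), dna)
  res <- binomial_covariation_test(y, selection(1:10, msa = y), 1, "A")
  expect_equal(res$null_p, 0.5)
  expect_equal(res$n_success, 0L)
  expect_equal(res$p_value_one_sided_less, 0.5^10)
  # P(<=k) + P(>=k) = 1 + P(=k)
  expect_equal(res$p_value_one_sided_less + res$p_value_one_sided_greater,
               1 + dbinom(0, 10, 0.5))
  # k = n p exactly: two-sided p = 1
  z <- msa(sprintf("s%02d", 1:20),
           c(rep("A", 5), rep("C", 5), rep("A", 5), rep("C", 5)), dna)
  res2 <- binomial_covariation_test(z, selection(1:10, msa = z), 1, "A")
  expect_equal(res2$n_success, 5L)
  expect_equal(res2$p_value_two_sided, 1)
})

test_that("both tails and both conventions agree with enumeration for n <= 12", {
  for (n in c(3, 7, 12)) for (p in c(0.1, 0.5, 0.9)) for (k in 0:n) {
    oracle <- enum_binom(k, n, p)
    p_less <- pbinom(k, n, p)
    p_greater <- pbinom(k - 1, n, p, lower.tail = FALSE)
    expect_equal(p_less, oracle$less, tolerance = 1e-12)
    expect_equal(p_greater, oracle$greater, tolerance = 1e-12)
    # cross-check the minlike convention against stats::binom.test
    expect_equal(oracle$minlike,
                 stats::binom.test(k, n, p)$p.value, tolerance = 1e-9)
  }
})

test_that("null population choice and degenerate nulls behave as specified", {
  dna <- builtin_alphabets()$dna
  x <- msa(sprintf("s%02d", 1:12),
           c(rep("AG", 4), rep("AT", 4), rep("CT", 4)), dna)
  sel <- evaluate_query("site(1) = A", x)      # 8 sequences
  all_null <- binomial_covariation_test(x, sel, 2, "G",
                                        null_from = "all_sequences")
  expect_equal(all_null$null_p, 4 / 12)
  comp_null <- suppressMessages(
    binomial_covariation_test(x, sel, 2, "G", null_from = "complement"))
  expect_equal(comp_null$null_p, 0)
  expect_true(all(c(all_null$p_value_two_sided,
                    comp_null$p_value_two_sided) >= 0))
  expect_true(all(c(all_null$p_value_two_sided,
                    comp_null$p_value_two_sided) <= 1))
  # central convention is twice the smaller tail, capped
  cen <- binomial_covariation_test(x, sel, 2, "G", two_sided = "central")
  expect_equal(cen$p_value_two_sided,
               min(1, 2 * min(cen$p_value_one_sided_less,
                              cen$p_value_one_sided_greater)))
  expect_error(
    binomial_covariation_test(x, selection(integer(), msa = x), 1, "A"),
    class = "grouping_error")
  expect_error(binomial_covariation_test(x, sel, 99, "A"),
               class = "bounds_error")
})
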