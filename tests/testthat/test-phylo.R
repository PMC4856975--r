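test_that("the substitution kernel averages columnwise scores", {
  p <- builtin_alphabets()$protein
  x <- msa(c("s1", "s2", "s3"), c("AR", "AK", "--"), p)
  K <- kernel_matrix(x)
  expect_equal(K["s1", "s1"], (4 + 5) / 2)       # BLOSUM62 A/A=4, R/R=5
  expect_equal(K["s1", "s2"], (4 + 2) / 2)       # A/A=4, R/K=2
  expect_equal(K["s3", "s3"], 0)                 # gap-gap default 0
  expect_equal(K["s1", "s3"], -4)                # gap-residue default -4
  expect_true(isSymmetric(K))
  expect_error(kernel_matrix(x, "NOSUCH"), class = "config_error")
  # nucleotide alphabets fall back to identity scores
  d <- msa(c("a", "b"), c("ACGT", "ACGA"), builtin_alphabets()$dna)
  expect_message(Kd <- kernel_matrix(d), "identity")
  expect_equal(Kd["a", "b"], 3 / 4)
})

test_that("kernel distances are clamped squared feature-space norms", {
  p <- builtin_alphabets()$protein
  x <- msa(c("s1", "s2", "s3"), c("AR", "AK", "AR"), p)
  d <- kernel_to_distance(kernel_matrix(x))
  expect_equal(d["s1", "s2"], 4.5 + 4.5 - 2 * 3)
  expect_equal(d["s1", "s3"], 0)                 # identical rows
  expect_equal(diag(d), rep(0, 3), ignore_attr = TRUE)
  expect_true(all(d >= 0))
  expect_true(isSymmetric(unname(d)))
  expect_false(is.na(attr(d, "n_triangle_violations")))
})

test_that("NJ reproduces three-point branch lengths and the n=2 edge", {
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d3)
  bl <- stats::setNames(tr$edge.length,
                        tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 2, C = 3))
  d2 <- matrix(c(0, 5, 5, 0), 2, dimnames = list(c("x", "y"),
                                                 c("x", "y")))
  tr2 <- neighbor_joining(d2)
  expect_equal(sum(tr2$edge.length), 5)
  expect_error(neighbor_joining(d2[1, 1, drop = FALSE]),
               class = "input_error")
})

test_that("NJ recovers random additive trees exactly", {
  set.seed(47)
  for (rep in 1:15) {
    gen <- random_additive_matrix(sample(6:10, 1))
    tr <- neighbor_joining(gen$d)
    expect_equal(phangorn::RF.dist(ape::unroot(gen$tree), tr), 0)
    path <- ape::cophenetic.phylo(tr)[rownames(gen$d), colnames(gen$d)]
    expect_lt(max(abs(path - gen$d)), 1e-9)
    # independent oracle: ape's own NJ finds the same topology
    expect_equal(phangorn::RF.dist(ape::nj(gen$d), tr), 0)
  }
})

test_that("negative NJ branch estimates are clamped to zero", {
  d <- matrix(c(0, 1, 10, 10.5,
                1, 0, 10.2, 10.4,
                10, 10.2, 0, 0.1,
                10.5, 10.4, 0.1, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- suppressMessages(neighbor_joining(d))
  expect_true(all(tr$edge.length >= 0))
})

test_that("Newick I/O round-trips topology, labels and branch lengths", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((a:1,b:2):0.5,c:3);", f)
  tr <- read_newick(f)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  set.seed(53)
  for (rep in 1:10) {
    gen <- random_additive_matrix(sample(4:12, 1))
    tr <- neighbor_joining(gen$d)
    g <- withr::local_tempfile(fileext = ".nwk")
    write_newick(tr, g)
    back <- read_newick(g)
    expect_equal(phangorn::RF.dist(back, tr), 0)
    expect_equal(sort(back$edge.length), sort(tr$edge.length),
                 tolerance = 1e-9)
  }
  writeLines("((a:1,b:2", f)
  expect_error(read_newick(f), class = "io_error")
})

test_that("spectral clustering recovers planted blocks deterministically", {
  n <- 14
  d <- matrix(10, n, n)
  d[1:7, 1:7] <- 0.1
  d[8:n, 8:n] <- 0.1
  diag(d) <- 0
  rownames(d) <- colnames(d) <- sprintf("s%02d", 1:n)
  g <- spectral_clustering(d, 2, seed = 7L)
  expect_equal(unname(g$membership[1:7]), rep("cluster1", 7))
  expect_equal(unname(g$membership[8:n]), rep("cluster2", 7))
  g2 <- spectral_clustering(d, 2, seed = 7L)
  expect_identical(g$membership, g2$membership)
  expect_length(unique(spectral_clustering(d, 1)$membership), 1L)
  gk <- spectral_clustering(d, n)
  expect_length(unique(gk$membership), n)
  expect_error(spectral_clustering(d, n + 1), class = "input_error")
})

test_that("motif/clade status matches brute-force bipartition enumeration", {
  p <- builtin_alphabets()$protein
  # hand-built cases
  x <- msa(paste0("t", 1:5), c("AM", "AM", "AL", "AL", "AL"), p)
  mono <- ape::read.tree(text = "((t1:1,t2:1):1,(t3:1,(t4:1,t5:1):1):1);")
  expect_equal(motif_clade_status(mono, x, list(c(2, "M")))$status,
               "SYNAPOMORPHY")
  para <- ape::read.tree(text = "((t1:1,t3:1):1,(t2:1,(t4:1,t5:1):1):1);")
  res <- motif_clade_status(para, x, list(c(2, "M")))
  expect_equal(res$status, "HOMOPLASY")
  expect_setequal(res$carriers, c("t1", "t2"))
  expect_equal(motif_clade_status(mono, x, list(c(2, "W")))$status,
               "ABSENT")
  expect_equal(motif_clade_status(mono, x, list(c(1, "A")))$status,
               "UNIVERSAL")
  expect_error(motif_clade_status(mono, x, list(c(99, "A"))),
               class = "bounds_error")

  # randomized agreement with the exhaustive edge-cut oracle
  set.seed(61)
  dna <- builtin_alphabets()$dna
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    tr <- ape::rtree(n)
    tr$tip.label <- sprintf("t%02d", seq_len(n))
    rows <- paste0(sample(c("A", "C"), n, replace = TRUE),
                   sample(c("G", "T"), n, replace = TRUE))
    xx <- msa(tr$tip.label, rows, dna)
    motif <- list(c(1, sample(c("A", "C"), 1)))
    res <- motif_clade_status(tr, xx, motif)
    carriers <- res$carriers
    if (res$status %in% c("SYNAPOMORPHY", "HOMOPLASY")) {
      expect_equal(res$status == "SYNAPOMORPHY",
                   bruteforce_is_split(tr, carriers))
      expect_true(all(carriers %in% res$spanning_clade))
    }
  }
})
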