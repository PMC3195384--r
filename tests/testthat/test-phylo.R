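test_that("complete deletion removes columns with any missing residue", {
  res <- c(a = "FYKL", b = "FYKL", c = "FYKL")
  expect_equal(as.character(complete_deletion(res)), unname(res))

  res2 <- c(a = "FYKL", b = "FXKL", c = "FY-L")
  cd <- complete_deletion(res2)
  expect_equal(as.character(cd), c("FL", "FL", "FL"))
  expect_equal(attr(cd, "kept_columns"), c(1L, 4L))

  expect_error(complete_deletion(c(a = "XY", b = "YX")),
               class = "pbrselect_nodata")

  set.seed(51)
  m <- matrix(sample(c("A", "F", "X"), 60, replace = TRUE, prob = c(4, 4, 1)),
              nrow = 5)
  strs <- apply(m, 1, paste, collapse = "")
  expected <- sum(colSums(m == "X") == 0)
  if (expected > 0) {
    expect_equal(nchar(complete_deletion(strs)[[1]]), expected)
  }
})

test_that("Poisson distance matches its closed form", {
  expect_equal(poisson_distance("FFFF", "FFFF"), 0)
  expect_equal(poisson_distance(paste(rep("F", 10), collapse = ""),
                                paste(c("Y", rep("F", 9)), collapse = "")),
               -log(0.9))
  expect_error(poisson_distance("FY", "YF"), class = "pbrselect_saturation")
  # convexity: d >= p
  set.seed(52)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:10) {
    a <- paste(sample(aas, 30, TRUE), collapse = "")
    b <- paste(sample(aas, 30, TRUE), collapse = "")
    p <- mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    if (p < 1) expect_gte(poisson_distance(a, b), p)
  }
})

test_that("3-taxon NJ reproduces the closed-form branch lengths", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[["A"]], (3 + 4 - 5) / 2)
  expect_equal(len[["B"]], (3 + 5 - 4) / 2)
  expect_equal(len[["C"]], (4 + 5 - 3) / 2)
  expect_equal(attr(tr, "total_length"), 6)
})

test_that("NJ validates its input matrix", {
  D <- matrix(c(0, 1, 1, 0), 2)
  expect_error(nj_tree(D), "at least 3")
  D3 <- matrix(c(0, 1, 2, 9, 0, 3, 2, 3, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(D3), "symmetric")
  D4 <- matrix(c(0, -1, 1, -1, 0, 1, 1, 1, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(D4), "nonnegative")
})

test_that("NJ recovers additive trees exactly, matching ape", {
  set.seed(53)
  for (i in 1:15) {
    case <- random_additive_case(sample(4:8, 1))
    tr <- nj_tree(case$D)
    # additive recovery: leaf-to-leaf path lengths reproduce the input
    co <- ape::cophenetic.phylo(tr)[rownames(case$D), colnames(case$D)]
    expect_equal(co, case$D, tolerance = 1e-8)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
                                           ape::unroot(case$tree))), 0)
    expect_equal(attr(tr, "total_length"), sum(case$tree$edge.length),
                 tolerance = 1e-8)
    # agreement with the reference implementation on the same matrix
    expect_equal(as.numeric(ape::dist.topo(
      ape::unroot(tr), ape::unroot(ape::nj(case$D)))), 0)
  }
})

test_that("NJ output is invariant under taxon-order permutation", {
  set.seed(54)
  case <- random_additive_case(7)
  tr1 <- nj_tree(case$D)
  perm <- sample(nrow(case$D))
  tr2 <- nj_tree(case$D[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr1),
                                         ape::unroot(tr2))), 0)
  co1 <- ape::cophenetic.phylo(tr1)
  co2 <- ape::cophenetic.phylo(tr2)[rownames(co1), colnames(co1)]
  expect_equal(co1, co2, tolerance = 1e-10)
})

test_that("negative branch lengths are clamped with the deficit logged", {
  # a non-additive matrix known to produce a negative NJ branch
  D <- matrix(c(0, 2, 2, 6,
                2, 0, 1, 5,
                2, 1, 0, 1,
                6, 5, 1, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
  expect_gt(attr(tr, "clamped"), 0)
})

test_that("bootstrap supports separate two simulated clades", {
  set.seed(55)
  anc <- random_sense_sequence(40)
  mutate_some <- function(s, k) {
    cods <- substring(s, 3 * (1:40) - 2, 3 * (1:40))
    idx <- sample(40, k)
    cods[idx] <- sample(sense_codons, k, TRUE)
    paste(cods, collapse = "")
  }
  base1 <- mutate_some(anc, 8)
  base2 <- mutate_some(anc, 8)
  seqs <- c(vapply(1:4, function(i) mutate_some(base1, 3), ""),
            vapply(1:4, function(i) mutate_some(base2, 3), ""))
  x <- allele_set(paste0(rep(c("p", "q"), each = 4), 1:4), seqs)
  res <- complete_deletion(translate_alleles(x))
  tr <- bootstrap_supports(res, replicates = 100, seed = 7)
  supp <- attr(tr, "supports")
  expect_true(all(supp >= 0 & supp <= 100))
  # the clade-separating bipartition must be strongly supported
  sig <- names(supp)
  grp <- vapply(strsplit(sig, "\r", fixed = TRUE), function(s)
    all(startsWith(s, "p")) || all(startsWith(s, "q")), TRUE)
  full_split <- lengths(strsplit(sig, "\r", fixed = TRUE)) == 4 & grp
  expect_true(any(full_split))
  expect_gt(max(supp[full_split]), 90)
  # determinism
  tr2 <- bootstrap_supports(res, replicates = 100, seed = 7)
  expect_identical(attr(tr2, "supports"), supp)
})

test_that("newick round-trips preserve lengths and supports", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  rt <- read_newick(f)
  expect_equal(sort(rt$tip.label), c("A", "B", "C"))
  expect_equal(attr(rt, "total_length"), attr(tr, "total_length"),
               tolerance = 1e-6)

  set.seed(56)
  seqs <- vapply(1:6, function(i) random_sense_sequence(30), "")
  x <- allele_set(paste0("s", 1:6), seqs)
  tb <- bootstrap_supports(complete_deletion(translate_alleles(x)),
                           replicates = 50, seed = 3)
  f2 <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tb, f2)
  rt2 <- read_newick(f2)
  expect_equal(abs(attr(rt2, "total_length") - attr(tb, "total_length")) <
                 1e-5, TRUE)
  expect_equal(sort(rt2$node.label), sort(tb$node.label))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(rt2),
                                         ape::unroot(tb))), 0)
})
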