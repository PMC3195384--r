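test_that("site counts match hand-derived values and reject non-sense input", {
  f <- codon_site_counts("TTT")
  expect_equal(f$syn_sites, 1 / 3)
  expect_equal(f$nonsyn_sites, 8 / 3)
  m <- codon_site_counts("ATG")
  expect_equal(m$syn_sites, 0)
  expect_equal(m$nonsyn_sites, 3)
  expect_equal(codon_site_counts("GGG")$syn_sites, 1)
  expect_error(codon_site_counts("TAA"), class = "pbrselect_undefined_codon")
  expect_error(codon_site_counts("TNG"), class = "pbrselect_undefined_codon")
})

test_that("pathway differences average over admissible orderings", {
  expect_equal(pathway_differences("TTT", "TTT")[c("syn_diffs", "nonsyn_diffs")],
               list(syn_diffs = 0, nonsyn_diffs = 0))
  # single step Phe -> Leu
  p1 <- pathway_differences("TTT", "TTA")
  expect_equal(p1$syn_diffs, 0)
  expect_equal(p1$nonsyn_diffs, 1)
  # two orderings: TTT>GTT>GTA = (1 syn, 1 nonsyn); TTT>TTA>GTA = (0, 2)
  p2 <- pathway_differences("TTT", "GTA")
  expect_equal(p2$syn_diffs, 0.5)
  expect_equal(p2$nonsyn_diffs, 1.5)
})

test_that("pairwise pN/pS composes site and difference counting", {
  same <- pairwise_pn_ps("TTTATG", "TTTATG")
  expect_equal(same$pN, 0)
  expect_equal(same$pS, 0)
  # TTT vs TTA is one nonsynonymous difference; sites averaged over the two
  # sequences: N = ((8/3 + 3) + (7/3 + 3)) / 2 = 5.5
  x <- pairwise_pn_ps("TTTATG", "TTAATG")
  expect_equal(x$N, 5.5)
  expect_equal(x$pN, 1 / 5.5)
  expect_equal(x$pS, 0)
  expect_equal(x$S + x$N, 3 * x$compared_codons)
  # gap codons are excluded pairwise
  g <- pairwise_pn_ps("TT-ATG", "TTAATG")
  expect_equal(g$compared_codons, 1L)
  expect_error(pairwise_pn_ps("---", "TTA"), class = "pbrselect_nodata")
})

test_that("proportions stay in [0,1] for moderately diverged pairs", {
  # unrelated random codon pairs can push the pathway-counted pN a hair
  # above 1 (differences and sites are counted on different scales), but on
  # the method's working range -- sequences sharing recent ancestry, below
  # Jukes-Cantor saturation -- both proportions behave as proportions
  set.seed(31)
  for (i in 1:25) {
    a <- random_sense_sequence(30)
    cods <- substring(a, 3 * (1:30) - 2, 3 * (1:30))
    flip <- sample(30, 8)
    cods[flip] <- sample(sense_codons, 8, TRUE)
    b <- paste(cods, collapse = "")
    x <- pairwise_pn_ps(a, b)
    expect_true(x$pN >= 0 && x$pN <= 1)
    expect_true(x$pS >= 0 && x$pS <= 1)
  }
})

test_that("Jukes-Cantor correction matches the closed form and its domain", {
  expect_equal(jukes_cantor_correct(0), 0)
  expect_equal(jukes_cantor_correct(0.3), -0.75 * log(0.6))
  expect_error(jukes_cantor_correct(0.75), class = "pbrselect_saturation")
  # strictly increasing and >= p
  p <- seq(0, 0.7, by = 0.05)
  d <- vapply(p, jukes_cantor_correct, 0)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
})

test_that("K2P distance matches closed forms and ape's implementation", {
  expect_equal(k2p_distance("ACGT", "ACGT"), 0)
  expect_equal(k2p_distance("AAAA", "GAAA"), -0.5 * log(0.5))
  # transversions only at Q = 0 reduce to the transition-only form
  expect_equal(k2p_distance("AAAAAAAA", "GAAAAAAA"),
               -0.5 * log(1 - 2 * (1 / 8)))
  set.seed(32)
  for (i in 1:10) {
    a <- random_sense_sequence(40)
    ch <- strsplit(a, "")[[1]]
    flip <- sample(length(ch), 20)
    ch[flip] <- sample(c("A", "C", "G", "T"), 20, TRUE)
    b <- paste(ch, collapse = "")
    bin <- ape::as.DNAbin(rbind(a = strsplit(tolower(a), "")[[1]],
                                b = strsplit(tolower(b), "")[[1]]))
    ref <- as.numeric(ape::dist.dna(bin, model = "K80"))
    expect_equal(k2p_distance(a, b), ref, tolerance = 1e-10)
  }
  expect_error(k2p_distance("AAAA", "CCCC"), class = "pbrselect_saturation")
})

test_that("mean pairwise equals the mean of hand-computed pair values", {
  pan <- make_fixture_panel("tiny")
  man <- pan$manifest
  expect_equal(as.numeric(mean_pairwise(pan$alleles, "dN")),
               attr(man, "mean_dN"))
  expect_equal(as.numeric(mean_pairwise(pan$alleles, "dS")),
               attr(man, "mean_dS"))
  # a 2-sequence set returns the single pairwise value
  two <- pan$alleles[c("a", "b")]
  expect_equal(as.numeric(mean_pairwise(two, "dS")), man$dS[1])
  # identical sequences give zero for every statistic
  same <- allele_set(c("u", "v"), rep("TTTATGGGGCATGAACTG", 2))
  for (st in c("dN", "dS", "d_k2p"))
    expect_equal(as.numeric(mean_pairwise(same, st)), 0)
})

test_that("codon bootstrap is deterministic and degenerate-safe", {
  pan <- make_fixture_panel("tiny")
  b1 <- bootstrap_se(pan$alleles, "dN", replicates = 100, seed = 9)
  b2 <- bootstrap_se(pan$alleles, "dN", replicates = 100, seed = 9)
  expect_identical(b1, b2)
  b3 <- bootstrap_se(pan$alleles, "dN", replicates = 100, seed = 10)
  expect_false(identical(b1$std_error, b3$std_error))
  same <- allele_set(c("u", "v"), rep("TTTATGGGGCATGAACTG", 2))
  b0 <- bootstrap_se(same, "dS", replicates = 50, seed = 1)
  expect_equal(b0$estimate, 0)
  expect_equal(b0$std_error, 0)
})

test_that("bootstrap SE shrinks when the alignment doubles in length", {
  pan <- make_fixture_panel("paper-like", seed = 3)
  x <- pan$alleles
  x2 <- allele_set(x$ids, paste0(x$sequences, x$sequences), x$label)
  seL <- bootstrap_se(x, "dN", replicates = 300, seed = 2)$std_error
  se2L <- bootstrap_se(x2, "dN", replicates = 300, seed = 2)$std_error
  expect_lt(se2L, seL)
})

test_that("bootstrap SE is stable across master seeds", {
  pan <- make_fixture_panel("paper-like", seed = 8)
  ses <- vapply(1:5, function(s)
    bootstrap_se(pan$alleles, "dS", replicates = 300, seed = s)$std_error, 0)
  expect_lt(stats::sd(ses) / mean(ses), 0.10)
})

test_that("the Z-test reproduces the reference ratio and normal tail", {
  mk <- function(est, se) structure(
    list(estimate = est, std_error = se, replicates = 100L, seed = 1L,
         statistic = "dN"), class = "substitution_estimate")
  # dN = dS gives Z = 0, p = 0.5
  z0 <- z_test_selection(mk(0.1, 0.02), mk(0.1, 0.03))
  expect_equal(z0$z_stat, 0)
  expect_equal(z0$p_value, 0.5)
  # published-style PBR contrast: 0.332 vs 0.139 -> ratio 2.38 at 2 d.p.
  zt <- z_test_selection(mk(0.332, 0.064), mk(0.139, 0.050))
  expect_equal(zt$ratio, 0.332 / 0.139)
  expect_lt(abs(zt$ratio - 2.38), 0.01)
  expect_equal(zt$z_stat, (0.332 - 0.139) / sqrt(0.064^2 + 0.050^2))
  expect_true(zt$z_stat > 0)
  # Z = 1.645 corresponds to p ~ 0.05 one-tailed
  z5 <- z_test_selection(mk(1.645, 1), mk(0, 0))
  expect_equal(z5$p_value, stats::pnorm(1.645, lower.tail = FALSE))
  expect_equal(round(z5$p_value, 2), 0.05)
  # degenerate variance with unequal estimates is an error
  expect_error(z_test_selection(mk(0.1, 0), mk(0.2, 0)),
               class = "pbrselect_degenerate_variance")
  # undefined ratio flag when dS = 0
  zu <- z_test_selection(mk(0.1, 0.01), mk(0, 0.01))
  expect_false(zu$ratio_defined)
})

test_that("ng_selection fits expose strata through the S3 surface", {
  pan <- make_fixture_panel("tiny")
  fit <- ng_selection(pan$alleles, pan$partition, replicates = 60, seed = 2)
  expect_s3_class(fit, "ng_selection")
  cf <- coef(fit)
  expect_equal(rownames(cf), c("PBR", "Non-PBR", "All"))
  expect_equal(colnames(cf), c("d_k2p", "dN", "dS", "dN_dS", "z", "p"))
  df <- as.data.frame(fit)
  expect_equal(df$n_codons, c(2L, 4L, 6L))
  expect_equal(df$dN[df$stratum == "All"], attr(pan$manifest, "mean_dN"))
  sm <- summary(fit)
  expect_s3_class(sm, "summary.ng_selection")
  expect_output(print(fit), "dN/dS")
  # plot method draws without error
  tf <- withr::local_tempfile(fileext = ".png")
  grDevices::png(tf); on.exit(grDevices::dev.off(), add = TRUE)
  expect_silent(plot(fit))
})
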