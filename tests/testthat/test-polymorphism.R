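test_that("variable-site counting follows the two-distinct-symbols rule", {
  same <- allele_set(c("u", "v"), rep("TTTATG", 2))
  v0 <- variable_sites(same, "nucleotide")
  expect_equal(v0$variable, 0L)
  expect_equal(v0$total, 6L)
  expect_equal(v0$fraction, 0)

  v1 <- variable_sites(c("ACG", "ACT"), "nucleotide")
  expect_equal(v1$variable, 1L)
  expect_equal(v1$fraction, 1 / 3)

  # a column of {A, N} is not variable: missing symbols carry no variation
  v2 <- variable_sites(c("ACG", "NCG"), "nucleotide")
  expect_equal(v2$variable, 0L)

  pan <- make_fixture_panel("tiny")
  vn <- variable_sites(pan$alleles, "nucleotide")
  va <- variable_sites(pan$alleles, "amino_acid")
  expect_equal(vn$variable, 2L)   # codon-1 third base, codon-4 second base
  expect_equal(va$variable, 1L)   # only the His->Arg change shows
})

test_that("amino-acid variability never exceeds nucleotide variability", {
  set.seed(41)
  for (i in 1:10) {
    x <- simulate_alleles(simulation_config(
      n_alleles = 6, n_codons = 20,
      partition = codon_partition(20, 1:5), seed = i))
    vn <- variable_sites(x, "nucleotide")
    va <- variable_sites(x, "amino_acid")
    # each variable residue needs at least one variable base in its codon
    expect_lte(va$variable, vn$variable)
  }
})

test_that("partition variability splits the variable sites exactly", {
  pan <- make_fixture_panel("paper-like", seed = 12)
  res <- translate_alleles(pan$alleles)
  pv <- partition_variability(res, pan$partition)
  total <- variable_sites(res, "amino_acid")
  expect_equal(pv$pbr_variable + pv$nonpbr_variable, total$variable)
  expect_equal(pv$pbr_total, 22L)
  expect_equal(pv$nonpbr_total, 56L)

  mono <- rep(paste(rep("A", 78), collapse = ""), 3)
  pv0 <- partition_variability(mono, pan$partition)
  expect_equal(pv0$pbr_variable, 0L)
  expect_equal(pv0$nonpbr_variable, 0L)

  # variation confined to masked positions leaves the complement clean
  v <- c("AAAA", "CAAA", "CAAA")  # only position 1 varies
  pvm <- partition_variability(v, codon_partition(4, 1))
  expect_equal(pvm$nonpbr_variable, 0L)
  expect_equal(pvm$pbr_variable, 1L)
})

test_that("residue tables list sorted repertoires and flag the PBR", {
  res <- c("FYA", "LYA", "YYA")
  tab <- residue_table(res, codon_partition(3, 2))
  expect_s3_class(tab, "polymorphism_table")
  expect_equal(tab$residues, c("FLY", "Y", "A"))
  expect_equal(tab$is_pbr, c(FALSE, TRUE, FALSE))
  expect_equal(attr(tab, "n_sequences"), 3L)
  # X from gapped codons never enters a repertoire
  tabx <- residue_table(c("FX", "FY"), codon_partition(2, integer(0)))
  expect_equal(tabx$residues, c("F", "Y"))
  # residue numbering offset for exon-2 style display
  tab8 <- residue_table(res, codon_partition(3, 2), residue_offset = 8)
  expect_equal(tab8$position, 9:11)
})

test_that("residue tables ignore sequence order and duplication", {
  set.seed(42)
  x <- simulate_alleles(simulation_config(n_alleles = 8, n_codons = 10,
                                          partition = codon_partition(10, 1:3),
                                          seed = 5))
  res <- translate_alleles(x)
  p <- codon_partition(10, c(1, 2, 3))
  t1 <- residue_table(res, p)
  t2 <- residue_table(rev(res), p)
  t3 <- residue_table(c(res, res[3]), p)
  expect_equal(t1$residues, t2$residues)
  expect_equal(t1$residues, t3$residues)
})

test_that("identity matrix is symmetric with a correct range", {
  same <- allele_set(c("u", "v"), rep("TTTATG", 2))
  expect_equal(attr(identity_matrix(same), "min"), 100)

  x <- allele_set(c("a", "b"), c("AAATTT", "AAATTG"))
  im <- identity_matrix(x)
  expect_equal(im["a", "b"], 100 * 5 / 6)
  expect_identical(im, t(im))

  pan <- make_fixture_panel("tiny")
  imt <- identity_matrix(pan$alleles)
  expect_equal(attr(imt, "min"), 100 * 16 / 18)
  expect_equal(attr(imt, "max"), 100 * 17 / 18)
  expect_true(all(diag(imt) == 100))
})
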