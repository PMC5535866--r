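test_that("residue counting tallies positions exactly and conserves n", {
  cm <- count_residues(c("AAAAKAAAA", "AAAARAAAA"))
  expect_equal(unname(cm["P1", "K"]), 1L)
  expect_equal(unname(cm["P1", "R"]), 1L)
  expect_equal(unname(cm["P5", "A"]), 2L)
  expect_equal(unname(rowSums(cm)), rep(2L, 9))

  expect_error(count_residues(character()), "empty")
  expect_error(count_residues(c("AAAAKAAAA", "SHORT")), "index: 2")

  const <- count_residues(rep("VVHVKSLET", 75))
  expect_equal(unname(apply(const, 1, max)), rep(75L, 9))
  expect_equal(unname(rowSums(const > 0)), rep(1L, 9))
})

test_that("enrichment z-score matches independent arithmetic", {
  expect_equal(delta_sigma(20, 100, 0.2), 0)
  expect_equal(delta_sigma(15, 75, 0.05), (15 - 3.75) / sqrt(3.75 * 0.95))
  expect_equal(delta_sigma(15, 75, 0.05), 5.9604, tolerance = 1e-4)
  expect_equal(delta_sigma(0, 75, 0.05), -1.9868, tolerance = 1e-4)
  expect_equal(delta_sigma(1, 1, 1 / 31), sqrt(30))
  expect_error(delta_sigma(1, 1, 0), "between 0 and 1")
  expect_error(delta_sigma(1, 1, 1), "between 0 and 1")
  expect_error(delta_sigma(1, 0, 0.5), "positive")
})

test_that("enrichment z-score is standard normal under the binomial null", {
  # simulation oracle: draws from the null must give mean ~0, sd ~1
  set.seed(42)
  for (np in list(c(75, 0.05), c(75, 1 / 31), c(200, 0.3))) {
    z <- delta_sigma(rbinom(1e5, np[1], np[2]), np[1], np[2])
    expect_equal(mean(z), 0, tolerance = 0.05)
    expect_equal(sd(z), 1, tolerance = 0.05)
  }
})

test_that("specificity matrices score samplable cells and mask the rest", {
  # null selection: pool drawn exactly at a uniform 2-residue background
  sch <- codon_scheme("ARG")
  cm <- count_residues(c(rep("RRRRRRRRR", 5), rep("KKKKKKKKK", 5)))
  d2 <- build_library_design(rep(list(sch), 9))
  m <- specificity_matrix(cm, d2)
  expect_equal(unname(m$scores[!m$mask]), rep(0, 18))

  # fixed-P1 design: only R and K are scored at P1, 18 cells masked
  cm2 <- count_residues(rep("AAAARSLET", 10))
  m2 <- specificity_matrix(cm2, design_rk)
  expect_equal(sum(m2$mask["P1", ]), 18L)
  expect_false(any(m2$mask[-5, ]))
  expect_true(all(is.na(m2$scores["P1", !colnames(m2$scores) %in%
                                           c("R", "K")])))

  # single observed Trp at an NNK position
  m3 <- specificity_matrix(count_residues("WAAAAAAAA"), design_x)
  expect_equal(unname(m3$scores["P5", "W"]), sqrt(30), tolerance = 1e-12)

  # counts at a masked cell are an inconsistency, not a silent NA
  cmq <- count_residues(rep("AAAAQSLET", 3))
  expect_error(specificity_matrix(cmq, design_rk), "inconsistent")
})

test_that("per-position count deviations sum to zero over the alphabet", {
  set.seed(7)
  peps <- simulate_library(design_rk, 500, seed = 11)
  cm <- count_residues(peps)
  n <- attr(cm, "n")
  for (i in 1:9) {
    open <- design_rk$background[i, ] > 0
    expect_equal(sum(cm[i, open] - n * design_rk$background[i, open]), 0,
                 tolerance = 1e-9)
  }
})

test_that("normalization maps onto -5..+5, preserves zero, sign and rank", {
  cm <- count_residues(c(rep("VVHVKSLET", 60), rep("AAAARAAAA", 15)))
  m <- normalize_matrix(specificity_matrix(cm, design_x))
  expect_equal(max(abs(m$normalized)), 5)
  expect_true(all(abs(m$normalized) <= 5))
  # linearity: {10, -4, 2} -> {5, -2, 1}
  expect_equal(unname(5 * c(10, -4, 2) / 10), c(5, -2, 1))
  # sign and ranking preserved cellwise
  keep <- !m$mask
  expect_equal(sign(m$normalized[keep]), sign(m$scores[keep]))
  expect_equal(rank(m$normalized[keep]), rank(m$scores[keep]))
  # zero maps to zero
  expect_true(all((m$scores[keep] == 0) == (m$normalized[keep] == 0)))

  # all-zero matrix is returned unchanged with a warning
  sch <- codon_scheme("ARG")
  d2 <- build_library_design(rep(list(sch), 9))
  null_m <- specificity_matrix(
    count_residues(c("RRRRRRRRR", "KKKKKKKKK")), d2)
  expect_warning(nm <- normalize_matrix(null_m), "zero")
  expect_equal(unname(nm$normalized[!nm$mask]), rep(0, 18))
})

test_that("normalization is idempotent and the mask policy sets sentinels", {
  cm <- count_residues(rep(c("AAAARSLET", "VVHVKSLET"), c(50, 25)))
  m <- normalize_matrix(specificity_matrix(cm, design_rk))
  again <- m
  again$scores <- m$normalized
  again <- normalize_matrix(again)
  expect_equal(again$normalized, m$normalized)

  expect_equal(unname(m$normalized["P1", "A"]), 0)  # neutral_zero default
  hard <- normalize_matrix(specificity_matrix(cm, design_rk),
                           mask_policy = "hard_exclude")
  expect_equal(unname(hard$normalized["P1", "A"]), -5)
})

test_that("enrichment rate is the plain eluted/control ratio", {
  expect_equal(enrichment_rate(8e5, 1e5), 8)
  expect_equal(enrichment_rate(1000, 1000), 1)
  expect_equal(enrichment_rate(0, 1000), 0)
  expect_error(enrichment_rate(10, 0), "zero")
})

test_that("matrices round-trip through TSV byte-identically", {
  cm <- count_residues(rep(c("AAAARSLET", "VVHVKSLET", "GYRARVRAV"),
                           c(40, 20, 15)))
  m <- normalize_matrix(specificity_matrix(cm, design_rk))
  for (layer in c("scores", "normalized")) {
    f1 <- withr::local_tempfile(fileext = ".tsv")
    f2 <- withr::local_tempfile(fileext = ".tsv")
    write_matrix_tsv(m, f1, layer)
    back <- read_matrix_tsv(f1)
    write_matrix_tsv(back, f2)
    expect_identical(readLines(f1), readLines(f2))
    expect_equal(is.na(back), m$mask & layer == "scores")
  }
})
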