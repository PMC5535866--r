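test_that("simulated libraries follow the design background", {
  pool <- simulate_library(design_rk, 2000, seed = 3)
  expect_true(all(nchar(pool) == 9L))
  expect_true(all(substr(pool, 5, 5) %in% c("R", "K")))

  # empirical NNK frequencies within binomial tolerance (3 sd)
  big <- simulate_library(design_x, 1e5, seed = 4)
  p_w <- mean(substr(big, 1, 1) == "W")
  tol <- 3 * sqrt((1 / 31) * (30 / 31) / 1e5)
  expect_lt(abs(p_w - 1 / 31), tol)

  expect_identical(simulate_library(design_x, 50, seed = 9),
                   simulate_library(design_x, 50, seed = 9))
})

test_that("selection without a score gradient does not enrich", {
  truth <- random_truth_matrix(design_x, seed = 13)
  pool <- simulate_library(design_x, 3000, seed = 14)
  null_sel <- simulate_selection(pool, truth, rounds = 2, b0 = -1, b1 = 0,
                                 clones_sequenced = 500, seed = 15)
  pool_scores <- vapply(pool, score_window, 1, matrix = truth,
                        USE.NAMES = FALSE)
  # survivor scores statistically match the input pool under b1 = 0
  expect_lt(abs(mean(null_sel$rounds$mean_truth_score[2]) -
                  mean(pool_scores)),
            3 * sd(pool_scores) / sqrt(200))
})

test_that("positive selection enriches scores and elutes above control", {
  truth <- random_truth_matrix(design_x, seed = 21)
  pool <- simulate_library(design_x, 10000, seed = 22)
  sel <- simulate_selection(pool, truth, rounds = 3,
                            clones_sequenced = 500, seed = 23)
  expect_true(all(diff(sel$rounds$mean_truth_score) > 0))
  expect_true(all(sel$rounds$rate > 1))
  # enrichment-rate property holds across independent seeds
  rates <- vapply(1:20, function(s) {
    p <- simulate_library(design_x, 2000, seed = 100 + s)
    simulate_selection(p, truth, rounds = 1, clones_sequenced = 10,
                       seed = 200 + s)$rounds$rate
  }, 1)
  expect_true(all(rates > 1))

  expect_identical(
    simulate_selection(pool, truth, rounds = 2, clones_sequenced = 50,
                       seed = 31)$sequenced,
    simulate_selection(pool, truth, rounds = 2, clones_sequenced = 50,
                       seed = 31)$sequenced)

  # harsh stringency on a tiny pool goes extinct with a clear signal
  tiny <- simulate_library(design_x, 20, seed = 33)
  expect_error(simulate_selection(tiny, truth, rounds = 1, b0 = -30,
                                  clones_sequenced = 5, seed = 34),
               "extinct")
})

test_that("planted proteomes embed their sites verbatim with known truth", {
  truth <- random_truth_matrix(design_x, seed = 51)
  sim <- simulate_proteome(truth, n_proteins = 40, n_planted = 8,
                           plant_outside_ecd = c(7, 8), seed = 52)
  expect_equal(nrow(sim$truth), 8L)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    seqi <- sim$proteins[[tr$protein_id]]
    expect_equal(substr(seqi, tr$p1_index - 4, tr$p1_index + 4), tr$window)
  }
  # single protein, single planted consensus window: scan's top hit is it
  one <- simulate_proteome(truth, n_proteins = 1, n_planted = 1,
                           length_range = c(100, 100), seed = 53)
  hits <- scan_protein(one$proteins[[1]], truth,
                       protein_id = names(one$proteins), threshold = -Inf)
  expect_equal(hits$p1_index[1], one$truth$p1_index)
  expect_equal(hits$site_label[1],
               paste0(one$truth$p1_index, "-", one$truth$p1_index + 1))

  # sites planted beyond the ectodomain are dropped by the filter
  ann <- load_topology(sim$topology)
  out_sites <- sim$truth[!sim$truth$in_ecd, ]
  expect_true(nrow(out_sites) >= 1)
  for (i in seq_len(nrow(out_sites)))
    expect_false(site_within_ecd(out_sites$p1_index[i],
                                 ann[[out_sites$protein_id[i]]]))

  # zero planted sites + high threshold: (near) empty prediction set
  none <- simulate_proteome(truth, n_proteins = 20, n_planted = 0,
                            seed = 54)
  preds <- scan_proteome(none$proteins, truth, threshold = 40)
  expect_equal(nrow(preds), 0L)
})

test_that("simulated ELISA readouts recover the programmed efficiency", {
  exact <- simulate_elisa(90, noise_sd = 0, replicates = 4, seed = 61)
  s <- elisa_summary(exact)
  expect_equal(s$mean_da_over_a, 90)
  zero <- elisa_summary(simulate_elisa(0, noise_sd = 0, seed = 62))
  expect_equal(zero$mean_da_over_a, 0)

  # Monte-Carlo: mean recovered efficiency within 1 point of the truth
  means <- vapply(1:500, function(s) {
    r <- simulate_elisa(50, noise_sd = 2, replicates = 4, seed = 1000 + s)
    mean(cleavage_efficiency(r$a450[r$arm == "untreated"],
                             r$a450[r$arm == "treated"]))
  }, 1)
  expect_lt(abs(mean(means) - 50), 1)
})

test_that("selection profiling recovers a known specificity landscape", {
  # headline parameter-recovery property at the study's scale
  truth <- random_truth_matrix(design_x, seed = 71)
  pool <- simulate_library(design_x, 1e4, seed = 72)
  sel <- simulate_selection(pool, truth, rounds = 3,
                            clones_sequenced = 2000, seed = 73)
  rec <- recovery_stats(profile_selection(sel$sequenced, design_x), truth)
  expect_gte(rec$spearman, 0.7)
  expect_gte(rec$top1_agreement, 0.8)

  # with only 75 clones sequenced, recovery degrades but stays informative
  sel75 <- simulate_selection(pool, truth, rounds = 3,
                              clones_sequenced = 75, seed = 73)
  rec75 <- recovery_stats(profile_selection(sel75$sequenced, design_x), truth)
  expect_gte(rec75$spearman, 0.4)
})
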