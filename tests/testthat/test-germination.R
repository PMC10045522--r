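tc_mixed <- germination_time_course(c(10, 5, 5), total_seeds = 20)
tc_partial <- germination_time_course(c(10, 5, 0), total_seeds = 20)

test_that("time-course constructor enforces its invariants", {
  expect_error(germination_time_course(c(10, 15), total_seeds = 20),
               "exceeds")
  expect_error(germination_time_course(c(1, -1)), "non-negative")
  expect_error(germination_time_course(c(1, 1), times = c(2, 1)),
               "strictly increasing")
  expect_error(germination_time_course(c(1, 1), times = c(0, 1)),
               "strictly increasing")
  expect_error(germination_time_course(c(1, 1), total_seeds = 0), "positive")
  expect_error(germination_time_course(c(1.5, 1)), "integers")
  expect_error(germination_time_course(c(1, 1), times = 1), "same length")
})

test_that("worked examples for the seven indices are reproduced", {
  expect_equal(germinability(zero_course()), 0)
  expect_equal(germinability(tc_mixed), 100)
  expect_equal(germinability(tc_partial), 75)

  expect_equal(peak_value(zero_course()), 0)
  expect_equal(peak_value(germination_time_course(c(20))), 20)
  expect_equal(peak_value(tc_mixed), max(10 / 1, 15 / 2, 20 / 3))

  expect_equal(mean_germination_time(germination_time_course(c(20))), 1)
  expect_equal(mean_germination_time(tc_mixed), (10 + 10 + 15) / 20)
  expect_true(is.na(mean_germination_time(zero_course())))

  expect_equal(mean_germination_rate(tc_mixed), 1 / 1.75)
  expect_true(is.na(mean_germination_rate(zero_course())))
  expect_equal(coefficient_of_velocity(tc_mixed), 100 / 1.75)
  expect_true(is.na(coefficient_of_velocity(zero_course())))

  expect_equal(uncertainty_index(zero_course()), 0)
  expect_equal(uncertainty_index(germination_time_course(c(0, 20, 0))), 0)
  expect_equal(uncertainty_index(tc_mixed), 1.5)  # -(.5 lg .5 + 2 * .25 lg .25)

  expect_equal(synchrony_index(zero_course()), 0)
  expect_equal(synchrony_index(germination_time_course(c(20))), 1)
  expect_equal(synchrony_index(tc_mixed), 65 / 190)
})

test_that("algebraic identities and bounds hold on random time courses", {
  set.seed(101)
  for (i in 1:200) {
    tc <- random_time_course()
    n_tot <- sum(tc$counts)
    z <- synchrony_index(tc)
    u <- uncertainty_index(tc)
    expect_gte(z, 0); expect_lte(z, 1)
    expect_gte(u, 0)
    k <- sum(tc$counts > 0)
    if (k > 0) expect_lte(u, log2(k) + 1e-12)
    if (n_tot >= 1) {
      mgt <- mean_germination_time(tc)
      expect_equal(mean_germination_rate(tc) * mgt, 1)
      expect_equal(coefficient_of_velocity(tc),
                   100 * mean_germination_rate(tc))
    }
  }
})

test_that("uncertainty equals log2(k) exactly for equal counts over k days", {
  for (k in 2:5) {
    tc <- germination_time_course(rep(4L, k), total_seeds = 4 * k)
    expect_equal(uncertainty_index(tc), log2(k))
  }
})

test_that("shifting germination one day later adds 1 to MGT, fixes U and Z", {
  set.seed(77)
  for (i in 1:25) {
    tc <- random_time_course()
    if (sum(tc$counts) == 0) next
    shifted <- germination_time_course(tc$counts, times = tc$times + 1,
                                       total_seeds = tc$total_seeds)
    expect_equal(mean_germination_time(shifted),
                 mean_germination_time(tc) + 1)
    expect_equal(uncertainty_index(shifted), uncertainty_index(tc))
    expect_equal(synchrony_index(shifted), synchrony_index(tc))
  }
})

test_that("an all-zero time course yields the degenerate index pattern", {
  idx <- germination_indices(zero_course())
  expect_equal(idx$G, 0)
  expect_equal(idx$PV, 0)
  expect_equal(idx$U, 0)
  expect_equal(idx$Z, 0)
  expect_true(all(is.na(c(idx$MGT, idx$MGR, idx$CVG))))
})

test_that("treatment summaries average per-replicate indices", {
  reps <- do.call(rbind, lapply(1:3, function(r)
    germination_indices(germination_time_course(c(10, 5, 2),
                                                treatment = "CTRL",
                                                replicate = r))))
  s <- summarize_treatment(reps)
  expect_equal(s$mean[s$index == "G"], 85)
  expect_equal(s$dispersion[s$index == "G"], 0)

  # hand-built MGT replicates 2.1, 2.2, 2.3 -> mean 2.2, sd .1
  reps$MGT <- c(2.1, 2.2, 2.3)
  s2 <- summarize_treatment(reps)
  expect_equal(s2$mean[s2$index == "MGT"], 2.2)
  expect_equal(s2$dispersion[s2$index == "MGT"], 0.1)

  sem <- summarize_treatment(reps, dispersion = "sem")
  expect_equal(sem$dispersion[sem$index == "MGT"], 0.1 / sqrt(3))

  mixed <- reps
  mixed$treatment <- c("CTRL", "CTRL", "HP2")
  expect_error(summarize_treatment(mixed), "mixes treatments")
})

test_that("not-defined replicates propagate and render as n.d.", {
  hs <- do.call(rbind, lapply(1:3, function(r)
    germination_indices(zero_course(replicate = r))))
  ctrl <- do.call(rbind, lapply(list(c(8, 5, 2), c(9, 4, 2), c(7, 6, 3)),
                                function(n) germination_indices(
                                  germination_time_course(n, treatment = "CTRL"))))
  s <- summarize_treatment(hs, control = ctrl)
  fmt <- format_treatment_summary(s)
  expect_equal(unname(fmt[c("MGT", "MGR", "CVG")]), rep("n.d.", 3))
  expect_equal(unname(fmt["PV"]), "0 ± 0 *")
  expect_equal(unname(fmt["U"]), "0 ± 0 *")
  expect_equal(unname(fmt["Z"]), "0 ± 0 *")
  # constant-but-different groups are significant, the t-test flag set
  expect_true(all(s$sig_vs_control[s$index %in% c("PV", "U", "Z", "G")]))
})
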