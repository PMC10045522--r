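test_that("scenario constructors validate their parameters", {
  expect_error(germination_scenario(p_germ = 1.2, mgt_true = 1), "p_germ")
  expect_error(germination_scenario(p_germ = 0.5, mgt_true = 5,
                                    monitoring_days = 3), "mgt_true")
  expect_error(germination_scenario(0.5, 1, dispersion = -1), "dispersion")
  expect_error(assay_scenario(rooh_uM = c(A = 1), rfu = c(B = 1)), "named")
  expect_error(qpcr_scenario(list(HP = c(g = -1))), "positive")
})

test_that("simulation is deterministic under a fixed seed", {
  sc <- germination_scenario(0.8, 1.5, rng_seed = 99)
  a <- simulate_germination(sc)
  b <- simulate_germination(sc)
  expect_identical(a, b)

  asc <- assay_scenario(rooh_uM = c(CTRL = 2, HS = 4),
                        rfu = c(CTRL = 3000, HS = 5000), rng_seed = 12)
  expect_identical(simulate_assays(asc), simulate_assays(asc))

  qsc <- qpcr_scenario(list(HP4 = c(CAT1 = 2)), rng_seed = 12)
  expect_identical(simulate_ct(qsc), simulate_ct(qsc))

  # the simulator leaves the caller's RNG state untouched
  set.seed(1); before <- .Random.seed
  invisible(simulate_germination(sc))
  expect_identical(.Random.seed, before)
})

test_that("degenerate scenarios reproduce their analytic limits", {
  hs <- germination_scenario(p_germ = 0, mgt_true = 1, rng_seed = 4)
  tcs <- simulate_germination(hs)
  expect_true(all(vapply(tcs, function(tc) sum(tc$counts) == 0, logical(1))))

  sync <- germination_scenario(p_germ = 1, mgt_true = 1.8, dispersion = 0,
                               rng_seed = 4)
  tcs2 <- simulate_germination(sync)
  for (tc in tcs2) {
    expect_equal(which(tc$counts > 0), 2L)  # round(1.8)
    expect_equal(synchrony_index(tc), 1)
  }
})

test_that("replicate MGT estimates converge to the censoring-adjusted truth", {
  sc <- germination_scenario(p_germ = 0.9, mgt_true = 1.3, dispersion = 0.5,
                             n_replicates = 400L, rng_seed = 17)
  tcs <- simulate_germination(sc)
  mgts <- vapply(tcs, mean_germination_time, numeric(1))
  expect_equal(mean(mgts, na.rm = TRUE), expected_mgt(sc), tolerance = 0.1)
  # truncation pulls the observable mean below the untruncated truth's grid
  expect_lte(expected_mgt(sc), sc$monitoring_days)
})

test_that("noiseless assay simulation recovers the calibration exactly", {
  asc <- assay_scenario(rooh_uM = c(CTRL = 2, ZERO = 0),
                        rfu = c(CTRL = 3000, ZERO = 1000),
                        cv = 0, noise_sd = 0, rng_seed = 2)
  d <- simulate_assays(asc)
  std <- d[d$assay == "FOX1" & d$is_standard, ]
  std$a560 <- std$value
  cal <- fit_calibration(std)
  expect_equal(cal$slope, asc$slope)
  expect_equal(cal$intercept, asc$intercept)

  smp <- d[d$assay == "FOX1" & !d$is_standard, ]
  pred <- predict_concentration(cal, smp$value)
  expect_equal(pred$rooh_uM[smp$treatment == "CTRL"], rep(2, 5))
  expect_equal(pred$rooh_uM[smp$treatment == "ZERO"], rep(0, 5))
})

test_that("noiseless Ct simulation encodes folds as exact cycle shifts", {
  qsc <- qpcr_scenario(list(HP4 = c(CAT1 = 2, APX2 = 1)),
                       ref_stability_sd = 0, tech_sd = 0, rng_seed = 1)
  d <- simulate_ct(qsc)
  ct_of <- function(tr, g) unique(d$ct[d$treatment == tr & d$gene == g])
  expect_equal(ct_of("CTRL", "CAT1") - ct_of("HP4", "CAT1"), 1)
  expect_equal(ct_of("CTRL", "APX2"), ct_of("HP4", "APX2"))
  res <- relative_to_control(d, reference_genes = c("CYP", "RP40S"))
  expect_equal(res$rel_expression[res$gene == "CAT1" & res$treatment == "HP4"],
               2)
  expect_equal(res$rel_expression[res$gene == "APX2" & res$treatment == "HP4"],
               1)
})

test_that("the study template reproduces the qualitative design", {
  tpl <- study_template("soybean", seed = 11)
  expect_equal(tpl$germination$HS$p_germ, 0)
  expect_equal(tpl$germination$CTRL$monitoring_days, 3L)
  expect_equal(study_template("wheat")$germination$CTRL$monitoring_days,
               5L)
  expect_equal(study_template("tomato")$germination$CTRL$monitoring_days,
               6L)
  # ROS ordering template: HS highest, every HP below CTRL
  ro <- tpl$assays$rooh_uM
  expect_true(ro["HS"] > ro["CTRL"])
  expect_true(all(ro[c("HP2", "HP4", "HP8")] < ro["CTRL"]))

  sim <- simulate_study(tpl)
  expect_named(sim, c("counts", "assays", "ct"))
  hs <- sim$counts[sim$counts$treatment == "HS", ]
  expect_true(all(hs$new_germinated == 0))

  dir1 <- file.path(tempdir(), "simA"); dir2 <- file.path(tempdir(), "simB")
  simulate_study(tpl, dir1); simulate_study(tpl, dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  unlink(c(dir1, dir2), recursive = TRUE)
})
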