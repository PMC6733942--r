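test_that("leverage arithmetic matches the conservative-mixing fixture", {
  fx <- mixing_fixture()
  lv <- subcatchment_leverage(fx$network, fx$dataset, "early", "DOC",
                              partition = "incremental")
  lev <- setNames(lv$sites$leverage_pct, lv$sites$site_id)
  # L = 100 * ((C - 1.4)/1.4) * (A/100)
  expect_equal(unname(lev["h1"]), 100 * ((3 - 1.4) / 1.4) * 0.2)
  expect_equal(unname(lev["h2"]), 100 * ((1 - 1.4) / 1.4) * 0.8)
  expect_equal(unname(lev["out"]), 0)
  # exact cancellation over the disjoint partition
  expect_equal(lv$summary$mean, 0, tolerance = 1e-12)
})

test_that("leverage is invariant to rescaling concentrations", {
  fx <- mixing_fixture()
  ds2 <- fx$dataset
  ds2$chem$concentration <- ds2$chem$concentration * 37.5
  lv1 <- subcatchment_leverage(fx$network, fx$dataset, "early", "DOC")
  lv2 <- subcatchment_leverage(fx$network, ds2, "early", "DOC")
  expect_equal(lv1$sites$leverage_pct, lv2$sites$leverage_pct)
})

test_that("missing or zero outlet concentration is a hard error", {
  fx <- mixing_fixture()
  ds <- fx$dataset
  ds$chem <- ds$chem[ds$chem$site_id != "out", ]
  expect_error(subcatchment_leverage(fx$network, ds, "early", "DOC"),
               "outlet-missing")

  ds0 <- fx$dataset
  ds0$chem$concentration[ds0$chem$site_id == "out"] <- 0
  expect_error(subcatchment_leverage(fx$network, ds0, "early", "DOC"),
               "division error")
})

test_that("summary reports type-7 quartiles and 1.5 IQR whisker outliers", {
  s <- mean_leverage_summary(c(-10, 0, 10))
  expect_equal(s$mean, 0)
  expect_equal(s$median, 0)

  s <- mean_leverage_summary(c(1, 2, 3, 4, 100))
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  expect_equal(s$outliers, 100) # beyond 4 + 1.5 * 2
  expect_equal(s$whisker_high, 4)

  s <- mean_leverage_summary(42)
  expect_equal(s$mean, 42)
  expect_equal(s$median, 42)
})

test_that("conservative leaf-source watersheds have exactly zero mean leverage", {
  for (seed in c(4, 17, 60)) {
    cfg <- sim_config(n_headwaters = 12, k_r = 0, source_at = "leaves")
    sim <- simulate_dataset(cfg, seed = seed, solutes = "DOC")
    nw <- sim$dataset$networks[["synthetic"]]
    lv <- subcatchment_leverage(nw, sim$dataset, "early", "DOC",
                                partition = "incremental")
    expect_equal(lv$summary$mean, 0, tolerance = 1e-9)
  }
})

test_that("mean leverage sign tracks the net reaction and grows with |k_r|", {
  cfg <- sim_config(n_headwaters = 12)
  means <- vapply(c(-0.2, -0.05, 0.05, 0.2), function(kr) {
    cfg$k_r <- kr
    sim <- simulate_dataset(cfg, seed = 23, solutes = "DOC")
    nw <- sim$dataset$networks[["synthetic"]]
    subcatchment_leverage(nw, sim$dataset, "early", "DOC")$summary$mean
  }, numeric(1))
  expect_true(all(sign(means) == c(-1, -1, 1, 1)))
  expect_gt(abs(means[1]), abs(means[2]))
  expect_gt(abs(means[4]), abs(means[3]))
})
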