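test_that("random networks have the expected size and exact area accounting", {
  nw <- generate_network(sim_config(n_headwaters = 2), seed = 1)
  expect_equal(nrow(nw$sites), 3) # two headwaters + outlet

  for (seed in c(2, 33)) {
    nw <- generate_network(sim_config(n_headwaters = 25), seed = seed)
    expect_equal(nrow(nw$sites), 49)
    expect_equal(sum(nw$sites$incremental_area_km2), outlet_area(nw),
                 tolerance = 1e-9)
    expect_length(network_leaves(nw), 25)
  }

  a <- generate_network(sim_config(), seed = 5)
  b <- generate_network(sim_config(), seed = 5)
  expect_identical(a, b)
})

test_that("greedy patching respects the target area and covers every reach", {
  nw <- chain_network() # areas 1, 5, 10 -> incremental 1, 4, 5
  p <- partition_patches(nw, 4)
  expect_setequal(names(p), nw$sites$site_id)
  expect_true(all(p >= 1))

  # a chain of 4 unit reaches with A_p = 2 splits into two 2-reach patches
  chain4 <- stream_network(data.frame(
    site_id = c("a", "b", "c", "d"),
    drainage_area_km2 = 1:4,
    downstream_id = c("b", "c", "d", NA)), "W")
  p4 <- partition_patches(chain4, 2)
  expect_equal(unname(p4[c("a", "b", "c", "d")]), c(1, 1, 2, 2))

  expect_warning(p1 <- partition_patches(chain4, 100), "single patch")
  expect_equal(unname(unique(p1)), 1L)

  # A_p below the smallest incremental area: every reach its own patch
  tiny <- partition_patches(chain4, 0.5)
  expect_equal(length(unique(tiny)), 4)

  # patch areas are bounded below by A_p except for merged tails
  nw2 <- generate_network(sim_config(n_headwaters = 30), seed = 6)
  p2 <- partition_patches(nw2, 8)
  incr <- setNames(nw2$sites$incremental_area_km2, nw2$sites$site_id)
  areas <- tapply(incr[names(p2)], p2, sum)
  expect_true(all(areas >= 8 | seq_along(areas) == length(areas)))
})

test_that("source fields honour degenerate settings", {
  nw <- generate_network(sim_config(n_headwaters = 10), seed = 2)
  p <- partition_patches(nw, 5)

  cfg0 <- sim_config(n_headwaters = 10, patch_sd = 0, local_sd = 0)
  f <- generate_source_field(nw, p, cfg0, seed = 3)
  expect_true(all(f$early == cfg0$baseline_concentration))
  expect_true(all(f$late == cfg0$baseline_concentration))

  cfg1 <- sim_config(n_headwaters = 10, rho_season = 1)
  f1 <- generate_source_field(nw, p, cfg1, seed = 3)
  expect_equal(f1$early, f1$late)
})

test_that("independent seasons give near-zero rank correlation on average", {
  cfg <- sim_config(rho_season = 0) # default network size, ~13 patches
  rs <- vapply(1:50, function(i) {
    nw <- generate_network(cfg, seed = 70 + i)
    p <- partition_patches(nw, cfg$patch_area_km2)
    f <- generate_source_field(nw, p, cfg, seed = 170 + i)
    cor(rank(f$early), rank(f$late))
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("conservative routing equals the flatten-the-tree oracle", {
  for (seed in c(3, 12)) {
    cfg <- sim_config(n_headwaters = 100) # 199 reaches
    nw <- generate_network(cfg, seed = seed)
    p <- partition_patches(nw, 10)
    src <- generate_source_field(nw, p, cfg, seed = seed + 1)$early
    conc <- route_and_mix(nw, src, k_r = 0)
    w <- setNames(nw$sites$incremental_area_km2, nw$sites$site_id)
    oracle <- sum(src[names(w)] * w) / outlet_area(nw)
    expect_equal(unname(conc[nw$outlet_id]), oracle, tolerance = 1e-12)

    # uniform sources pass through unchanged
    flat <- setNames(rep(4.2, length(w)), names(w))
    expect_equal(unname(route_and_mix(nw, flat, 0)), rep(4.2, length(w)),
                 tolerance = 1e-12)

    # net removal strictly lowers the outlet below the conservative value
    removed <- route_and_mix(nw, src, k_r = 0.1)
    expect_lt(removed[nw$outlet_id], oracle)
  }
})

test_that("simulated datasets carry the study cardinality and the truth record", {
  sim <- simulate_dataset(default_study_configs(), seed = 31)
  expect_equal(nrow(sim$dataset$sites), 31 + 42 + 41)
  expect_equal(nrow(sim$dataset$chem), 114 * 2 * 3)
  expect_equal(nrow(sim$truth), 9)
  expect_setequal(unique(sim$truth$watershed_id),
                  c("Tundra", "Lake", "Alpine"))
  # outlets are always sampled
  for (nw in sim$dataset$networks) {
    expect_true(nw$outlet_id %in% sim$dataset$sites$site_id)
  }
  # determinism
  sim2 <- simulate_dataset(default_study_configs(), seed = 31)
  expect_identical(sim$dataset$chem, sim2$dataset$chem)

  expect_error(
    simulate_dataset(sim_config(n_headwaters = 4, n_sites_sampled = 20),
                     seed = 1),
    "config error")
})
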