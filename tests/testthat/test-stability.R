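test_that("perfect monotone and reversed pairings give r_s of +1 and -1", {
  up <- spatial_stability(paired_season_dataset(1:4, c(2, 4, 6, 8))$networks[[1]],
                          paired_season_dataset(1:4, c(2, 4, 6, 8)), "DOC")
  expect_equal(up$r_s, 1)

  ds <- paired_season_dataset(1:4, c(8, 6, 4, 2))
  down <- spatial_stability(ds$networks[[1]], ds, "DOC")
  expect_equal(down$r_s, -1)
})

test_that("r_s matches the rank-difference formula on 5-point examples", {
  # one transposition: d^2 = (0, 1, 1, 0, 0)
  ds <- paired_season_dataset(1:5, c(1, 3, 2, 4, 5))
  st <- spatial_stability(ds$networks[[1]], ds, "DOC")
  expect_equal(st$r_s, 1 - 6 * 2 / (5 * 24))
  expect_equal(st$r_s, 0.9)

  # two transpositions: d^2 = (1, 1, 1, 1, 0)
  ds <- paired_season_dataset(1:5, c(2, 1, 4, 3, 5))
  st <- spatial_stability(ds$networks[[1]], ds, "DOC")
  expect_equal(st$r_s, 1 - 6 * 4 / (5 * 24))
  expect_equal(st$r_s, 0.8)
})

test_that("r_s and p agree with cor.test across tie-free cases", {
  withr::with_seed(14, {
    for (n in c(6, 9, 15, 30)) {
      x <- rlnorm(n)
      y <- 0.6 * x + rlnorm(n, sdlog = 0.8)
      ds <- paired_season_dataset(x, y)
      st <- spatial_stability(ds$networks[[1]], ds, "DOC")
      ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                       exact = (n <= 10)))
      expect_equal(st$r_s, unname(ref$estimate))
      if (n > 10) {
        # both use the t approximation
        expect_equal(st$p_value, ref$p.value, tolerance = 1e-9)
      } else {
        # enumeration null vs cor.test's AS 89 null: same to ~coarse grain
        expect_lt(abs(st$p_value - ref$p.value), 0.01)
      }
    }
  })
})

test_that("small-n p-values equal an independently coded permutation null", {
  # depth-first enumeration written from scratch, using cor() directly
  perm_p <- function(x, y) {
    n <- length(y)
    obs <- cor(rank(x), rank(y))
    count <- 0L
    total <- 0L
    recurse <- function(chosen, remaining) {
      if (length(remaining) == 0L) {
        total <<- total + 1L
        if (abs(cor(rank(x), chosen)) >= abs(obs) - 1e-12) {
          count <<- count + 1L
        }
        return(invisible())
      }
      for (r in remaining) {
        recurse(c(chosen, r), setdiff(remaining, r))
      }
    }
    recurse(numeric(0), rank(y))
    count / total
  }
  withr::with_seed(31, {
    x <- rlnorm(6)
    y <- 0.8 * x + rlnorm(6, sdlog = 0.4)
    ds <- paired_season_dataset(x, y)
    st <- spatial_stability(ds$networks[[1]], ds, "DOC")
    expect_equal(st$p_value, perm_p(x, y))
  })
})

test_that("ties get average ranks", {
  ds <- paired_season_dataset(c(1, 2, 2, 3, 4), c(1, 2, 3, 4, 5))
  st <- spatial_stability(ds$networks[[1]], ds, "DOC")
  expect_equal(st$r_s, cor(rank(c(1, 2, 2, 3, 4)), rank(1:5)))
})

test_that("r_s is invariant under strictly monotone transforms", {
  withr::with_seed(21, {
    x <- rlnorm(12)
    y <- rlnorm(12)
    ds1 <- paired_season_dataset(x, y)
    ds2 <- paired_season_dataset(log(x), y^3)
    expect_equal(spatial_stability(ds1$networks[[1]], ds1, "DOC")$r_s,
                 spatial_stability(ds2$networks[[1]], ds2, "DOC")$r_s)
  })
})

test_that("degenerate pairings are rejected", {
  ds <- paired_season_dataset(c(1, 2), c(2, 1))
  # only two paired sites after construction
  expect_error(spatial_stability(ds$networks[[1]], ds, "DOC"),
               "insufficient data")

  flat <- paired_season_dataset(c(5, 5, 5, 5), 1:4)
  expect_error(spatial_stability(flat$networks[[1]], flat, "DOC"),
               "undefined correlation")
})

test_that("only sites measured in both seasons enter the correlation", {
  ds <- paired_season_dataset(1:6, c(2, 4, 6, 8, 10, 12))
  ds$chem <- ds$chem[!(ds$chem$season == "late" &
                         ds$chem$site_id %in% c("s01", "s02")), ]
  st <- spatial_stability(ds$networks[[1]], ds, "DOC")
  expect_equal(st$n_pairs, 4)
  expect_equal(st$r_s, 1)
})
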