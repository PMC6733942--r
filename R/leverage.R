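#' Subcatchment leverage on outlet chemistry
#'
#' Leverage measures each site's percent influence on the concentration
#' observed at the watershed outlet, under the assumption of area-proportional
#' runoff (uniform specific discharge, so flow is proportional to drainage
#' area):
#' \deqn{L_i = 100 \times \frac{C_i - C_{out}}{C_{out}}
#'   \times \frac{A_i}{A_{out}}}
#' A site with above-outlet concentration and a large relative drainage area
#' has high positive leverage. Under conservative mixing the area-weighted
#' deviations cancel, so leverage over a disjoint headwater partition has mean
#' zero; a positive mean indicates headwater excess lost in transit (net
#' in-network removal/uptake) and a negative mean indicates net in-network
#' production. The outlet's own leverage is exactly zero.
#'
#' @param network a [stream_network].
#' @param dataset a `synoptic_dataset` holding the concentrations.
#' @param season,solute which measurement campaign and solute to evaluate.
#' @param partition `"all"` (default) evaluates every non-outlet site with a
#'   concentration — the nested view behind per-site maps; `"incremental"`
#'   restricts the summary to sampled sites with no sampled upstream
#'   neighbour, whose drainage areas are mutually disjoint, the partition on
#'   which the conservative zero-mean contract can be tested.
#' @return A `leverage_result`: list with `sites` (per-site table:
#'   `site_id`, `drainage_area_km2`, `concentration`, `leverage_pct`,
#'   `in_partition`), `summary` (see [mean_leverage_summary()]), plus
#'   `watershed_id`, `season`, `solute`, `partition`, `outlet_id`.
#' @export
subcatchment_leverage <- function(network, dataset, season, solute,
                                  partition = c("all", "incremental")) {
  stopifnot(inherits(network, "stream_network"),
            inherits(dataset, "synoptic_dataset"))
  partition <- match.arg(partition)
  ws <- network$watershed_id
  ser <- chem_series(dataset, ws, season, solute, drop_missing = TRUE)

  out_row <- ser[ser$site_id == network$outlet_id, ]
  if (nrow(out_row) == 0L) {
    stop("outlet-missing error: no ", solute, " concentration at outlet '",
         network$outlet_id, "' of watershed '", ws, "' in season '", season,
         "'", call. = FALSE)
  }
  c_out <- out_row$concentration
  if (c_out == 0) {
    stop("division error: outlet concentration of ", solute,
         " in watershed '", ws, "', season '", season,
         "' is zero; leverage is undefined", call. = FALSE)
  }
  a_out <- outlet_area(network)

  lev <- 100 * ((ser$concentration - c_out) / c_out) *
    (ser$drainage_area_km2 / a_out)
  lev[ser$site_id == network$outlet_id] <- 0

  # Partition membership: sites with no *sampled* site upstream of them.
  if (partition == "incremental") {
    down <- network$sites$downstream_id[match(ser$site_id,
                                              network$sites$site_id)]
    sampled <- ser$site_id
    # walk each sampled site downstream; the first sampled site hit gets an
    # upstream neighbour
    has_upstream <- rep(FALSE, nrow(ser))
    names(has_upstream) <- sampled
    parent_of <- stats::setNames(network$sites$downstream_id,
                                 network$sites$site_id)
    for (s in sampled) {
      cur <- parent_of[[s]]
      while (!is.na(cur)) {
        if (cur %in% sampled) {
          has_upstream[cur] <- TRUE
          break
        }
        cur <- parent_of[[cur]]
      }
    }
    in_part <- !has_upstream[ser$site_id] & ser$site_id != network$outlet_id
  } else {
    in_part <- ser$site_id != network$outlet_id
  }

  sites <- data.frame(
    site_id = ser$site_id,
    drainage_area_km2 = ser$drainage_area_km2,
    concentration = ser$concentration,
    leverage_pct = lev,
    in_partition = as.vector(in_part),
    stringsAsFactors = FALSE
  )

  res <- structure(
    list(sites = sites,
         watershed_id = ws, season = season, solute = solute,
         partition = partition, outlet_id = network$outlet_id,
         summary = NULL),
    class = "leverage_result"
  )
  res$summary <- mean_leverage_summary(res)
  res
}

#' Boxplot-style summary of leverage values
#'
#' Mean, median, quartiles (linear-interpolation, type 7), whiskers at the
#' most extreme values within 1.5 x IQR of the quartiles, and the points
#' beyond the whiskers — the statistics a leverage boxplot displays.
#'
#' @param result a `leverage_result`, or a bare numeric vector of leverage
#'   values.
#' @return list with `n`, `mean`, `median`, `q1`, `q3`, `whisker_low`,
#'   `whisker_high`, `outliers` (values beyond 1.5 x IQR).
#' @export
mean_leverage_summary <- function(result) {
  lev <- if (inherits(result, "leverage_result")) {
    result$sites$leverage_pct[result$sites$in_partition]
  } else {
    as.numeric(result)
  }
  if (length(lev) < 1L) {
    stop("insufficient data: no non-outlet leverage values", call. = FALSE)
  }
  q <- stats::quantile(lev, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- lev[lev >= lo_fence & lev <= hi_fence]
  list(
    n = length(lev),
    mean = mean(lev),
    median = q[2],
    q1 = q[1],
    q3 = q[3],
    whisker_low = min(inside),
    whisker_high = max(inside),
    outliers = sort(lev[lev < lo_fence | lev > hi_fence])
  )
}

#' @export
print.leverage_result <- function(x, ...) {
  s <- x$summary
  cat("<leverage_result> ", x$watershed_id, " / ", x$season, " / ",
      x$solute, " (partition: ", x$partition, ")\n", sep = "")
  cat(sprintf("  n = %d, mean = %.3f%%, median = %.3f%% [q1 %.3f, q3 %.3f]\n",
              s$n, s$mean, s$median, s$q1, s$q3))
  invisible(x)
}

# All permutations of 1..n as an n! x n integer matrix (n <= 10).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- all_permutations(n - 1L)
  m <- nrow(p)
  out <- matrix(0L, n * m, n)
  for (i in seq_len(n)) {
    block <- ((i - 1L) * m + 1L):(i * m)
    out[block, 1L] <- i
    out[block, -1L] <- p + (p >= i)
  }
  out
}

#' Seasonal spatial stability of a solute
#'
#' Spearman rank correlation between the concentrations of the same sites in
#' two sampling campaigns. High `r_s` means the spatial pattern of sources
#' and sinks persisted between seasons; a low, non-significant `r_s` means
#' the landscape reorganised. Ties receive average ranks. The two-sided
#' p-value uses the t approximation
#' `t = r_s * sqrt((n - 2) / (1 - r_s^2))` for n > 10 and the exact
#' permutation null (all n! pairings) for n <= 10.
#'
#' @param network a [stream_network] (identifies the watershed).
#' @param dataset a `synoptic_dataset`.
#' @param solute solute name.
#' @param season_a,season_b the two campaigns to compare (defaults: first and
#'   second season of the dataset).
#' @param alpha significance level.
#' @return A `stability_result`: list with `r_s`, `p_value`, `significant`,
#'   `n_pairs`, `pairs` (site table), `watershed_id`, `solute`, `seasons`.
#' @export
spatial_stability <- function(network, dataset, solute,
                              season_a = NULL, season_b = NULL,
                              alpha = 0.05) {
  stopifnot(inherits(network, "stream_network"),
            inherits(dataset, "synoptic_dataset"))
  if (is.null(season_a)) season_a <- dataset$seasons[1]
  if (is.null(season_b)) season_b <- dataset$seasons[2]
  ws <- network$watershed_id
  a <- chem_series(dataset, ws, season_a, solute, drop_missing = TRUE)
  b <- chem_series(dataset, ws, season_b, solute, drop_missing = TRUE)
  common <- intersect(a$site_id, b$site_id)
  n <- length(common)
  if (n < 3L) {
    stop("insufficient data: need >= 3 paired sites, got ", n, call. = FALSE)
  }
  x <- a$concentration[match(common, a$site_id)]
  y <- b$concentration[match(common, b$site_id)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance in one season", call. = FALSE)
  }
  rx <- rank(x) # average ranks for ties
  ry <- rank(y)
  r_s <- stats::cor(rx, ry)

  if (n > 10L) {
    tstat <- r_s * sqrt((n - 2) / (1 - r_s^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  } else {
    perms <- all_permutations(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    # r_s under every re-pairing of the second season's ranks
    null_rs <- as.vector(matrix(ryc[perms], nrow(perms)) %*% rxc) / denom
    p <- mean(abs(null_rs) >= abs(r_s) - 1e-12)
  }

  structure(
    list(r_s = r_s, p_value = p, significant = p <= alpha, n_pairs = n,
         alpha = alpha,
         pairs = data.frame(site_id = common, conc_a = x, conc_b = y,
                            stringsAsFactors = FALSE),
         watershed_id = ws, solute = solute,
         seasons = c(season_a, season_b)),
    class = "stability_result"
  )
}

#' @export
print.stability_result <- function(x, ...) {
  cat("<stability_result> ", x$watershed_id, " / ", x$solute, " (",
      x$seasons[1], " vs ", x$seasons[2], ")\n", sep = "")
  cat(sprintf("  r_s = %.3f, p = %.4f (%s), n = %d\n", x$r_s, x$p_value,
              if (x$significant) "significant" else "NS", x$n_pairs))
  invisible(x)
}
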