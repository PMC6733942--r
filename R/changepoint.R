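#' Scale concentrations to z-scores ordered by drainage area
#'
#' Centres and scales one watershed x season x solute concentration series
#' (subtract the mean, divide by the sample standard deviation) and orders
#' sites by increasing drainage area, ties broken by site id. This is the
#' series on which the variance-collapse change-point test operates: scaling
#' makes variance profiles comparable across solutes measured in different
#' units.
#'
#' @param values data.frame with columns `area` (km2) and `concentration`;
#'   optionally `site_id` for deterministic tie-breaking.
#' @return A `scaled_series`: list with `area` (ascending), `z` (mean 0,
#'   sd 1), `site_id`, `n`.
#' @export
scale_concentrations <- function(values) {
  stopifnot(is.data.frame(values),
            all(c("area", "concentration") %in% names(values)))
  values <- values[!is.na(values$concentration), ]
  n <- nrow(values)
  if (n < 2L) stop("insufficient data: need at least 2 sites, got ", n,
                   call. = FALSE)
  if (is.null(values$site_id)) values$site_id <- as.character(seq_len(n))
  s <- stats::sd(values$concentration)
  if (s == 0) stop("zero variance: concentrations are constant across sites",
                   call. = FALSE)
  ord <- order(values$area, values$site_id)
  values <- values[ord, ]
  structure(
    list(area = values$area,
         z = (values$concentration - mean(values$concentration)) / s,
         site_id = as.character(values$site_id),
         n = n),
    class = "scaled_series"
  )
}

# Max of the two-segment Gaussian variance log-likelihood ratio over all
# admissible split points. Vectorised via prefix sums; segment variances are
# maximum-likelihood (each segment centred at its own mean), floored at
# 1e-12 so an exactly constant segment cannot produce an infinite statistic.
# Returns the first argmax for determinism under ties.
max_lr_split <- function(z, min_segment) {
  n <- length(z)
  k <- seq.int(min_segment, n - min_segment)
  s1 <- cumsum(z)
  s2 <- cumsum(z^2)
  v_left <- s2[k] / k - (s1[k] / k)^2
  v_right <- (s2[n] - s2[k]) / (n - k) - ((s1[n] - s1[k]) / (n - k))^2
  v_all <- s2[n] / n - (s1[n] / n)^2
  eps <- 1e-12
  lr <- n * log(max(v_all, eps)) - k * log(pmax(v_left, eps)) -
    (n - k) * log(pmax(v_right, eps))
  i <- which.max(lr)
  list(k = k[i], lr = lr[i])
}

#' Detect the drainage-area scale of variance collapse
#'
#' Tests for a single change point in the variance of scaled concentrations
#' ordered by drainage area. The statistic is the Gaussian log-likelihood
#' ratio
#' \deqn{LR(k) = n\log\hat\sigma^2_{1..n} - k\log\hat\sigma^2_{1..k}
#'   - (n-k)\log\hat\sigma^2_{k+1..n}}
#' maximised exhaustively over split indices
#' `k in [min_segment, n - min_segment]` (segment variances are ML estimates
#' about each segment's own mean). Significance comes from a permutation
#' test: the site order is shuffled `n_perm` times and the maximal LR
#' recomputed, giving `p = (1 + #{perm >= obs}) / (n_perm + 1)`. When
#' significant, the collapse threshold is reported as the geometric mean of
#' the drainage areas bracketing the split — the natural interpolant when
#' areas span orders of magnitude. A non-significant result (`p > alpha`)
#' means no variance-collapse scale is identifiable within the watershed and
#' both the index and the threshold area are `NA`.
#'
#' @param series a `scaled_series` from [scale_concentrations()].
#' @param alpha significance level for the permutation test.
#' @param n_perm number of permutations.
#' @param min_segment minimum sites per segment; guards against degenerate
#'   end splits.
#' @param seed integer seed for the permutation null (required, so results
#'   are reproducible).
#' @param window window width forwarded to [variance_profile()] for the
#'   diagnostic profile (skipped when `n < window`).
#' @return A `collapse_result`: list with `changepoint_index`,
#'   `threshold_area_km2` (both `NA` if not significant), `lr_statistic`,
#'   `p_value`, `n`, `n_permutations`, `alpha`, and `variance_profile`.
#' @export
detect_variance_collapse <- function(series, alpha = 0.05, n_perm = 999,
                                     min_segment = 5, seed,
                                     window = 10) {
  stopifnot(inherits(series, "scaled_series"))
  if (missing(seed)) stop("seed must be supplied", call. = FALSE)
  n <- series$n
  if (n < 2 * min_segment) {
    stop("insufficient data: need at least ", 2 * min_segment,
         " sites (2 x min_segment), got ", n, call. = FALSE)
  }
  obs <- max_lr_split(series$z, min_segment)
  perm_ge <- withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    sum(vapply(seq_len(n_perm), function(i) {
      max_lr_split(sample(series$z), min_segment)$lr
    }, numeric(1)) >= obs$lr - 1e-12)
  })
  p <- (1 + perm_ge) / (n_perm + 1)

  significant <- p <= alpha
  idx <- if (significant) obs$k else NA_integer_
  thr <- if (significant) {
    sqrt(series$area[obs$k] * series$area[obs$k + 1])
  } else NA_real_

  profile <- if (n >= window) variance_profile(series, window = window) else
    data.frame(area = numeric(0), variance = numeric(0))

  structure(
    list(changepoint_index = idx,
         threshold_area_km2 = thr,
         lr_statistic = obs$lr,
         p_value = p,
         n = n,
         n_permutations = n_perm,
         alpha = alpha,
         variance_profile = profile),
    class = "collapse_result"
  )
}

#' @export
print.collapse_result <- function(x, ...) {
  cat("<collapse_result> n = ", x$n, ", LR = ",
      format(x$lr_statistic, digits = 4),
      ", p = ", format(x$p_value, digits = 3), "\n", sep = "")
  if (is.na(x$changepoint_index)) {
    cat("  no significant variance collapse (alpha = ", x$alpha, ")\n",
        sep = "")
  } else {
    cat("  collapse after site ", x$changepoint_index,
        " at ~", format(x$threshold_area_km2, digits = 4), " km2\n", sep = "")
  }
  invisible(x)
}

#' Sliding-window variance profile along the drainage-area axis
#'
#' Sample variance of the scaled series in a sliding window over area-ordered
#' sites; each window is located at the geometric mean of its members'
#' drainage areas. Supports visual inspection of where variance collapses.
#'
#' @param series a `scaled_series`.
#' @param window window width (number of sites).
#' @return data.frame with columns `area` and `variance`,
#'   `n - window + 1` rows.
#' @export
variance_profile <- function(series, window = 10) {
  stopifnot(inherits(series, "scaled_series"))
  n <- series$n
  if (n < window) {
    stop("insufficient data: need at least ", window, " sites, got ", n,
         call. = FALSE)
  }
  starts <- seq_len(n - window + 1L)
  data.frame(
    area = vapply(starts, function(i) {
      exp(mean(log(series$area[i:(i + window - 1L)])))
    }, numeric(1)),
    variance = vapply(starts, function(i) {
      stats::var(series$z[i:(i + window - 1L)])
    }, numeric(1))
  )
}
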