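#' Run the full synoptic metrics pipeline
#'
#' For every watershed x season x solute combination computes the
#' variance-collapse change point and the subcatchment leverage summary, and
#' for every watershed x solute the between-season spatial stability. Results
#' come back as plain data.frames ready for [write_report()].
#'
#' @param dataset a `synoptic_dataset` with networks attached (real data via
#'   [read_chemistry_table()] + [read_network()], or simulated via
#'   [simulate_dataset()]).
#' @param alpha significance level used by both the permutation and the rank
#'   tests.
#' @param n_perm permutations for the change-point test.
#' @param window variance-profile window width.
#' @param min_segment minimum change-point segment length.
#' @param seed integer seed driving all permutation draws.
#' @param partition leverage summary mode, see [subcatchment_leverage()].
#' @return list of class `synoptic_report`: `collapse`, `leverage_summary`,
#'   `leverage_sites`, `stability` (data.frames), `warnings` (from
#'   [validate_dataset()]), and `config` (the run parameters).
#' @export
run_metrics_pipeline <- function(dataset, alpha = 0.05, n_perm = 999,
                                 window = 10, min_segment = 5, seed,
                                 partition = c("all", "incremental")) {
  stopifnot(inherits(dataset, "synoptic_dataset"))
  if (is.null(dataset$networks)) {
    stop("dataset has no network topology; call read_network() first",
         call. = FALSE)
  }
  if (missing(seed)) stop("seed must be supplied", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1, n_perm >= 99)
  partition <- match.arg(partition)
  seed <- as.integer(seed) %% .Machine$integer.max

  collapse <- list(); lev_sum <- list(); lev_sites <- list(); stab <- list()
  combo <- 0L
  for (ws in names(dataset$networks)) {
    nw <- dataset$networks[[ws]]
    for (sol in dataset$solutes) {
      for (season in dataset$seasons) {
        combo <- combo + 1L
        ser <- chem_series(dataset, ws, season, sol)
        scaled <- scale_concentrations(data.frame(
          area = ser$drainage_area_km2, concentration = ser$concentration,
          site_id = ser$site_id))
        cp <- detect_variance_collapse(scaled, alpha = alpha, n_perm = n_perm,
                                       min_segment = min_segment,
                                       seed = seed + combo, window = window)
        collapse[[length(collapse) + 1L]] <- data.frame(
          watershed_id = ws, season = season, solute = sol, n = cp$n,
          lr_statistic = cp$lr_statistic, p_value = cp$p_value,
          threshold_area_km2 = cp$threshold_area_km2,
          stringsAsFactors = FALSE
        )

        lv <- subcatchment_leverage(nw, dataset, season, sol,
                                    partition = partition)
        s <- lv$summary
        lev_sum[[length(lev_sum) + 1L]] <- data.frame(
          watershed_id = ws, season = season, solute = sol, n = s$n,
          mean = s$mean, median = s$median, q1 = s$q1, q3 = s$q3,
          whisker_low = s$whisker_low, whisker_high = s$whisker_high,
          n_outliers = length(s$outliers), stringsAsFactors = FALSE
        )
        st <- lv$sites
        lev_sites[[length(lev_sites) + 1L]] <- data.frame(
          watershed_id = ws, season = season, solute = sol,
          site_id = st$site_id, drainage_area_km2 = st$drainage_area_km2,
          leverage_pct = st$leverage_pct, stringsAsFactors = FALSE
        )
      }
      sres <- spatial_stability(nw, dataset, sol,
                                season_a = dataset$seasons[1],
                                season_b = dataset$seasons[2], alpha = alpha)
      stab[[length(stab) + 1L]] <- data.frame(
        watershed_id = ws, solute = sol, n_pairs = sres$n_pairs,
        r_s = sres$r_s, p_value = sres$p_value,
        significant = sres$significant, stringsAsFactors = FALSE
      )
    }
  }

  rb <- function(x) { y <- do.call(rbind, x); rownames(y) <- NULL; y }
  structure(
    list(collapse = rb(collapse),
         leverage_summary = rb(lev_sum),
         leverage_sites = rb(lev_sites),
         stability = rb(stab),
         warnings = validate_dataset(dataset),
         config = list(alpha = alpha, n_perm = n_perm, window = window,
                       min_segment = min_segment, seed = seed,
                       partition = partition)),
    class = "synoptic_report"
  )
}

#' @export
print.synoptic_report <- function(x, ...) {
  cat("<synoptic_report> ", nrow(x$collapse), " collapse rows, ",
      nrow(x$leverage_summary), " leverage summaries, ",
      nrow(x$stability), " stability rows\n", sep = "")
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("   - ", w, "\n", sep = "")
  }
  invisible(x)
}

format_table <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  df
}

#' Write a report bundle to disk
#'
#' Emits the result tables as CSV with stable column order and 6 significant
#' digits, plus a JSON manifest recording the run configuration, warnings,
#' and an MD5 checksum for every file. Refuses to overwrite an existing
#' non-empty directory unless `force = TRUE`; on failure partial outputs are
#' removed.
#'
#' @param report a `synoptic_report` from [run_metrics_pipeline()].
#' @param output_dir output directory (created if needed).
#' @param force overwrite an existing non-empty directory.
#' @return the manifest (a list), invisibly.
#' @export
write_report <- function(report, output_dir, force = FALSE) {
  stopifnot(inherits(report, "synoptic_report"))
  if (dir.exists(output_dir) &&
      length(list.files(output_dir, all.files = TRUE, no.. = TRUE)) > 0 &&
      !force) {
    stop("output directory ", output_dir,
         " exists and is not empty; use force = TRUE to overwrite",
         call. = FALSE)
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  tables <- c("collapse", "leverage_summary", "leverage_sites", "stability")
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)

  for (tb in tables) {
    df <- report[[tb]]
    if (is.null(df) || nrow(df) == 0L) next
    path <- file.path(output_dir, paste0(tb, ".csv"))
    utils::write.table(format_table(df), path, sep = ",", row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
    written <- c(written, path)
  }

  manifest <- list(
    config = report$config,
    warnings = report$warnings,
    files = lapply(written, function(p) {
      list(name = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  manifest_path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  written <- c(written, manifest_path)
  ok <- TRUE
  invisible(manifest)
}
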