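#' Read a long-format site chemistry table
#'
#' The expected layout is one row per site x season x solute, with a header
#' row and columns `site_id`, `watershed_id`, `drainage_area_km2`, `season`,
#' `solute`, `concentration`. Concentrations below the detection limit may be
#' written as `"<x"` (e.g. `"<0.5"`): such cells are substituted with half the
#' stated limit and flagged in the `below_lod` column so they remain auditable
#' while keeping the site in every metric. Missing concentrations (empty or
#' `NA`) stay missing; they are never coerced to zero.
#'
#' @param path path to a delimited text file (UTF-8).
#' @param sep field separator, comma by default.
#' @return A `synoptic_dataset`: list with `chem` (long table incl.
#'   `below_lod`), `sites` (one row per site), `networks` (`NULL` until
#'   [read_network()] attaches topology), `seasons`, `solutes`, `provenance`.
#' @seealso [read_network()], [validate_dataset()], [write_chemistry_table()]
#' @export
read_chemistry_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = TRUE,
                           strip.white = TRUE, na.strings = c("NA", ""),
                           fileEncoding = "UTF-8")
  required <- c("site_id", "watershed_id", "drainage_area_km2", "season",
                "solute", "concentration")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  conc_chr <- raw$concentration
  below_lod <- !is.na(conc_chr) & startsWith(conc_chr, "<")
  conc <- rep(NA_real_, length(conc_chr))
  conc[!below_lod] <- suppressWarnings(as.numeric(conc_chr[!below_lod]))
  lod <- suppressWarnings(as.numeric(sub("^<", "", conc_chr[below_lod])))
  conc[below_lod] <- lod / 2
  bad_num <- which(!is.na(conc_chr) & is.na(conc))
  if (length(bad_num) > 0L) {
    stop("validation error: non-numeric concentration in row(s) ",
         paste(utils::head(bad_num, 5), collapse = ", "), call. = FALSE)
  }
  if (any(conc < 0, na.rm = TRUE)) {
    stop("validation error: negative concentration in row(s) ",
         paste(utils::head(which(conc < 0), 5), collapse = ", "),
         call. = FALSE)
  }

  area <- suppressWarnings(as.numeric(raw$drainage_area_km2))
  bad_area <- which(is.na(area) | area <= 0)
  if (length(bad_area) > 0L) {
    stop("validation error: non-positive drainage_area_km2 in row(s) ",
         paste(utils::head(bad_area, 5), collapse = ", "), call. = FALSE)
  }

  chem <- data.frame(
    site_id = raw$site_id,
    watershed_id = raw$watershed_id,
    drainage_area_km2 = area,
    season = raw$season,
    solute = raw$solute,
    concentration = conc,
    below_lod = below_lod,
    stringsAsFactors = FALSE
  )

  key <- paste(chem$watershed_id, chem$site_id, chem$season, chem$solute,
               sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplication error: repeated measurement for (",
         gsub("\r", ", ", d), ")", call. = FALSE)
  }

  # One area per site: conflicting areas across rows are a data error.
  skey <- paste(chem$watershed_id, chem$site_id, sep = "\r")
  per_site <- tapply(chem$drainage_area_km2, skey,
                     function(a) length(unique(a)))
  if (any(per_site > 1)) {
    stop("validation error: conflicting drainage_area_km2 for site(s): ",
         paste(gsub("\r", "/", names(per_site)[per_site > 1]),
               collapse = ", "), call. = FALSE)
  }

  first <- !duplicated(skey)
  sites <- data.frame(
    site_id = chem$site_id[first],
    watershed_id = chem$watershed_id[first],
    drainage_area_km2 = chem$drainage_area_km2[first],
    downstream_id = NA_character_,
    stringsAsFactors = FALSE
  )

  seas <- unique(chem$season)
  if (setequal(seas, c("early", "late"))) seas <- c("early", "late")

  new_synoptic_dataset(chem = chem, sites = sites, networks = NULL,
                       seasons = seas, solutes = unique(chem$solute),
                       provenance = paste0("read_chemistry_table(", path, ")"))
}

new_synoptic_dataset <- function(chem, sites, networks, seasons, solutes,
                                 provenance = "") {
  structure(
    list(chem = chem, sites = sites, networks = networks,
         seasons = seasons, solutes = solutes, provenance = provenance),
    class = "synoptic_dataset"
  )
}

#' @export
print.synoptic_dataset <- function(x, ...) {
  cat("<synoptic_dataset> ", length(unique(x$sites$watershed_id)),
      " watershed(s), ", nrow(x$sites), " sites, ",
      nrow(x$chem), " measurements\n", sep = "")
  cat("  seasons: ", paste(x$seasons, collapse = ", "),
      " | solutes: ", paste(x$solutes, collapse = ", "), "\n", sep = "")
  cat("  topology: ",
      if (is.null(x$networks)) "not attached" else
        paste(names(x$networks), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Attach network topology to a chemistry dataset
#'
#' Reads a two-column edge list (`site_id`, `downstream_id`; empty
#' `downstream_id` marks the watershed outlet), builds one validated rooted
#' tree per watershed and computes incremental drainage areas.
#'
#' @param path path to the delimited edge-list file.
#' @param dataset a `synoptic_dataset` from [read_chemistry_table()].
#' @param sep field separator.
#' @return the dataset with a `networks` list of [stream_network] objects.
#' @export
read_network <- function(path, dataset, sep = ",") {
  stopifnot(inherits(dataset, "synoptic_dataset"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  edges <- utils::read.table(path, header = TRUE, sep = sep,
                             colClasses = "character", strip.white = TRUE,
                             na.strings = c("NA", ""),
                             fileEncoding = "UTF-8")
  missing_cols <- setdiff(c("site_id", "downstream_id"), names(edges))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  not_in_chem <- setdiff(edges$site_id, dataset$sites$site_id)
  if (length(not_in_chem) > 0L) {
    stop("topology error: edge list site(s) absent from chemistry table: ",
         paste(not_in_chem, collapse = ", "), call. = FALSE)
  }
  no_edge <- setdiff(dataset$sites$site_id, edges$site_id)
  if (length(no_edge) > 0L) {
    stop("topology error: chemistry site(s) absent from edge list: ",
         paste(no_edge, collapse = ", "), call. = FALSE)
  }

  sites <- dataset$sites
  sites$downstream_id <- edges$downstream_id[match(sites$site_id,
                                                   edges$site_id)]
  networks <- lapply(split(sites, sites$watershed_id), function(s) {
    stream_network(s[, c("site_id", "drainage_area_km2", "downstream_id")],
                   watershed_id = s$watershed_id[1])
  })
  dataset$sites <- sites
  dataset$networks <- networks
  dataset
}

#' Write the chemistry table of a dataset
#'
#' Emits the same dialect [read_chemistry_table()] reads, bit-stable for
#' round-trip testing. Cells flagged `below_lod` are written back as
#' `"<2*value"` (the original detection limit).
#'
#' @param dataset a `synoptic_dataset`.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_chemistry_table <- function(dataset, path, sep = ",") {
  stopifnot(inherits(dataset, "synoptic_dataset"))
  chem <- dataset$chem
  conc <- ifelse(is.na(chem$concentration), "",
                 ifelse(chem$below_lod,
                        paste0("<", format(2 * chem$concentration,
                                           digits = 15, trim = TRUE,
                                           scientific = FALSE)),
                        format(chem$concentration, digits = 15, trim = TRUE,
                               scientific = FALSE)))
  out <- data.frame(
    site_id = chem$site_id,
    watershed_id = chem$watershed_id,
    drainage_area_km2 = format(chem$drainage_area_km2, digits = 15,
                               trim = TRUE, scientific = FALSE),
    season = chem$season,
    solute = chem$solute,
    concentration = conc,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write the network edge list of a dataset
#'
#' @param dataset a `synoptic_dataset` with networks attached.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_network <- function(dataset, path, sep = ",") {
  stopifnot(inherits(dataset, "synoptic_dataset"),
            !is.null(dataset$networks))
  out <- do.call(rbind, lapply(dataset$networks, function(nw) {
    data.frame(site_id = nw$sites$site_id,
               downstream_id = ifelse(is.na(nw$sites$downstream_id), "",
                                      nw$sites$downstream_id),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Data-quality warnings for a synoptic dataset
#'
#' Flags conditions that weaken the downstream metrics without being outright
#' errors: too few sites per watershed x season x solute for the change-point
#' test to have power, a high fraction of missing cells, and solutes with zero
#' variance across sites (for which scaling is undefined).
#'
#' @param dataset a `synoptic_dataset`.
#' @param min_sites minimum sites per watershed x season x solute before a
#'   low-n warning is raised.
#' @return character vector of warnings (empty when the dataset is clean).
#' @export
validate_dataset <- function(dataset, min_sites = 10) {
  stopifnot(inherits(dataset, "synoptic_dataset"))
  warnings_out <- character(0)
  chem <- dataset$chem

  grp <- interaction(chem$watershed_id, chem$season, chem$solute, drop = TRUE,
                     sep = " / ")
  n_obs <- tapply(!is.na(chem$concentration), grp, sum)
  low <- names(n_obs)[n_obs < min_sites]
  if (length(low) > 0L) {
    warnings_out <- c(warnings_out, paste0(
      "low site count (<", min_sites, ") for: ", paste(low, collapse = "; ")))
  }

  frac_missing <- mean(is.na(chem$concentration))
  if (frac_missing > 0.2) {
    warnings_out <- c(warnings_out, sprintf(
      "%.0f%% of concentration cells are missing", 100 * frac_missing))
  }

  sds <- tapply(chem$concentration, grp,
                function(x) stats::sd(x, na.rm = TRUE))
  flat <- names(sds)[!is.na(sds) & sds == 0]
  if (length(flat) > 0L) {
    warnings_out <- c(warnings_out, paste0(
      "zero variance across sites for: ", paste(flat, collapse = "; ")))
  }

  warnings_out
}

# Extract the (area, concentration) series for one watershed/season/solute,
# sorted by the ordering convention shared with the change-point module.
chem_series <- function(dataset, watershed, season, solute,
                        drop_missing = TRUE) {
  chem <- dataset$chem
  sel <- chem$watershed_id == watershed & chem$season == season &
    chem$solute == solute
  out <- chem[sel, c("site_id", "drainage_area_km2", "concentration")]
  if (drop_missing) out <- out[!is.na(out$concentration), ]
  out[order(out$drainage_area_km2, out$site_id), ]
}
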