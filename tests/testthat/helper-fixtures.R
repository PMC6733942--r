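# Small in-code fixtures shared across test files.

# Three-site chain a -> b -> c(outlet), areas 1, 5, 10.
chain_network <- function() {
  stream_network(data.frame(
    site_id = c("a", "b", "c"),
    drainage_area_km2 = c(1, 5, 10),
    downstream_id = c("b", "c", NA)
  ), watershed_id = "W")
}

# Two headwaters mixing conservatively into an outlet:
# leaves (C = 3, a = 20) and (C = 1, a = 80); outlet area 100, zero
# incremental area, so C_out = (3*20 + 1*80)/100 = 1.4.
mixing_fixture <- function() {
  nw <- stream_network(data.frame(
    site_id = c("h1", "h2", "out"),
    drainage_area_km2 = c(20, 80, 100),
    downstream_id = c("out", "out", NA)
  ), watershed_id = "W")
  chem <- data.frame(
    site_id = rep(c("h1", "h2", "out"), 1),
    watershed_id = "W",
    drainage_area_km2 = c(20, 80, 100),
    season = "early",
    solute = "DOC",
    concentration = c(3, 1, 1.4),
    below_lod = FALSE
  )
  sites <- data.frame(site_id = c("h1", "h2", "out"), watershed_id = "W",
                      drainage_area_km2 = c(20, 80, 100),
                      downstream_id = c("out", "out", NA))
  ds <- synoptic:::new_synoptic_dataset(
    chem = chem, sites = sites, networks = list(W = nw),
    seasons = "early", solutes = "DOC")
  list(network = nw, dataset = ds)
}

# Long-format chemistry table written to a temp file.
write_chem_fixture <- function(rows, path = tempfile(fileext = ".csv")) {
  utils::write.table(rows, path, sep = ",", row.names = FALSE, quote = FALSE)
  path
}

# Dataset with paired-season concentrations for one watershed, given two
# equal-length concentration vectors.
paired_season_dataset <- function(x, y, solute = "DOC") {
  n <- length(x)
  ids <- sprintf("s%02d", seq_len(n))
  areas <- seq_len(n)
  areas[n] <- n + 100 # outlet largest
  nw <- stream_network(data.frame(
    site_id = ids,
    drainage_area_km2 = areas,
    downstream_id = c(ids[-1], NA)
  ), watershed_id = "W")
  chem <- rbind(
    data.frame(site_id = ids, watershed_id = "W",
               drainage_area_km2 = areas, season = "early", solute = solute,
               concentration = x, below_lod = FALSE),
    data.frame(site_id = ids, watershed_id = "W",
               drainage_area_km2 = areas, season = "late", solute = solute,
               concentration = y, below_lod = FALSE)
  )
  sites <- data.frame(site_id = ids, watershed_id = "W",
                      drainage_area_km2 = areas,
                      downstream_id = c(ids[-1], NA))
  synoptic:::new_synoptic_dataset(
    chem = chem, sites = sites, networks = list(W = nw),
    seasons = c("early", "late"), solutes = solute)
}

# Scaled series from raw vectors without going through a dataset.
as_scaled_series <- function(z, area = seq_along(z)) {
  structure(list(area = area, z = z,
                 site_id = as.character(seq_along(z)),
                 n = length(z)),
            class = "scaled_series")
}

# Brute-force two-segment variance LR, independent of the implementation:
# plain loops, ML variances computed with mean()/sum() directly.
brute_force_lr <- function(z, min_segment) {
  n <- length(z)
  best_k <- NA_integer_
  best_lr <- -Inf
  mlvar <- function(x) max(mean((x - mean(x))^2), 1e-12)
  for (k in min_segment:(n - min_segment)) {
    lr <- n * log(mlvar(z)) - k * log(mlvar(z[1:k])) -
      (n - k) * log(mlvar(z[(k + 1):n]))
    if (lr > best_lr) {
      best_lr <- lr
      best_k <- k
    }
  }
  list(k = best_k, lr = best_lr)
}
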