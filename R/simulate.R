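#' Configuration for a synthetic watershed
#'
#' Describes one simulated watershed: a random binary stream network whose
#' reaches carry lognormal incremental areas, a patch-structured solute
#' source field with a controllable characteristic patch area, conservative
#' area-weighted routing with optional net first-order reaction, and a
#' Gaussian copula coupling the two seasons' source fields.
#'
#' Parameters (all per watershed; `patch_area_km2`, `k_r` and `rho_season`
#' may be vectors named by solute):
#' \describe{
#'   \item{n_headwaters}{number of headwater (leaf) reaches; the network has
#'     `2 * n_headwaters - 1` reaches in total.}
#'   \item{area_lognormal_mu, area_lognormal_sigma}{log-scale mean and sd of
#'     incremental reach areas (km2). The defaults (0, 1) give a ~130 km2
#'     watershed at 40 headwaters, so patch areas of 3-30 km2 sit well inside
#'     the span of sampled drainage areas.}
#'   \item{patch_area_km2}{characteristic area of a source/sink patch: the
#'     greedy patch partition closes a patch once its accumulated incremental
#'     area reaches this value.}
#'   \item{patch_sd, local_sd}{between-patch and within-patch (site-level) sd
#'     of the local source concentration. The default 2 / 0.3 ratio makes
#'     patches the dominant source of spatial variance, which is the regime
#'     the variance-collapse metric targets.}
#'   \item{baseline_concentration}{mean local source concentration (mg/L);
#'     sources are truncated at zero.}
#'   \item{k_r}{net per-reach first-order reaction: concentrations are
#'     multiplied by `exp(-k_r)` at every reach, so `k_r > 0` is net removal,
#'     `k_r < 0` net production, `0` exact conservative mixing.}
#'   \item{rho_season}{correlation of the Gaussian copula sharing the patch
#'     and site deviates between seasons; the induced between-season Spearman
#'     correlation of the source field is `(6 / pi) * asin(rho / 2)`.}
#'   \item{n_sites_sampled}{number of reaches reported in the chemistry
#'     table (the outlet is always included); `NULL` samples every reach.}
#'   \item{source_at}{`"all"` gives every reach a positive incremental area;
#'     `"leaves"` gives internal junction reaches zero incremental area so
#'     all solute mass enters at the leaves — the configuration in which the
#'     conservative zero-mean leverage contract holds exactly on the leaf
#'     partition.}
#' }
#'
#' @param watershed_id name of the simulated watershed.
#' @param n_headwaters,area_lognormal_mu,area_lognormal_sigma,patch_area_km2
#'   see Details.
#' @param patch_sd,local_sd,baseline_concentration,k_r,rho_season see
#'   Details.
#' @param n_sites_sampled,source_at see Details.
#' @return a `sim_config` list.
#' @export
sim_config <- function(watershed_id = "synthetic",
                       n_headwaters = 40,
                       area_lognormal_mu = 0,
                       area_lognormal_sigma = 1,
                       patch_area_km2 = 10,
                       patch_sd = 2,
                       local_sd = 0.3,
                       baseline_concentration = 5,
                       k_r = 0,
                       rho_season = 0.7,
                       n_sites_sampled = NULL,
                       source_at = c("all", "leaves")) {
  source_at <- match.arg(source_at)
  stopifnot(all(patch_area_km2 > 0),
            all(abs(rho_season) <= 1),
            patch_sd >= 0, local_sd >= 0,
            baseline_concentration > 0)
  if (n_headwaters < 2) stop("n_headwaters must be >= 2", call. = FALSE)
  structure(
    list(watershed_id = watershed_id,
         n_headwaters = as.integer(n_headwaters),
         area_lognormal_mu = area_lognormal_mu,
         area_lognormal_sigma = area_lognormal_sigma,
         patch_area_km2 = patch_area_km2,
         patch_sd = patch_sd, local_sd = local_sd,
         baseline_concentration = baseline_concentration,
         k_r = k_r, rho_season = rho_season,
         n_sites_sampled = n_sites_sampled,
         source_at = source_at),
    class = "sim_config"
  )
}

#' Generate a random stream network
#'
#' Builds a random binary tree by uniform random attachment: starting from an
#' outlet with one headwater, each new headwater splits a uniformly chosen
#' existing edge, inserting a junction. Every reach then receives an
#' incremental area drawn from LogNormal(mu, sigma) (junction reaches get
#' zero area when `source_at = "leaves"`), and cumulative drainage areas are
#' accumulated downstream.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the network is deterministic given the seed.
#' @return a [stream_network].
#' @export
generate_network <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    n_leaves <- config$n_headwaters
    # parent[i] = downstream node index; node 1 is the outlet reach, which
    # starts with two headwaters; each further headwater splits a uniformly
    # chosen edge with a new junction. Total reaches: 2 * n_leaves - 1.
    parent <- c(NA_integer_, 1L, 1L)
    is_leaf <- c(FALSE, TRUE, TRUE)
    for (leaf in seq_len(n_leaves - 2L)) {
      candidates <- which(!is.na(parent))
      child <- if (length(candidates) == 1L) candidates else
        sample(candidates, 1L)
      junction <- length(parent) + 1L
      parent <- c(parent, parent[child], junction)
      parent[child] <- junction
      is_leaf <- c(is_leaf, FALSE, TRUE)
    }
    n <- length(parent)
    incr <- stats::rlnorm(n, config$area_lognormal_mu,
                          config$area_lognormal_sigma)
    if (config$source_at == "leaves") incr[!is_leaf] <- 0

    # cumulative areas: process nodes leaves-first by depth
    depth <- integer(n)
    for (i in seq_len(n)) {
      cur <- i; d <- 0L
      while (!is.na(parent[cur])) { cur <- parent[cur]; d <- d + 1L }
      depth[i] <- d
    }
    cum <- incr
    for (i in order(depth, decreasing = TRUE)) {
      if (!is.na(parent[i])) cum[parent[i]] <- cum[parent[i]] + cum[i]
    }

    ids <- sprintf("%s_s%02d", config$watershed_id, seq_len(n))
    # zero-area junctions still need a positive cumulative area; they do, as
    # they always have upstream leaves. Guard tiny areas for validity.
    sites <- data.frame(
      site_id = ids,
      drainage_area_km2 = cum,
      downstream_id = ifelse(is.na(parent), NA_character_, ids[parent]),
      stringsAsFactors = FALSE
    )
    stream_network(sites, config$watershed_id)
  })
}

#' Greedy patch partition of a network
#'
#' Assigns every reach to a landscape patch of characteristic area
#' `patch_area_km2`: reaches are visited in post-order (headwaters before
#' junctions, so patches are spatially coherent subtrees) and the current
#' patch is closed as soon as its accumulated incremental area reaches the
#' target. A trailing patch smaller than the target is merged into the last
#' closed patch. Patch areas therefore lie in
#' `[patch_area_km2, patch_area_km2 + max incremental area)` apart from the
#' merged tail.
#'
#' @param network a [stream_network].
#' @param patch_area_km2 target patch area (km2).
#' @return named integer vector: patch id per site id.
#' @export
partition_patches <- function(network, patch_area_km2) {
  stopifnot(inherits(network, "stream_network"), patch_area_km2 > 0)
  total <- outlet_area(network)
  ids <- network$post_order
  incr <- network$sites$incremental_area_km2[match(ids,
                                                   network$sites$site_id)]
  if (patch_area_km2 >= total) {
    warning("patch_area_km2 >= watershed area; single patch")
    return(stats::setNames(rep(1L, length(ids)), ids))
  }
  patch <- integer(length(ids))
  cur <- 1L
  acc <- 0
  for (i in seq_along(ids)) {
    patch[i] <- cur
    acc <- acc + incr[i]
    if (acc >= patch_area_km2) {
      cur <- cur + 1L
      acc <- 0
    }
  }
  # merge an unfinished tail patch into the previous one
  if (acc > 0 && acc < patch_area_km2 && cur > 1L) {
    patch[patch == cur] <- cur - 1L
  }
  stats::setNames(patch, ids)
}

#' Generate patch-structured local source concentrations for two seasons
#'
#' Each patch p draws an amplitude `u_p ~ N(0, 1)`; reaches inside the patch
#' receive the deviation `patch_sd * u_p * s_i`, where the fixed geometric
#' pattern `s_i` (+1 over the first half of the patch's area, -1 over the
#' second, fractional on the crossing reach) integrates to zero over the
#' patch: `sum(a_i * s_i) = 0`. Each site adds local noise `local_sd * e_i`
#' and concentrations are truncated at zero.
#'
#' The zero-integral construction is what makes the patch area a true
#' variance-collapse scale: a subcatchment smaller than a patch sits inside
#' the patch's internal gradient and sees the full amplitude, while a
#' subcatchment that integrates whole patches cancels them exactly and
#' retains only boundary fragments, so among-site variance drops sharply at
#' `patch_area_km2`. (An i.i.d. patch-mean field would instead decay by the
#' central limit theorem, ~1/area, leaving no well-defined collapse scale.)
#'
#' The two seasons share the `u` and `e` deviates through a Gaussian copula
#' with correlation `rho_season`, so `rho = 1` reproduces the early field
#' exactly and `rho = 0` draws the late field independently; the geometric
#' pattern `s_i` is landscape structure and is common to both seasons.
#'
#' @param network a [stream_network].
#' @param patches patch assignment from [partition_patches()].
#' @param config a [sim_config()] (`patch_sd`, `local_sd`, `baseline`,
#'   `rho_season` are used; scalar values only — per-solute vectors are
#'   handled by [simulate_dataset()]).
#' @param seed integer seed.
#' @param rho_season optional override of `config$rho_season`.
#' @return list with elements `early` and `late`, each a named numeric
#'   vector of local source concentrations per site.
#' @export
generate_source_field <- function(network, patches, config, seed,
                                  rho_season = NULL) {
  stopifnot(inherits(network, "stream_network"))
  rho <- if (is.null(rho_season)) config$rho_season[1] else rho_season
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    ids <- names(patches)
    n_patch <- max(patches)
    n <- length(ids)

    # zero-integral within-patch pattern: +1 over the first half of each
    # patch's area, -1 over the second, fractional on the crossing reach so
    # that sum(a_i * s_i) = 0 exactly (single-reach patches get s = 0)
    incr <- network$sites$incremental_area_km2[match(ids,
                                                     network$sites$site_id)]
    s_pat <- numeric(n)
    for (p in seq_len(n_patch)) {
      idx <- which(patches == p) # contiguous in post-order
      a <- incr[idx]
      total <- sum(a)
      if (length(idx) == 1L || total == 0) next
      acc <- cumsum(a)
      before <- c(0, acc[-length(acc)])
      j <- which(before <= total / 2 & acc >= total / 2)[1]
      s <- ifelse(acc <= total / 2, 1, -1)
      s[j] <- (total - 2 * before[j] - a[j]) / a[j]
      s_pat[idx] <- s
    }

    u1 <- stats::rnorm(n_patch)
    e1 <- stats::rnorm(n)
    u2 <- rho * u1 + sqrt(1 - rho^2) * stats::rnorm(n_patch)
    e2 <- rho * e1 + sqrt(1 - rho^2) * stats::rnorm(n)
    field <- function(u, e) {
      m <- config$baseline_concentration +
        config$patch_sd * u[patches] * s_pat
      stats::setNames(pmax(0, m + config$local_sd * e), ids)
    }
    list(early = field(u1, e1), late = field(u2, e2))
  })
}

#' Route local sources through the network by conservative mixing
#'
#' Computes in-stream concentrations: in post-order, each reach mixes its
#' upstream inputs with its local source in proportion to drainage area
#' (area-proportional runoff), then applies the net reaction factor
#' `exp(-k_r)`. With `k_r = 0` this is exact conservative mixing and the
#' outlet concentration equals the incremental-area-weighted mean of all
#' local sources.
#'
#' @param network a [stream_network].
#' @param sources named numeric vector of local source concentrations per
#'   site (from [generate_source_field()]).
#' @param k_r net per-reach reaction rate (+ removal, - production, 0
#'   conservative).
#' @return named numeric vector of in-stream concentrations per site.
#' @export
route_and_mix <- function(network, sources, k_r = 0) {
  stopifnot(inherits(network, "stream_network"))
  s <- network$sites
  ord <- match(network$post_order, s$site_id)
  conc <- stats::setNames(rep(NA_real_, nrow(s)), s$site_id)
  load <- stats::setNames(rep(0, nrow(s)), s$site_id) # accumulated C * A
  for (i in ord) {
    id <- s$site_id[i]
    kids <- s$site_id[!is.na(s$downstream_id) & s$downstream_id == id]
    inflow <- if (length(kids)) sum(load[kids]) else 0
    local <- sources[[id]] * s$incremental_area_km2[i]
    c_here <- (inflow + local) / s$drainage_area_km2[i]
    c_here <- c_here * exp(-k_r)
    conc[id] <- c_here
    load[id] <- c_here * s$drainage_area_km2[i]
  }
  conc
}

#' Simulate a complete multi-watershed synoptic dataset
#'
#' Builds one network per configuration, partitions it into patches,
#' generates coupled early/late source fields for each solute, routes them
#' to in-stream concentrations, and assembles a `synoptic_dataset` from a
#' sampled subset of reaches (always including the outlet). A truth record
#' stores the generating parameters per watershed x solute for parameter
#' recovery.
#'
#' @param configs a [sim_config()] or list of them (one per watershed).
#' @param seed integer master seed; all derived draws are deterministic.
#' @param solutes solute names; per-solute `patch_area_km2`, `k_r` and
#'   `rho_season` vectors in the configs are matched by name or recycled.
#' @return list with `dataset` (a `synoptic_dataset`, networks attached) and
#'   `truth` (data.frame: watershed, solute, patch_area_km2, k_r, rho_season,
#'   n_sites).
#' @export
simulate_dataset <- function(configs, seed,
                             solutes = c("DOC", "NO3", "SRP")) {
  if (inherits(configs, "sim_config")) configs <- list(configs)
  seed <- as.integer(seed) %% .Machine$integer.max

  param_for <- function(p, solute, j) {
    if (!is.null(names(p)) && solute %in% names(p)) p[[solute]]
    else p[[(j - 1L) %% length(p) + 1L]]
  }

  chem_rows <- list()
  truth_rows <- list()
  networks <- list()
  site_rows <- list()

  for (w in seq_along(configs)) {
    cfg <- configs[[w]]
    nw_full <- generate_network(cfg, seed = seed + 1000L * w)
    s <- nw_full$sites

    n_samp <- if (is.null(cfg$n_sites_sampled)) nrow(s) else
      cfg$n_sites_sampled
    if (n_samp > nrow(s)) {
      stop("config error: n_sites_sampled (", n_samp,
           ") exceeds number of reaches (", nrow(s), ") in watershed '",
           cfg$watershed_id, "'", call. = FALSE)
    }
    sampled <- withr::with_seed(seed + 1000L * w + 1L, {
      others <- setdiff(s$site_id, nw_full$outlet_id)
      c(nw_full$outlet_id, sample(others, n_samp - 1L))
    })

    for (j in seq_along(solutes)) {
      sol <- solutes[j]
      a_p <- param_for(cfg$patch_area_km2, sol, j)
      k_r <- param_for(cfg$k_r, sol, j)
      rho <- param_for(cfg$rho_season, sol, j)

      patches <- partition_patches(nw_full, a_p)
      fields <- generate_source_field(nw_full, patches, cfg,
                                      seed = seed + 1000L * w + 10L * j,
                                      rho_season = rho)
      for (season in c("early", "late")) {
        conc <- route_and_mix(nw_full, fields[[season]], k_r = k_r)
        keep <- match(sampled, s$site_id)
        chem_rows[[length(chem_rows) + 1L]] <- data.frame(
          site_id = s$site_id[keep],
          watershed_id = cfg$watershed_id,
          drainage_area_km2 = s$drainage_area_km2[keep],
          season = season,
          solute = sol,
          concentration = as.numeric(conc[sampled]),
          below_lod = FALSE,
          stringsAsFactors = FALSE
        )
      }
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        watershed_id = cfg$watershed_id, solute = sol,
        patch_area_km2 = a_p, k_r = k_r, rho_season = rho,
        n_sites = n_samp, stringsAsFactors = FALSE
      )
    }

    # network restricted to sampled sites: reconnect each sampled site to
    # its nearest sampled downstream neighbour
    parent_of <- stats::setNames(s$downstream_id, s$site_id)
    down_sampled <- vapply(sampled, function(id) {
      cur <- parent_of[[id]]
      while (!is.na(cur) && !(cur %in% sampled)) cur <- parent_of[[cur]]
      if (is.na(cur)) NA_character_ else cur
    }, character(1))
    sub <- data.frame(
      site_id = sampled,
      drainage_area_km2 = s$drainage_area_km2[match(sampled, s$site_id)],
      downstream_id = unname(down_sampled),
      stringsAsFactors = FALSE
    )
    networks[[cfg$watershed_id]] <- stream_network(sub, cfg$watershed_id)
    site_rows[[w]] <- data.frame(
      site_id = sub$site_id, watershed_id = cfg$watershed_id,
      drainage_area_km2 = sub$drainage_area_km2,
      downstream_id = sub$downstream_id, stringsAsFactors = FALSE
    )
  }

  chem <- do.call(rbind, chem_rows)
  rownames(chem) <- NULL
  dataset <- new_synoptic_dataset(
    chem = chem,
    sites = do.call(rbind, site_rows),
    networks = networks,
    seasons = c("early", "late"),
    solutes = solutes,
    provenance = sprintf("simulate_dataset(seed = %d)", seed)
  )
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  list(dataset = dataset, truth = truth)
}

#' Three-watershed configuration mimicking an Arctic synoptic design
#'
#' Convenience set of three `sim_config`s shaped like a typical repeated
#' synoptic study: a homogeneous tundra watershed (42 sites, large patches,
#' high seasonal persistence), a lake-dominated watershed (41 sites, small
#' patches, strong seasonal reorganisation) and a steep alpine watershed
#' (31 sites, intermediate patches, near-conservative transport).
#'
#' @return list of three [sim_config()] objects.
#' @export
default_study_configs <- function() {
  list(
    sim_config("Tundra", n_headwaters = 40, patch_area_km2 = 20,
               k_r = c(DOC = -0.02, NO3 = 0.05, SRP = -0.03),
               rho_season = c(DOC = 0.85, NO3 = 0.3, SRP = 0.3),
               n_sites_sampled = 42),
    sim_config("Lake", n_headwaters = 40, patch_area_km2 = 5,
               k_r = c(DOC = -0.03, NO3 = 0.02, SRP = 0.04),
               rho_season = c(DOC = 0.15, NO3 = 0.4, SRP = 0.6),
               n_sites_sampled = 41),
    sim_config("Alpine", n_headwaters = 35, patch_area_km2 = 10,
               k_r = c(DOC = 0, NO3 = 0, SRP = -0.02),
               rho_season = c(DOC = 0.65, NO3 = 0.5, SRP = 0.3),
               n_sites_sampled = 31)
  )
}
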