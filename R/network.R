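#' Stream-network topology for one watershed
#'
#' A `stream_network` is a rooted tree of sampling sites (reaches). Each site
#' drains a cumulative area `drainage_area_km2` and points to the site
#' immediately downstream (`downstream_id`); the single site with no
#' downstream link is the watershed outlet (the root). The incremental area of
#' a site is its cumulative area minus the cumulative areas of its immediate
#' upstream neighbours, i.e. the land that drains to this site but to no other
#' sampled site. Incremental areas partition the watershed: they are
#' non-negative and sum to the outlet's drainage area.
#'
#' @param sites data.frame with columns `site_id`, `drainage_area_km2`,
#'   `downstream_id` (`NA` for the outlet).
#' @param watershed_id single string naming the watershed.
#'
#' @return An object of class `stream_network`: a list with elements
#'   `watershed_id`, `sites` (the input plus `incremental_area_km2`),
#'   `outlet_id`, and `post_order` (site ids ordered leaves-first so every
#'   site precedes its downstream neighbour).
#' @export
stream_network <- function(sites, watershed_id) {
  stopifnot(is.data.frame(sites))
  required <- c("site_id", "drainage_area_km2", "downstream_id")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols) > 0L) {
    stop("stream_network: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sites <- data.frame(
    site_id = as.character(sites$site_id),
    drainage_area_km2 = as.numeric(sites$drainage_area_km2),
    downstream_id = as.character(sites$downstream_id),
    stringsAsFactors = FALSE
  )
  sites$downstream_id[!is.na(sites$downstream_id) &
                        sites$downstream_id == ""] <- NA_character_

  if (anyDuplicated(sites$site_id)) {
    stop("stream_network: duplicated site_id in watershed '", watershed_id,
         "'", call. = FALSE)
  }
  if (any(!is.finite(sites$drainage_area_km2)) ||
      any(sites$drainage_area_km2 <= 0)) {
    bad <- sites$site_id[!is.finite(sites$drainage_area_km2) |
                           sites$drainage_area_km2 <= 0]
    stop("stream_network: non-positive drainage area at site(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  is_outlet <- is.na(sites$downstream_id)
  if (sum(is_outlet) != 1L) {
    stop("topology error in watershed '", watershed_id, "': expected exactly ",
         "one outlet (empty downstream_id), found ", sum(is_outlet),
         call. = FALSE)
  }
  outlet_id <- sites$site_id[is_outlet]

  unknown <- setdiff(stats::na.omit(sites$downstream_id), sites$site_id)
  if (length(unknown) > 0L) {
    stop("topology error in watershed '", watershed_id,
         "': downstream_id refers to unknown site(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  n <- nrow(sites)
  parent <- match(sites$downstream_id, sites$site_id) # NA at outlet

  # Cycle check: walk each site towards the root; more than n steps => cycle.
  for (start in seq_len(n)) {
    cur <- start
    path <- integer(0)
    steps <- 0L
    while (!is.na(cur)) {
      steps <- steps + 1L
      if (steps > n) {
        cyc <- unique(sites$site_id[path])
        stop("topology error in watershed '", watershed_id,
             "': cycle involving site(s): ", paste(cyc, collapse = " -> "),
             call. = FALSE)
      }
      path <- c(path, cur)
      cur <- parent[cur]
    }
  }

  # Nesting: a site cannot drain more area than the site downstream of it.
  up_idx <- which(!is.na(parent))
  bad <- up_idx[sites$drainage_area_km2[up_idx] >
                  sites$drainage_area_km2[parent[up_idx]]]
  if (length(bad) > 0L) {
    stop("nesting error in watershed '", watershed_id, "': site(s) ",
         paste(sites$site_id[bad], collapse = ", "),
         " drain more area than their downstream site", call. = FALSE)
  }

  children_area <- vapply(seq_len(n), function(i) {
    sum(sites$drainage_area_km2[which(parent == i)])
  }, numeric(1))
  incr <- sites$drainage_area_km2 - children_area
  if (any(incr < -1e-9 * sites$drainage_area_km2)) {
    bad <- sites$site_id[incr < -1e-9 * sites$drainage_area_km2]
    stop("nesting error in watershed '", watershed_id,
         "': upstream areas exceed cumulative area at site(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  incr[incr < 0] <- 0
  sites$incremental_area_km2 <- incr

  # Post-order: children before parents (iterative DFS from the outlet).
  kids <- split(seq_len(n), factor(parent, levels = seq_len(n)))
  order_idx <- integer(0)
  stack <- which(is_outlet)
  emit <- integer(0)
  while (length(stack) > 0L) {
    node <- stack[length(stack)]
    stack <- stack[-length(stack)]
    emit <- c(emit, node)
    stack <- c(stack, kids[[node]])
  }
  order_idx <- rev(emit)

  structure(
    list(
      watershed_id = as.character(watershed_id),
      sites = sites,
      outlet_id = outlet_id,
      post_order = sites$site_id[order_idx]
    ),
    class = "stream_network"
  )
}

#' @export
print.stream_network <- function(x, ...) {
  cat("<stream_network> watershed '", x$watershed_id, "': ",
      nrow(x$sites), " sites, outlet ", x$outlet_id, " (",
      format(x$sites$drainage_area_km2[x$sites$site_id == x$outlet_id],
             digits = 4),
      " km2)\n", sep = "")
  invisible(x)
}

#' Headwater (leaf) sites of a network
#'
#' Sites with no sampled upstream neighbour. Their drainage areas are mutually
#' disjoint, which makes them the natural partition for mass-conservation
#' checks.
#'
#' @param network a `stream_network`.
#' @return character vector of site ids.
#' @export
network_leaves <- function(network) {
  stopifnot(inherits(network, "stream_network"))
  with_kids <- unique(stats::na.omit(network$sites$downstream_id))
  setdiff(network$sites$site_id, with_kids)
}

#' Outlet drainage area of a network
#' @param network a `stream_network`.
#' @return numeric, km2.
#' @export
outlet_area <- function(network) {
  network$sites$drainage_area_km2[network$sites$site_id == network$outlet_id]
}
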