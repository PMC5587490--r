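# Synthetic atlas generator: landscape -> biased effort -> community ->
# checklists, with every stage seeded and all hidden parameters recorded
# so that downstream estimates can be checked against known truth.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

#' Landscape configuration for the synthetic atlas
#'
#' Defines a rectangular pentad grid with three smooth climate surfaces
#' (linear gradient from a hot, dry north-west corner to a moist, mild
#' south-east corner, plus low-order sinusoidal terrain noise), a
#' nearest-seed biome partition, sampling hubs, a densified road
#' polyline, and protected/urban/cultivated cover fields.
#'
#' Climate smoothness comes from a small sinusoidal basis rather than a
#' Gaussian-process draw: cheap, exactly reproducible, and sufficient to
#' produce spatially contiguous climate classes. With `noise_amp = 0`
#' every climate surface is exactly linear in the grid coordinates.
#'
#' @param nrow,ncol grid extent in pentads (each >= 4).
#' @param lat0,lon0 NW corner of the grid, decimal degrees (south
#'   negative).
#' @param noise_amp relative amplitude of the smooth climate noise
#'   (multiplies each variable's nominal noise scale; >= 0).
#' @param n_biomes number of biome seed points (at most 7 named biomes).
#' @param n_hubs number of sampling hubs.
#' @param road_waypoints extra random waypoints on the road polyline.
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(nrow = 40L, ncol = 40L, lat0 = -26, lon0 = 22,
                             noise_amp = 1, n_biomes = 7L, n_hubs = 4L,
                             road_waypoints = 16L) {
  stopifnot(nrow >= 4L, ncol >= 4L, noise_amp >= 0, n_hubs >= 1L,
            n_biomes >= 1L, n_biomes <= 7L)
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 lat0 = lat0, lon0 = lon0, noise_amp = noise_amp,
                 n_biomes = as.integer(n_biomes), n_hubs = as.integer(n_hubs),
                 road_waypoints = as.integer(road_waypoints)),
            class = "landscape_config")
}

.biome_names <- c("Savanna", "Grassland", "NamaKaroo", "Fynbos",
                  "SucculentKaroo", "AlbanyThicket", "IOCB")

# smooth 2D field on [0,1]^2: K random-orientation sinusoids, unit-ish scale
.smooth_field <- function(u, v, k = 4L) {
  z <- numeric(length(u))
  for (i in seq_len(k)) {
    a <- stats::runif(1, 0.5, 3); b <- stats::runif(1, 0.5, 3)
    ph <- stats::runif(1, 0, 2 * pi)
    z <- z + sin(2 * pi * (a * u + b * v) + ph) / i
  }
  z / sqrt(sum(1 / seq_len(k)^2) / 2) # approx unit sd
}

#' Generate a synthetic landscape
#'
#' Deterministic given `seed`. Returns the per-pentad covariate table
#' (including derived hub and road distances), the landmark sets, the
#' biome map and the grid indexing needed by later stages.
#'
#' @param config a [landscape_config()].
#' @param seed integer RNG seed.
#' @return a `landscape` list with elements `covariates`
#'   (`pentad_covariates`, incl. `dist_hub_km`, `dist_road_km`), `grid`
#'   (pentad, row, col, midpoint coords), `hubs` (pentad codes),
#'   `hub_points`, `road_points` (lat/lon matrices) and `biome`
#'   (dominant biome per pentad).
#' @export
generate_landscape <- function(config = landscape_config(), seed = 1L) {
  stopifnot(inherits(config, "landscape_config"))
  .with_seed(seed, {
    nr <- config$nrow; nc <- config$ncol
    step <- 5 / 60
    g <- expand.grid(row = seq_len(nr), col = seq_len(nc))
    lat_corner <- config$lat0 - (g$row - 1) * step
    lon_corner <- config$lon0 + (g$col - 1) * step
    pentad <- encode_pentad(lat_corner, lon_corner)
    mid_lat <- lat_corner - step / 2
    mid_lon <- lon_corner + step / 2
    u <- (g$row - 1) / (nr - 1)   # 0 = north edge
    v <- (g$col - 1) / (nc - 1)   # 0 = west edge
    grad <- (u + v) / 2           # NW (hot, dry) -> SE (moist, mild)

    amp <- config$noise_amp
    precip   <- 150 + 750 * grad + amp * 60 * .smooth_field(u, v)
    t_summer <- 33 - 11 * grad + amp * 1.2 * .smooth_field(u, v)
    t_winter <- 6 + 7 * grad + amp * 2.0 * .smooth_field(u, v)
    precip <- pmax(precip, 10)

    # biomes: nearest seed point in grid coordinates
    labs <- .biome_names[seq_len(config$n_biomes)]
    seeds_uv <- cbind(stats::runif(config$n_biomes), stats::runif(config$n_biomes))
    d2 <- outer(u, seeds_uv[, 1], "-")^2 + outer(v, seeds_uv[, 2], "-")^2
    nearest <- max.col(-d2)
    biome <- labs[nearest]
    # dominant-biome fraction with a little mixing from the runner-up
    dom_frac <- stats::runif(length(u), 0.55, 0.95)
    second <- if (config$n_biomes > 1L) {
      d2b <- d2; d2b[cbind(seq_along(nearest), nearest)] <- Inf
      labs[max.col(-d2b)]
    } else biome
    bf <- matrix(0, length(u), length(labs), dimnames = list(NULL, labs))
    bf[cbind(seq_along(nearest), match(biome, labs))] <- dom_frac
    bf[cbind(seq_along(nearest), match(second, labs))] <-
      bf[cbind(seq_along(nearest), match(second, labs))] + (1 - dom_frac)

    # hubs: distinct random pentads, kept off the outer edge
    inner <- which(g$row > 1 & g$row < nr & g$col > 1 & g$col < nc)
    hub_idx <- sample(inner, config$n_hubs)
    hub_points <- cbind(lat = mid_lat[hub_idx], lon = mid_lon[hub_idx])
    # road: polyline through hubs plus random waypoints, densified ~1 km
    way <- cbind(lat = stats::runif(config$road_waypoints,
                                    min(mid_lat), max(mid_lat)),
                 lon = stats::runif(config$road_waypoints,
                                    min(mid_lon), max(mid_lon)))
    verts <- rbind(hub_points, way)
    verts <- verts[order(verts[, "lon"]), , drop = FALSE]
    road_points <- .densify_polyline(verts, max_km = 1)

    dist_hub <- .min_dist_to_set(mid_lat, mid_lon, hub_points)
    dist_road <- .min_dist_to_set(mid_lat, mid_lon, road_points)

    urban <- pmin(1, 0.85 * exp(-(dist_hub / 12)^2) +
                    0.05 * stats::rbeta(length(u), 0.6, 8))
    res_ctr <- cbind(lat = stats::runif(3, min(mid_lat), max(mid_lat)),
                     lon = stats::runif(3, min(mid_lon), max(mid_lon)))
    dist_res <- .min_dist_to_set(mid_lat, mid_lon, res_ctr)
    protected <- pmin(1, 0.9 * exp(-(dist_res / 20)^2))
    cultivated <- pmin(1, pmax(0, 0.55 * stats::plogis((precip - 550) / 120) +
                                 0.1 * .smooth_field(u, v)))

    cov <- data.frame(pentad = pentad, precip = precip, t_summer = t_summer,
                      t_winter = t_winter, protected = protected,
                      urban = urban, cultivated = cultivated,
                      dist_hub_km = dist_hub, dist_road_km = dist_road,
                      stringsAsFactors = FALSE)
    cov <- cbind(cov, as.data.frame(bf) |> stats::setNames(paste0("biome_", labs)))
    cov <- as_pentad_covariates(cov)

    structure(list(
      covariates = cov,
      grid = data.frame(pentad = pentad, row = g$row, col = g$col,
                        midpoint_lat = mid_lat, midpoint_lon = mid_lon,
                        stringsAsFactors = FALSE),
      hubs = pentad[hub_idx],
      hub_points = hub_points,
      road_points = road_points,
      biome = stats::setNames(biome, pentad),
      config = config, seed = seed
    ), class = "landscape")
  })
}

# interpolate extra vertices so consecutive points are <= max_km apart
.densify_polyline <- function(verts, max_km = 1) {
  if (nrow(verts) < 2L) return(verts)
  out <- list(verts[1, , drop = FALSE])
  for (i in seq_len(nrow(verts) - 1L)) {
    a <- verts[i, ]; b <- verts[i + 1L, ]
    d <- haversine_km(a, b)
    nseg <- max(1L, ceiling(d / max_km))
    tfrac <- seq_len(nseg) / nseg
    out[[i + 1L]] <- cbind(lat = a[1] + tfrac * (b[1] - a[1]),
                           lon = a[2] + tfrac * (b[2] - a[2]))
  }
  do.call(rbind, out)
}

.min_dist_to_set <- function(lat, lon, points) {
  pts <- as.matrix(points)
  apply(cbind(lat, lon), 1L, function(p) {
    min(haversine_km(matrix(p, nrow = nrow(pts), ncol = 2, byrow = TRUE), pts))
  })
}

#' Effort-model coefficients for the synthetic generator
#'
#' Log-scale coefficients of the visit-count generator: the linear
#' predictor is
#' `b0 + b_loghub*log(dist_hub_km) + b_road*dist_road_km +
#'  b_prot*protected + b_urban*urban + b_cult*cultivated +
#'  b_precip*z(precip) + b_tsummer*z(t_summer) + b_twinter*z(t_winter)`
#' with climate variables standardized across the included pentads.
#'
#' Default signs follow the field's expectation for volunteer atlases:
#' effort decays with distance to hubs and roads and rises with
#' protected and urban cover; under the defaults roughly three quarters
#' of pentads receive at least one visit while well under a fifth
#' receive ten or more, matching a mature but uneven national atlas.
#'
#' @param b0 intercept (log expected visits at baseline).
#' @param b_loghub per unit log(km) to nearest hub (negative = decay).
#' @param b_road per km to nearest road.
#' @param b_prot,b_urban,b_cult per unit cover fraction.
#' @param b_precip,b_tsummer,b_twinter per standardized climate unit.
#' @return an `effort_coefficients` named numeric vector.
#' @export
effort_coefficients <- function(b0 = 3.2, b_loghub = -0.45, b_road = -0.03,
                                b_prot = 1.5, b_urban = 2.0, b_cult = 0.3,
                                b_precip = 0.15, b_tsummer = -0.1,
                                b_twinter = 0.1) {
  x <- c(b0 = b0, b_loghub = b_loghub, b_road = b_road, b_prot = b_prot,
         b_urban = b_urban, b_cult = b_cult, b_precip = b_precip,
         b_tsummer = b_tsummer, b_twinter = b_twinter)
  stopifnot(all(is.finite(x)))
  structure(x, class = "effort_coefficients")
}

#' Generate per-pentad visit counts
#'
#' Draws visit counts from a Poisson log-linear model of the landscape
#' covariates — the same model family the effort analysis fits — with
#' log-transformed hub distance. Hub pentads themselves are excluded
#' from the output (they would have zero hub distance and, in a real
#' atlas, pathological effort).
#'
#' @param landscape a [generate_landscape()] result.
#' @param coeffs an [effort_coefficients()] vector.
#' @param seed integer RNG seed.
#' @return data.frame `pentad`, `visits`, plus the linear predictor
#'   `eta` used (for diagnostics); attribute `coeffs` records truth.
#' @export
generate_effort <- function(landscape, coeffs = effort_coefficients(),
                            seed = 1L) {
  stopifnot(inherits(landscape, "landscape"),
            inherits(coeffs, "effort_coefficients"))
  cov <- landscape$covariates
  keep <- !(cov$pentad %in% landscape$hubs)
  cov <- cov[keep, , drop = FALSE]
  if (any(cov$dist_hub_km <= 0)) {
    stop("included pentad has zero hub distance; hub pentads must be excluded",
         call. = FALSE)
  }
  z <- function(x) as.numeric(scale(x))
  eta <- coeffs["b0"] +
    coeffs["b_loghub"] * log(cov$dist_hub_km) +
    coeffs["b_road"] * cov$dist_road_km +
    coeffs["b_prot"] * cov$protected +
    coeffs["b_urban"] * cov$urban +
    coeffs["b_cult"] * cov$cultivated +
    coeffs["b_precip"] * z(cov$precip) +
    coeffs["b_tsummer"] * z(cov$t_summer) +
    coeffs["b_twinter"] * z(cov$t_winter)
  visits <- .with_seed(seed, stats::rpois(nrow(cov), exp(eta)))
  out <- data.frame(pentad = cov$pentad, visits = visits, eta = as.numeric(eta),
                    stringsAsFactors = FALSE)
  attr(out, "coeffs") <- coeffs
  out
}

#' Generate a zone-structured species community
#'
#' Each environmental zone receives a species pool whose size is the
#' zone's true richness; a configurable fraction of widespread species
#' is shared across all pools. Every pool species occupies each pentad
#' of its zone(s) independently with the stated occupancy probability.
#'
#' @param landscape a [generate_landscape()] result.
#' @param zones named character/factor vector: pentad -> zone id (every
#'   landscape pentad must be present).
#' @param richness_model list with `base` (median zone richness),
#'   `spread` (lognormal sd of zone richness multipliers), `occupancy`
#'   (per-pentad occupancy probability) and `shared_fraction` (fraction
#'   of the smallest pool that is widespread); or a `richness` named
#'   integer vector giving R_z per zone directly.
#' @param seed integer RNG seed.
#' @return list with logical `occupancy` matrix (pentads x species),
#'   `richness` (true R_z per zone), `zone_of_species` and the model
#'   settings.
#' @export
generate_community <- function(landscape, zones,
                               richness_model = list(base = 90, spread = 0.25,
                                                     occupancy = 0.35,
                                                     shared_fraction = 0.2),
                               seed = 1L) {
  stopifnot(inherits(landscape, "landscape"))
  pent <- landscape$grid$pentad
  zones <- zones[pent]
  if (any(is.na(zones))) {
    stop("every landscape pentad must be assigned a zone", call. = FALSE)
  }
  .with_seed(seed, {
    zl <- sort(unique(as.character(zones)))
    occ_p <- richness_model$occupancy %||% 0.35
    shared_f <- richness_model$shared_fraction %||% 0.2
    if (!is.null(richness_model$richness)) {
      R <- richness_model$richness[zl]
    } else {
      R <- stats::setNames(
        pmax(1L, as.integer(round((richness_model$base %||% 90) *
               exp(stats::rnorm(length(zl), 0, richness_model$spread %||% 0.25))))),
        zl)
    }
    if (any(R < 1)) stop("zone richness must be >= 1", call. = FALSE)
    W <- as.integer(round(shared_f * min(R)))
    n_specific <- R - W
    shared_ids <- if (W > 0) sprintf("wide%04d", seq_len(W)) else character(0)
    spec_ids <- unlist(lapply(zl, function(z) {
      k <- n_specific[[z]]
      if (k > 0) sprintf("%s.sp%04d", z, seq_len(k)) else character(0)
    }))
    species <- c(shared_ids, spec_ids)
    zone_of_species <- c(rep(NA_character_, W),
                         rep(zl, times = n_specific[zl]))
    names(zone_of_species) <- species
    occ <- matrix(FALSE, length(pent), length(species),
                  dimnames = list(pent, species))
    for (j in seq_along(species)) {
      zj <- zone_of_species[j]
      rows <- if (is.na(zj)) seq_along(pent) else which(as.character(zones) == zj)
      occ[rows, j] <- stats::runif(length(rows)) < occ_p
    }
    list(occupancy = occ, richness = R, zone_of_species = zone_of_species,
         occupancy_prob = occ_p, shared_fraction = shared_f, seed = seed)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate checklists from effort, occupancy and detectability
#'
#' Each visit to a pentad detects each occupying species independently
#' with probability `p_det`; there are no false positives (real atlas
#' records pass a vetting step that removes them, so the observation
#' model is false-negative only). Visits that detect nothing are dropped
#' from the output — a real submitted list always has at least one
#' species — but counted in the truth record.
#'
#' @param visit_counts data.frame `pentad`, `visits` from
#'   [generate_effort()].
#' @param occupancy logical pentads x species matrix from
#'   [generate_community()].
#' @param p_det per-visit detection probability in (0, 1]; optionally a
#'   named per-species vector.
#' @param seed integer RNG seed.
#' @return list `checklists` (a `checklist_table`) and `truth` (a
#'   `synthetic_truth` list: coefficients if attached to
#'   `visit_counts`, detection probability, dropped-empty-list count,
#'   seeds).
#' @export
generate_checklists <- function(visit_counts, occupancy, p_det = 0.6,
                                seed = 1L) {
  species <- colnames(occupancy)
  if (length(p_det) == 1L) {
    p_vec <- rep(p_det, length(species))
  } else {
    p_vec <- p_det[species]
  }
  if (any(!is.finite(p_vec)) || any(p_vec <= 0) || any(p_vec > 1)) {
    stop("p_det must lie in (0, 1]", call. = FALSE)
  }
  .with_seed(seed, {
    rows_p <- character(0); rows_v <- character(0); rows_s <- list()
    n_empty <- 0L
    active <- visit_counts[visit_counts$visits > 0, , drop = FALSE]
    for (i in seq_len(nrow(active))) {
      pent <- active$pentad[i]
      present <- which(occupancy[pent, ])
      for (k in seq_len(active$visits[i])) {
        det <- present[stats::runif(length(present)) < p_vec[present]]
        if (length(det) == 0L) { n_empty <- n_empty + 1L; next }
        rows_p <- c(rows_p, pent)
        rows_v <- c(rows_v, sprintf("%s_v%03d", pent, k))
        rows_s <- c(rows_s, list(species[det]))
      }
    }
    checklists <- if (length(rows_p)) {
      as_checklist_table(rows_p, rows_v, rows_s)
    } else {
      structure(data.frame(pentad = character(0), visit_id = character(0)),
                class = c("checklist_table", "data.frame"))
    }
    truth <- structure(list(
      coeffs = attr(visit_counts, "coeffs"),
      p_det = p_det,
      n_empty_dropped = n_empty,
      visit_counts = visit_counts,
      seed = seed
    ), class = "synthetic_truth")
    list(checklists = checklists, truth = truth)
  })
}

#' Simulate a complete synthetic atlas
#'
#' Orchestrates landscape generation, environmental zonation, community
#' assembly and checklist generation under one master seed, returning
#' both the observable data (checklists, covariates, landmarks) and the
#' hidden truth (effort coefficients, per-zone richness, occupancy,
#' detectability) used to generate them.
#'
#' @param config a [landscape_config()].
#' @param coeffs an [effort_coefficients()] vector.
#' @param richness_model see [generate_community()].
#' @param p_det per-visit detection probability.
#' @param n_classes number of climate classes for zonation.
#' @param min_expected pooling threshold for [build_zones()].
#' @param seed master seed; stage seeds are derived from it.
#' @return a `synthetic_atlas` list: `landscape`, `zones`
#'   (`zone_partition`), `community`, `effort`, `checklists`, `truth`.
#' @export
simulate_atlas <- function(config = landscape_config(),
                           coeffs = effort_coefficients(),
                           richness_model = list(base = 90, spread = 0.25,
                                                 occupancy = 0.35,
                                                 shared_fraction = 0.2),
                           p_det = 0.6, n_classes = 10L, min_expected = 5,
                           seed = 1L) {
  seeds <- seed + c(land = 0L, effort = 1L, comm = 2L, lists = 3L)
  land <- generate_landscape(config, seed = seeds[["land"]])
  effort <- generate_effort(land, coeffs, seed = seeds[["effort"]])
  zones <- zonate_landscape(land, effort, n_classes = n_classes,
                            min_expected = min_expected)
  comm <- generate_community(land, zone_of(zones),
                             richness_model, seed = seeds[["comm"]])
  gc_out <- generate_checklists(effort, comm$occupancy, p_det,
                                seed = seeds[["lists"]])
  truth <- gc_out$truth
  truth$richness <- comm$richness
  truth$occupancy <- comm$occupancy
  truth$seeds <- seeds
  structure(list(landscape = land, zones = zones, community = comm,
                 effort = effort, checklists = gc_out$checklists,
                 truth = truth, seed = seed),
            class = "synthetic_atlas")
}

#' @export
print.synthetic_atlas <- function(x, ...) {
  cat(sprintf(
    "<synthetic_atlas> %d x %d pentads, %d zones, %d checklists, %d species\n",
    x$landscape$config$nrow, x$landscape$config$ncol,
    length(unique(zone_of(x$zones))), nrow(x$checklists),
    ncol(x$community$occupancy)))
  invisible(x)
}
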