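#' Read a checklist table
#'
#' The checklist CSV is the atlas's raw observational unit: one row per
#' visit, with header `pentad,visit_id,species` and the species column a
#' `;`-joined list of species identifiers. Rows with an empty species
#' field, duplicated visit ids or malformed pentad codes are rejected
#' (with the offending row number) rather than coerced.
#'
#' @param path path to a CSV file.
#' @return A data.frame of class `checklist_table` with character columns
#'   `pentad`, `visit_id` and a list-column `species` of character vectors.
#' @export
read_checklists <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("pentad", "visit_id", "species")
  if (!identical(names(raw)[seq_along(need)], need)) {
    stop("checklist file must have header 'pentad,visit_id,species'",
         call. = FALSE)
  }
  as_checklist_table(raw$pentad, raw$visit_id,
                     strsplit(raw$species, ";", fixed = TRUE))
}

#' Construct and validate a checklist table
#'
#' @param pentad character vector of pentad codes, one per visit.
#' @param visit_id character vector of unique visit identifiers.
#' @param species list of character vectors, the species recorded on each
#'   visit (non-empty).
#' @return a `checklist_table` data.frame.
#' @export
as_checklist_table <- function(pentad, visit_id, species) {
  pentad <- as.character(pentad)
  visit_id <- as.character(visit_id)
  species <- lapply(species, function(s) unique(as.character(s)))
  n <- length(pentad)
  stopifnot(length(visit_id) == n, length(species) == n)
  empty <- vapply(species, function(s) length(s) == 0L || all(!nzchar(s)),
                  logical(1))
  if (any(empty)) {
    stop(sprintf("empty species list at row %d: a checklist must contain at least one species",
                 which(empty)[1L]), call. = FALSE)
  }
  dup <- duplicated(visit_id)
  if (any(dup)) {
    stop(sprintf("duplicate visit_id '%s' at row %d", visit_id[dup][1L],
                 which(dup)[1L]), call. = FALSE)
  }
  bad <- !grepl("^[0-9]{4}_[0-9]{4,5}$", pentad)
  if (any(bad)) {
    stop(sprintf("unrecognised pentad code '%s' at row %d", pentad[bad][1L],
                 which(bad)[1L]), call. = FALSE)
  }
  out <- data.frame(pentad = pentad, visit_id = visit_id,
                    stringsAsFactors = FALSE)
  out$species <- species
  class(out) <- c("checklist_table", "data.frame")
  out
}

#' @export
print.checklist_table <- function(x, ...) {
  cat(sprintf("<checklist_table> %d visit(s), %d pentad(s), %d species\n",
              nrow(x), length(unique(x$pentad)),
              length(unique(unlist(x$species)))))
  invisible(x)
}

#' Write a checklist table
#'
#' Writes the CSV dialect read by [read_checklists()], with deterministic
#' row order (pentad, then visit_id) so that repeated runs are
#' byte-identical.
#'
#' @param table a `checklist_table`.
#' @param path output path.
#' @export
write_checklists <- function(table, path) {
  stopifnot(inherits(table, "checklist_table"))
  ord <- order(table$pentad, table$visit_id)
  out <- data.frame(
    pentad = table$pentad[ord],
    visit_id = table$visit_id[ord],
    species = vapply(table$species[ord], function(s) paste(sort(s), collapse = ";"),
                     character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.cover_cols <- c("protected", "urban", "cultivated")
.climate_cols <- c("precip", "t_summer", "t_winter")

#' Read a per-pentad covariate table
#'
#' One row per pentad with climate means (`precip` mm/yr, `t_summer` and
#' `t_winter` deg C), fractional covers (`protected`, `urban`,
#' `cultivated`, each in \[0, 1\]), per-biome cover fractions in columns
#' named `biome_<label>`, and optionally precomputed `dist_hub_km` /
#' `dist_road_km`. Missing distance columns are flagged for derivation
#' from landmark sets (attribute `needs_distances`).
#'
#' @param path path to a CSV file.
#' @return a validated `pentad_covariates` data.frame.
#' @export
read_covariates <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  as_pentad_covariates(raw)
}

#' Validate a per-pentad covariate table
#'
#' @param df data.frame with one row per pentad (see [read_covariates()]
#'   for the column contract).
#' @return a `pentad_covariates` data.frame; attribute `needs_distances`
#'   is TRUE when `dist_hub_km`/`dist_road_km` are absent.
#' @export
as_pentad_covariates <- function(df) {
  need <- c("pentad", .climate_cols, .cover_cols)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("covariate table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(df$pentad)
  if (any(dup)) {
    stop(sprintf("duplicated pentad '%s' in covariate table", df$pentad[dup][1L]),
         call. = FALSE)
  }
  frac_cols <- c(.cover_cols, grep("^biome_", names(df), value = TRUE))
  for (cl in frac_cols) {
    v <- df[[cl]]
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
      stop(sprintf("column '%s' must be a fraction in [0, 1]", cl),
           call. = FALSE)
    }
  }
  bf <- df[, grep("^biome_", names(df), value = TRUE), drop = FALSE]
  if (ncol(bf) && any(rowSums(bf) > 1 + 1e-6)) {
    stop("biome fractions must sum to at most 1 per pentad", call. = FALSE)
  }
  for (cl in intersect(c("dist_hub_km", "dist_road_km"), names(df))) {
    if (any(df[[cl]] < 0, na.rm = TRUE)) {
      stop(sprintf("column '%s' must be non-negative", cl), call. = FALSE)
    }
  }
  attr(df, "needs_distances") <-
    !all(c("dist_hub_km", "dist_road_km") %in% names(df))
  class(df) <- c("pentad_covariates", "data.frame")
  df
}

#' Export pentad polygons as GeoJSON
#'
#' Writes an RFC 7946 FeatureCollection (lon-lat coordinate order) with
#' one square polygon per pentad and any extra per-pentad columns of
#' `properties` attached as feature properties. Useful for inspecting
#' zone assignments or effort surfaces in any GIS viewer.
#'
#' @param pentads character vector of pentad codes.
#' @param properties optional data.frame (same length) of feature
#'   properties.
#' @param path output path.
#' @export
write_pentads_geojson <- function(pentads, properties = NULL, path) {
  dec <- decode_pentad(pentads)
  step <- 5 / 60
  features <- lapply(seq_len(nrow(dec)), function(i) {
    lat0 <- dec$lat_min[i]; lon0 <- dec$lon_min[i]
    ring <- list(
      c(lon0, lat0), c(lon0 + step, lat0),
      c(lon0 + step, lat0 - step), c(lon0, lat0 - step), c(lon0, lat0)
    )
    props <- list(pentad = dec$code[i])
    if (!is.null(properties)) {
      props <- c(props, as.list(properties[i, , drop = FALSE]))
    }
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = props)
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
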