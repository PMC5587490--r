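# Environmental zonation: climate PCA -> histogram classes -> dominant
# biome (with small-biome reassignment) -> biome x class zones pooled
# until every zone's expected frequency is large enough for a G-test.

#' Principal components of the pentad climate
#'
#' PCA of the correlation matrix (variables standardized) of mean annual
#' precipitation, mean summer temperature and mean winter temperature.
#' Standardization is forced because the variables mix mm/yr and deg C;
#' correlation-matrix PCA also makes the result invariant to units.
#' Sign convention: each component is flipped, if necessary, so that its
#' loading on precipitation is non-negative — PC1 then runs from hot and
#' dry (low scores) to moist and mild (high scores).
#'
#' @param covariates a `pentad_covariates` table (or any data.frame with
#'   `precip`, `t_summer`, `t_winter`).
#' @return a `climate_pca` list: `loadings` (3 x 3, variables x
#'   components), `scores` (pentads x 3; rownames = pentad codes when
#'   available), `variance_explained` (length 3, sums to 1).
#' @export
climate_pca <- function(covariates) {
  x <- as.matrix(covariates[, .climate_cols])
  if (nrow(x) < 3L) stop("need at least 3 pentads for a climate PCA", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("climate variable '%s' is constant; PCA is degenerate",
                 .climate_cols[sds == 0][1L]), call. = FALSE)
  }
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  flip <- ifelse(p$rotation["precip", ] < 0, -1, 1)
  loadings <- sweep(p$rotation, 2, flip, "*")
  scores <- sweep(p$x, 2, flip, "*")
  if ("pentad" %in% names(covariates)) rownames(scores) <- covariates$pentad
  structure(list(loadings = loadings,
                 scores = scores,
                 variance_explained = p$sdev^2 / sum(p$sdev^2)),
            class = "climate_pca")
}

#' @export
print.climate_pca <- function(x, ...) {
  cat("<climate_pca>\nloadings:\n")
  print(round(x$loadings, 3))
  cat("variance explained:", paste0(round(100 * x$variance_explained, 1), "%"),
      "\n")
  invisible(x)
}

#' Bin first-component climate scores into classes
#'
#' Equal-width bins spanning the observed score range, the histogram
#' analogue of climate classes: class 1 holds the lowest scores (hot and
#' dry, under the [climate_pca()] sign convention) and class
#' `n_classes` the highest (moist and mild). The top edge is closed so
#' the maximum score lands in the last class.
#'
#' @param scores numeric PC1 scores (finite), named by pentad when
#'   available.
#' @param n_classes number of classes (>= 2), default 10.
#' @return integer vector of classes in `1..n_classes`, names kept.
#' @export
assign_climate_classes <- function(scores, n_classes = 10L) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("n_classes must be at least 2", call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  rng <- range(scores)
  if (rng[1] == rng[2]) {
    stop("all scores are equal; climate classes are degenerate", call. = FALSE)
  }
  cls <- 1L + as.integer(floor((scores - rng[1]) / diff(rng) * n_classes))
  cls[cls > n_classes] <- n_classes  # right-closed top bin
  stats::setNames(cls, names(scores))
}

# row/col indices of pentads on the 5' grid (for queen adjacency)
.grid_index <- function(pentads) {
  dec <- decode_pentad(pentads)
  data.frame(pentad = pentads,
             row = as.integer(round(-dec$lat_min * 12)),
             col = as.integer(round(dec$lon_min * 12)),
             stringsAsFactors = FALSE)
}

#' Assign each pentad its dominant biome
#'
#' A pentad takes the biome covering the largest fraction of its area;
#' exact ties go to the lexicographically smallest label (with a
#' warning). Biomes listed in `reassign` — typically ones represented by
#' only a handful of pentads — are dissolved into their neighbours: each
#' affected pentad takes the modal biome among its queen-neighbourhood
#' (8-cell) non-reassigned pentads, iterated to a fixed point; isolated
#' islands fall back to the nearest non-reassigned pentad by distance,
#' with a warning.
#'
#' @param biome_fractions data.frame or matrix of per-biome cover
#'   fractions; columns may be bare labels or `biome_<label>`. A
#'   `pentad` column (or rownames) identifies the cells.
#' @param reassign character vector of biome labels to dissolve.
#' @return named character vector: pentad -> biome.
#' @export
assign_biome <- function(biome_fractions, reassign = character(0)) {
  bf <- as.data.frame(biome_fractions)
  if ("pentad" %in% names(bf)) {
    pentads <- as.character(bf$pentad)
    bf <- bf[, setdiff(names(bf), "pentad"), drop = FALSE]
  } else {
    pentads <- rownames(bf)
  }
  keep <- if (any(grepl("^biome_", names(bf)))) grep("^biome_", names(bf)) else seq_along(bf)
  bf <- bf[, keep, drop = FALSE]
  labs <- sub("^biome_", "", names(bf))
  m <- as.matrix(bf)
  if (any(rowSums(m) == 0)) {
    stop("pentad with all-zero biome fractions", call. = FALSE)
  }
  # argmax with lexicographic tie-break (labels scanned in sorted order)
  ord <- order(labs)
  m <- m[, ord, drop = FALSE]
  labs <- labs[ord]
  win <- max.col(m, ties.method = "first")
  tie <- apply(m, 1L, function(r) sum(r == max(r)) > 1L)
  if (any(tie)) {
    warning(sprintf("%d pentad(s) with tied biome fractions; lexicographically smallest label used",
                    sum(tie)), call. = FALSE)
  }
  biome <- stats::setNames(labs[win], pentads)
  if (length(reassign) == 0L || !any(biome %in% reassign)) return(biome)

  gi <- .grid_index(pentads)
  todo <- which(biome %in% reassign)
  fixed <- setdiff(seq_along(biome), todo)
  if (length(fixed) == 0L) {
    stop("all pentads belong to reassigned biomes; nothing to reassign to",
         call. = FALSE)
  }
  repeat {
    progressed <- FALSE
    for (i in todo) {
      if (!(biome[i] %in% reassign)) next
      nb <- which(abs(gi$row - gi$row[i]) <= 1L & abs(gi$col - gi$col[i]) <= 1L)
      nb <- setdiff(nb, i)
      nb <- nb[!(biome[nb] %in% reassign)]
      if (length(nb)) {
        tab <- sort(table(biome[nb]), decreasing = TRUE)
        biome[i] <- names(tab)[1L]
        progressed <- TRUE
      }
    }
    if (!any(biome %in% reassign)) break
    if (!progressed) {
      # isolated island: nearest non-reassigned pentad wins
      warning("isolated pentad(s) in reassigned biome; using nearest non-reassigned pentad",
              call. = FALSE)
      left <- which(biome %in% reassign)
      keep_idx <- which(!(biome %in% reassign))
      for (i in left) {
        d2 <- (gi$row[keep_idx] - gi$row[i])^2 + (gi$col[keep_idx] - gi$col[i])^2
        biome[i] <- biome[keep_idx[which.min(d2)]]
      }
      break
    }
  }
  biome
}

#' Pool biome-by-climate zones until expected frequencies allow a G-test
#'
#' Initial zones are every occupied biome x climate-class combination.
#' Zones too small for a goodness-of-fit G-test are pooled: while any
#' zone's expected frequency at the stricter sampling threshold falls
#' below `min_expected` (Cochran's rule, expected count >= 5), the zone
#' with the smallest expected frequency is merged with the zone of the
#' nearest climate class within the same biome (ties broken toward the
#' lower class). Pooled zone ids record the merged class range, e.g.
#' `"Fynbos:7+8"`.
#'
#' @param biomes named character vector: pentad -> biome.
#' @param classes named integer vector: pentad -> climate class.
#' @param list_counts named integer vector: pentad -> number of lists
#'   (pentads absent from the vector count as unsampled).
#' @param thresholds sampling-intensity thresholds (lists per pentad);
#'   the largest is the stricter one that drives pooling.
#' @param min_expected minimum expected count per zone, default 5.
#' @return a `zone_partition` data.frame (`pentad`, `biome`,
#'   `climate_class`, `zone_id`) with a `zones` attribute summarising
#'   each pooled zone (`zone_id`, `biome`, `classes`, `n_pentads`).
#' @export
build_zones <- function(biomes, classes, list_counts = integer(0),
                        thresholds = c(1L, 10L), min_expected = 5) {
  pentads <- names(biomes)
  stopifnot(!is.null(pentads), identical(sort(pentads), sort(names(classes))))
  classes <- classes[pentads]
  counts <- stats::setNames(rep(0L, length(pentads)), pentads)
  counts[names(list_counts)[names(list_counts) %in% pentads]] <-
    list_counts[names(list_counts) %in% pentads]
  strict <- max(thresholds)
  sampled_strict <- sum(counts >= strict)
  total <- length(pentads)

  # zone bookkeeping: a zone is (biome, set of classes)
  key <- paste(biomes, classes, sep = ":")
  zones <- lapply(split(seq_along(pentads), key), function(idx) {
    list(biome = biomes[idx[1]], classes = classes[idx[1]], idx = idx)
  })
  expected_of <- function(z) length(z$idx) / total * sampled_strict

  if (sampled_strict > 0) {
    repeat {
      ev <- vapply(zones, expected_of, numeric(1))
      if (all(ev >= min_expected) || length(zones) == 1L) break
      worst <- which.min(ev)
      zb <- zones[[worst]]$biome
      sib <- which(vapply(zones, function(z) z$biome == zb, logical(1)))
      sib <- setdiff(sib, worst)
      if (length(sib) == 0L) {
        stop(sprintf(
          "biome '%s' has total expected frequency %.2f < %g and no zone to merge with; use coarser climate classes",
          zb, ev[worst], min_expected), call. = FALSE)
      }
      gaps <- vapply(zones[sib], function(z) {
        min(abs(outer(z$classes, zones[[worst]]$classes, "-")))
      }, numeric(1))
      lo <- vapply(zones[sib], function(z) min(z$classes), numeric(1))
      target <- sib[order(gaps, lo)][1L]
      zones[[target]]$classes <- sort(unique(c(zones[[target]]$classes,
                                               zones[[worst]]$classes)))
      zones[[target]]$idx <- c(zones[[target]]$idx, zones[[worst]]$idx)
      zones[[worst]] <- NULL
    }
    ev <- vapply(zones, expected_of, numeric(1))
    if (any(ev < min_expected)) {
      stop(sprintf(
        "biome '%s' has total expected frequency %.2f < %g even after full pooling; use coarser climate classes",
        zones[[which.min(ev)]]$biome, min(ev), min_expected), call. = FALSE)
    }
  }

  zid <- vapply(zones, function(z) {
    paste0(z$biome, ":", paste(z$classes, collapse = "+"))
  }, character(1))
  zone_id <- character(total)
  for (k in seq_along(zones)) zone_id[zones[[k]]$idx] <- zid[k]
  out <- data.frame(pentad = pentads, biome = unname(biomes),
                    climate_class = unname(classes), zone_id = zone_id,
                    stringsAsFactors = FALSE)
  attr(out, "zones") <- data.frame(
    zone_id = zid,
    biome = vapply(zones, function(z) unname(z$biome), character(1)),
    classes = vapply(zones, function(z) paste(z$classes, collapse = "+"),
                     character(1)),
    n_pentads = vapply(zones, function(z) length(z$idx), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("zone_partition", "data.frame")
  out
}

#' Pentad-to-zone lookup
#'
#' @param partition a `zone_partition`.
#' @return named character vector: pentad -> zone_id.
#' @export
zone_of <- function(partition) {
  stopifnot(inherits(partition, "zone_partition"))
  stats::setNames(partition$zone_id, partition$pentad)
}

#' @export
print.zone_partition <- function(x, ...) {
  zs <- attr(x, "zones")
  cat(sprintf("<zone_partition> %d pentads, %d biome(s), %d zone(s)\n",
              nrow(x), length(unique(x$biome)), nrow(zs)))
  print(utils::head(zs[order(zs$zone_id), ], 12L), row.names = FALSE)
  if (nrow(zs) > 12L) cat(sprintf("... and %d more zones\n", nrow(zs) - 12L))
  invisible(x)
}

#' Zonate a landscape end to end
#'
#' Convenience wrapper: climate PCA, ten histogram classes on PC1,
#' dominant-biome assignment, then pooling driven by the observed
#' per-pentad list counts. Biomes whose total expected frequency at the
#' stricter threshold is below `min_expected` are dissolved into their
#' neighbours before zoning (the analogue of folding marginal biomes
#' represented by only a few cells into adjacent ones).
#'
#' @param landscape a [generate_landscape()] result, or a list with a
#'   `covariates` element.
#' @param effort data.frame `pentad`, `visits` (or `n_lists`).
#' @param n_classes,min_expected,thresholds see [build_zones()] /
#'   [assign_climate_classes()].
#' @return a `zone_partition`.
#' @export
zonate_landscape <- function(landscape, effort, n_classes = 10L,
                             min_expected = 5, thresholds = c(1L, 10L)) {
  cov <- landscape$covariates
  pca <- climate_pca(cov)
  cls <- assign_climate_classes(stats::setNames(pca$scores[, 1], cov$pentad),
                                n_classes = n_classes)
  bf <- cov[, c("pentad", grep("^biome_", names(cov), value = TRUE))]
  biome <- assign_biome(bf)
  cnt_col <- intersect(c("visits", "n_lists"), names(effort))[1]
  counts <- stats::setNames(as.integer(effort[[cnt_col]]), effort$pentad)
  strict <- max(thresholds)
  s_strict <- sum(counts >= strict)
  if (s_strict > 0) {
    btab <- table(biome)
    exp_biome <- as.numeric(btab) / length(biome) * s_strict
    small <- names(btab)[exp_biome < min_expected]
    if (length(small) && length(small) < length(btab)) {
      biome <- assign_biome(bf, reassign = small)
    }
  }
  part <- build_zones(biome, cls, counts, thresholds = thresholds,
                      min_expected = min_expected)
  attr(part, "pca") <- pca
  part
}
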