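# Representativeness of sampling across environmental zones: per-zone
# sampled-pentad counts at both intensity thresholds, size-proportional
# expected frequencies, goodness-of-fit G-tests, and the
# observed-minus-expected ranking of zones.

#' Per-zone sampled-pentad counts at each threshold
#'
#' Counts, for every zone, the pentads holding at least `t` lists for
#' each threshold `t` (default 1 and 10 — total coverage versus the
#' repeat sampling needed to pin down detectability), together with the
#' size-proportional expected frequencies and the observed-minus-
#' expected deficit.
#'
#' @param checklists a `checklist_table` (or a data.frame `pentad`,
#'   `n_lists` of precomputed list counts).
#' @param zones a `zone_partition`.
#' @param thresholds integer thresholds, default `c(1, 10)`.
#' @return a `zone_effort_table` data.frame: `zone_id`, `n_pentads`,
#'   then `n_sampled_<t>`, `expected_<t>`, `deficit_<t>` per threshold.
#' @export
zone_sampling_counts <- function(checklists, zones, thresholds = c(1L, 10L)) {
  stopifnot(inherits(zones, "zone_partition"))
  if (inherits(checklists, "checklist_table")) {
    lc <- table(checklists$pentad)
  } else {
    lc <- stats::setNames(checklists$n_lists, checklists$pentad)
  }
  missing <- setdiff(names(lc), zones$pentad)
  if (length(missing)) {
    stop("checklist pentad(s) absent from the zone partition: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  counts <- stats::setNames(rep(0L, nrow(zones)), zones$pentad)
  counts[names(lc)] <- as.integer(lc)
  zs <- attr(zones, "zones")
  out <- data.frame(zone_id = zs$zone_id, n_pentads = zs$n_pentads,
                    stringsAsFactors = FALSE)
  total <- sum(zs$n_pentads)
  for (t in thresholds) {
    sampled <- counts >= t
    n_s <- vapply(zs$zone_id, function(z) {
      sum(sampled[zones$zone_id == z])
    }, integer(1))
    ex <- expected_frequencies(zs$n_pentads, total, sum(n_s))
    out[[paste0("n_sampled_", t)]] <- unname(n_s)
    out[[paste0("expected_", t)]] <- ex
    out[[paste0("deficit_", t)]] <- unname(n_s) - ex
  }
  attr(out, "thresholds") <- as.integer(thresholds)
  class(out) <- c("zone_effort_table", "data.frame")
  out
}

#' Size-proportional expected sampling frequencies
#'
#' The expected number of sampled pentads per zone if sampling effort
#' were geographically homogeneous:
#' `(zone size / total pentads) * total sampled pentads`.
#' The expecteds sum exactly to the total sampled count.
#'
#' @param zone_sizes integer vector of pentads per zone.
#' @param total_pentads total pentads (must equal `sum(zone_sizes)`).
#' @param total_sampled total sampled pentads at the threshold.
#' @return numeric vector of expected frequencies.
#' @export
expected_frequencies <- function(zone_sizes, total_pentads, total_sampled) {
  if (total_pentads <= 0) stop("total_pentads must be positive", call. = FALSE)
  zone_sizes / total_pentads * total_sampled
}

#' Likelihood-ratio goodness-of-fit G-test
#'
#' `G = 2 * sum(O * ln(O / E))` with the convention `0 * ln 0 = 0`,
#' compared to a chi-square distribution on `k - 1` degrees of freedom.
#' No Williams correction is applied.
#'
#' @param observed,expected numeric vectors of equal length >= 2;
#'   expected must be strictly positive (pool zones first if not).
#' @return a `g_test` list: `G`, `df`, `p_value`, `observed`,
#'   `expected`.
#' @export
g_test <- function(observed, expected) {
  if (length(observed) != length(expected) || length(observed) < 2L) {
    stop("observed and expected must be equal-length vectors of length >= 2",
         call. = FALSE)
  }
  if (any(expected <= 0)) {
    stop("expected frequencies must be positive everywhere; pool small zones first",
         call. = FALSE)
  }
  terms <- ifelse(observed > 0, observed * log(observed / expected), 0)
  g <- 2 * sum(terms)
  df <- length(observed) - 1L
  structure(list(G = g, df = df,
                 p_value = stats::pchisq(g, df, lower.tail = FALSE),
                 observed = observed, expected = expected),
            class = "g_test")
}

#' @export
print.g_test <- function(x, ...) {
  cat(sprintf("<g_test> G = %.3f, df = %d, p = %.4g\n", x$G, x$df, x$p_value))
  invisible(x)
}

#' G-tests of zone representativeness
#'
#' Runs the overall goodness-of-fit G-test of sampled-pentad counts
#' against size-proportional expecteds at each threshold, plus one
#' per-biome test restricted to the biome's zones (expecteds recomputed
#' within the biome). Per-biome p-values are unadjusted by default; set
#' `holm = TRUE` for a Holm correction across biomes.
#'
#' @param effort_table a [zone_sampling_counts()] result.
#' @param zones the `zone_partition` the table was built from.
#' @param holm apply Holm correction to the per-biome p-values.
#' @return nested list: `overall[[threshold]]` and
#'   `per_biome[[threshold]][[biome]]`, each a `g_test` (per-biome
#'   entries gain `p_adjusted` when `holm`).
#' @export
representativeness_tests <- function(effort_table, zones, holm = FALSE) {
  thresholds <- attr(effort_table, "thresholds")
  zs <- attr(zones, "zones")
  biome_of_zone <- stats::setNames(zs$biome, zs$zone_id)
  out <- list(overall = list(), per_biome = list())
  for (t in thresholds) {
    key <- as.character(t)
    obs <- effort_table[[paste0("n_sampled_", t)]]
    ex <- effort_table[[paste0("expected_", t)]]
    out$overall[[key]] <- g_test(obs, ex)
    biomes <- unique(biome_of_zone[effort_table$zone_id])
    bt <- list()
    for (b in biomes) {
      idx <- biome_of_zone[effort_table$zone_id] == b
      if (sum(idx) < 2L) next
      sizes <- effort_table$n_pentads[idx]
      ex_b <- expected_frequencies(sizes, sum(sizes), sum(obs[idx]))
      if (any(ex_b <= 0)) next  # biome unsampled at this threshold
      bt[[b]] <- g_test(obs[idx], ex_b)
    }
    if (holm && length(bt)) {
      padj <- stats::p.adjust(vapply(bt, `[[`, numeric(1), "p_value"), "holm")
      for (b in names(bt)) bt[[b]]$p_adjusted <- padj[[b]]
    }
    out$per_biome[[key]] <- bt
  }
  out
}

#' Rank zones by observed-minus-expected sampling effort
#'
#' Orders zones by the deficit (observed minus expected sampled pentads)
#' at the chosen threshold, most oversampled first; ties break by
#' zone_id. Deficits sum to zero across zones by construction.
#'
#' @param table a `zone_effort_table`.
#' @param threshold one of the table's thresholds.
#' @return data.frame `zone_id`, `n_pentads`, `observed`, `expected`,
#'   `deficit`, `rank`.
#' @export
rank_by_effort <- function(table, threshold = 1L) {
  stopifnot(inherits(table, "zone_effort_table"))
  if (!(threshold %in% attr(table, "thresholds"))) {
    stop("threshold ", threshold, " not present in the effort table",
         call. = FALSE)
  }
  obs <- table[[paste0("n_sampled_", threshold)]]
  ex <- table[[paste0("expected_", threshold)]]
  d <- obs - ex
  ord <- order(-d, table$zone_id)
  out <- data.frame(zone_id = table$zone_id[ord],
                    n_pentads = table$n_pentads[ord],
                    observed = obs[ord], expected = ex[ord], deficit = d[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  out
}
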