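# End-to-end pipeline: (simulated or supplied) atlas -> zonation ->
# effort model -> representativeness -> completeness, with every
# interface table written to disk and a manifest sufficient to
# reproduce the run.

#' Pipeline configuration
#'
#' @param simulate logical; simulate a synthetic atlas (TRUE) or read
#'   `checklists_csv` / `covariates_csv` (FALSE).
#' @param checklists_csv,covariates_csv input paths when
#'   `simulate = FALSE`. The covariate table must carry `dist_hub_km`
#'   and `dist_road_km`; pentads with zero hub distance are treated as
#'   hubs and excluded from the effort model.
#' @param landscape a [landscape_config()] (simulation only).
#' @param coeffs an [effort_coefficients()] vector (simulation only).
#' @param richness_model,p_det community settings (simulation only),
#'   see [generate_community()] / [generate_checklists()].
#' @param thresholds strictly increasing positive integers, default
#'   `c(1, 10)`.
#' @param n_classes climate classes, default 10.
#' @param min_expected pooling threshold, default 5.
#' @param models richness models to fit, default all three.
#' @param seed master seed.
#' @param outdir output directory, or `NULL` to skip writing.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = TRUE, checklists_csv = NULL,
                            covariates_csv = NULL,
                            landscape = landscape_config(),
                            coeffs = effort_coefficients(),
                            richness_model = list(base = 90, spread = 0.25,
                                                  occupancy = 0.35,
                                                  shared_fraction = 0.2),
                            p_det = 0.6, thresholds = c(1L, 10L),
                            n_classes = 10L, min_expected = 5,
                            models = c("lomolino", "clench", "weibull"),
                            seed = 1L, outdir = NULL) {
  thresholds <- as.integer(thresholds)
  if (any(thresholds <= 0) || any(diff(thresholds) <= 0)) {
    stop("thresholds must be strictly increasing positive integers",
         call. = FALSE)
  }
  if (!simulate) {
    for (p in c(checklists_csv, covariates_csv)) {
      if (is.null(p) || !file.exists(p)) {
        stop("simulate = FALSE requires existing checklists_csv and covariates_csv",
             call. = FALSE)
      }
    }
  }
  structure(list(simulate = simulate, checklists_csv = checklists_csv,
                 covariates_csv = covariates_csv, landscape = landscape,
                 coeffs = coeffs, richness_model = richness_model,
                 p_det = p_det, thresholds = thresholds,
                 n_classes = n_classes, min_expected = min_expected,
                 models = models, seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of [pipeline_config()] can be given in a YAML file;
#' nested `landscape` and `coeffs` blocks are passed to
#' [landscape_config()] and [effort_coefficients()].
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$landscape)) args$landscape <- do.call(landscape_config, y$landscape)
  if (!is.null(y$coeffs)) args$coeffs <- do.call(effort_coefficients, y$coeffs)
  do.call(pipeline_config, args)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full sampling-bias pipeline
#'
#' Executes, in order: data acquisition (simulation or CSV input),
#' environmental zonation, the per-group quasi-Poisson effort model with
#' Moran's I residual diagnostic, zone representativeness (counts,
#' G-tests, effort ranking) and per-zone completeness at every
#' threshold. Deterministic for a fixed config and seed. When
#' `config$outdir` is set, every interface table is written there
#' (zones, effort table, rankings, curves, fits, G-tests, Table-1-style
#' t-value report, manifest); on failure partial outputs are removed.
#'
#' @param config a [pipeline_config()].
#' @return a `report_bundle` list: `zones`, `effort_table`, `g_tests`,
#'   `effort_fits`, `morans`, `curves`, `fits`, `rankings`,
#'   `completeness`, `checklists`, `covariates`, `truth` (simulation
#'   only), `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()

  acq <- .stage("acquire", {
    if (config$simulate) {
      atlas <- simulate_atlas(config$landscape, config$coeffs,
                              config$richness_model, config$p_det,
                              n_classes = config$n_classes,
                              min_expected = config$min_expected,
                              seed = config$seed)
      lc <- table(atlas$checklists$pentad)
      visits <- data.frame(pentad = atlas$landscape$covariates$pentad,
                           stringsAsFactors = FALSE)
      visits$n_lists <- as.integer(lc[visits$pentad])
      visits$n_lists[is.na(visits$n_lists)] <- 0L
      list(checklists = atlas$checklists,
           covariates = atlas$landscape$covariates,
           coords = atlas$landscape$grid,
           visits = atlas$effort,            # true visit counts (effort model)
           n_lists = visits,                 # observed list counts
           zones = atlas$zones, truth = atlas$truth, atlas = atlas)
    } else {
      checklists <- read_checklists(config$checklists_csv)
      covariates <- read_covariates(config$covariates_csv)
      if (attr(covariates, "needs_distances")) {
        stop("covariate table lacks dist_hub_km/dist_road_km", call. = FALSE)
      }
      lc <- table(checklists$pentad)
      n_lists <- data.frame(pentad = covariates$pentad, stringsAsFactors = FALSE)
      n_lists$n_lists <- as.integer(lc[n_lists$pentad])
      n_lists$n_lists[is.na(n_lists$n_lists)] <- 0L
      dec <- decode_pentad(covariates$pentad)
      coords <- data.frame(pentad = covariates$pentad,
                           midpoint_lat = dec$midpoint_lat,
                           midpoint_lon = dec$midpoint_lon)
      visits <- data.frame(pentad = n_lists$pentad, visits = n_lists$n_lists)
      visits <- visits[covariates$dist_hub_km[match(visits$pentad, covariates$pentad)] > 0, ]
      list(checklists = checklists, covariates = covariates, coords = coords,
           visits = visits, n_lists = n_lists, zones = NULL, truth = NULL)
    }
  })

  zones <- .stage("zonate", {
    if (!is.null(acq$zones)) acq$zones else {
      zonate_landscape(list(covariates = acq$covariates),
                       data.frame(pentad = acq$n_lists$pentad,
                                  visits = acq$n_lists$n_lists),
                       n_classes = config$n_classes,
                       min_expected = config$min_expected,
                       thresholds = config$thresholds)
    }
  })

  modelled <- .stage("effort-model", {
    des <- effort_design(acq$covariates, acq$visits, coords = acq$coords)
    fit <- fit_poisson_glm(des)
    mi <- morans_i(stats::residuals(fit$glm, type = "pearson"),
                   des[, c("midpoint_lat", "midpoint_lon")],
                   n_perm = 199L, seed = config$seed)
    fe <- fit_effort_models(des)
    list(design = des, fit = fit, morans = mi, table = fe$table)
  })

  repres <- .stage("representativeness", {
    et <- zone_sampling_counts(acq$checklists, zones,
                               thresholds = config$thresholds)
    gt <- representativeness_tests(et, zones)
    rk <- lapply(config$thresholds, function(t) rank_by_effort(et, t))
    names(rk) <- as.character(config$thresholds)
    list(table = et, g_tests = gt, rankings = rk)
  })

  compl <- .stage("completeness", {
    out <- lapply(config$thresholds, function(t) {
      zone_completeness(acq$checklists, zones, threshold = t,
                        models = config$models)
    })
    names(out) <- as.character(config$thresholds)
    out
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("atlaseffort")),
    r_version = R.version.string,
    seed = config$seed,
    thresholds = config$thresholds,
    n_classes = config$n_classes,
    min_expected = config$min_expected,
    models = config$models,
    simulate = config$simulate,
    config = utils::capture.output(utils::str(config, max.level = 2)),
    started = format(t0), finished = format(Sys.time())
  )

  bundle <- structure(list(
    zones = zones, effort_table = repres$table, g_tests = repres$g_tests,
    effort_fits = modelled, morans = modelled$morans,
    completeness = compl, rankings = repres$rankings,
    checklists = acq$checklists, covariates = acq$covariates,
    truth = acq$truth, manifest = manifest, config = config
  ), class = "report_bundle")

  if (!is.null(config$outdir)) .write_bundle(bundle, config$outdir)
  bundle
}

.write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  wr <- function(obj, name, json = FALSE) {
    p <- file.path(outdir, name)
    if (json) jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = 10,
                                   force = TRUE)
    else utils::write.csv(obj, p, row.names = FALSE)
    written <<- c(written, p)
  }
  tryCatch({
    zdf <- as.data.frame(bundle$zones)
    wr(zdf, "zone_assignment.csv")
    wr(attr(bundle$zones, "zones"), "zone_summary.csv")
    wr(as.data.frame(bundle$effort_table), "zone_effort.csv")
    wr(bundle$effort_fits$table, "effort_tvalues.csv")
    for (t in names(bundle$rankings)) {
      wr(bundle$rankings[[t]], sprintf("effort_ranking_t%s.csv", t))
    }
    gt <- lapply(bundle$g_tests$overall, function(g) {
      list(G = g$G, df = g$df, p_value = g$p_value)
    })
    wr(gt, "g_tests.json", json = TRUE)
    for (t in names(bundle$completeness)) {
      cz <- bundle$completeness[[t]]
      if (!is.null(cz$ranking)) {
        wr(cz$ranking, sprintf("completeness_t%s.csv", t))
      }
      curves <- do.call(rbind, lapply(names(cz$curves), function(z) {
        data.frame(zone_id = z, threshold = t, n = cz$curves[[z]]$n,
                   S_mao = cz$curves[[z]]$S)
      }))
      if (!is.null(curves)) wr(curves, sprintf("curves_t%s.csv", t))
    }
    wr(bundle$manifest, "manifest.json", json = TRUE)
  }, error = function(e) {
    unlink(written)
    stop("failed writing outputs: ", conditionMessage(e), call. = FALSE)
  })
  invisible(outdir)
}

#' Human-readable summary of a pipeline run
#'
#' Prints the share of pentads sampled at each threshold, the overall
#' G-test at each threshold, the five most over- and under-sampled
#' zones, and the five least complete zones.
#'
#' @param bundle a [run_pipeline()] result.
#' @return the summary lines, invisibly.
#' @export
summarize_report <- function(bundle) {
  stopifnot(inherits(bundle, "report_bundle"))
  et <- bundle$effort_table
  total <- sum(et$n_pentads)
  lines <- character(0)
  say <- function(...) lines <<- c(lines, sprintf(...))
  for (t in attr(et, "thresholds")) {
    s <- sum(et[[paste0("n_sampled_", t)]])
    say("%.1f%% of pentads sampled at threshold >=%d lists (%d of %d)",
        100 * s / total, t, s, total)
    g <- bundle$g_tests$overall[[as.character(t)]]
    say("  evenness G-test: G = %.3f, df = %d, p = %.4g", g$G, g$df, g$p_value)
    rk <- bundle$rankings[[as.character(t)]]
    say("  most oversampled: %s",
        paste(sprintf("%s (%+.1f)", utils::head(rk$zone_id, 5),
                      utils::head(rk$deficit, 5)), collapse = ", "))
    say("  most undersampled: %s",
        paste(sprintf("%s (%+.1f)", utils::tail(rk$zone_id, 5),
                      utils::tail(rk$deficit, 5)), collapse = ", "))
    cz <- bundle$completeness[[as.character(t)]]
    if (!is.null(cz$ranking)) {
      rk5 <- utils::head(cz$ranking, 5)
      say("  least complete inventories: %s",
          paste(sprintf("%s (%.1f%%)", rk5$zone_id, rk5$completeness),
                collapse = ", "))
    }
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  summarize_report(x)
  invisible(x)
}
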