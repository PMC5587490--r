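cfg_small <- landscape_config(nrow = 12, ncol = 12)

test_that("landscape generation is fully deterministic under a fixed seed", {
  a <- generate_landscape(cfg_small, seed = 5)
  b <- generate_landscape(cfg_small, seed = 5)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$road_points, b$road_points)
  expect_identical(a$hubs, b$hubs)
  d <- generate_landscape(cfg_small, seed = 6)
  expect_false(identical(a$covariates$precip, d$covariates$precip))
})

test_that("zero noise amplitude makes climate exactly linear in grid coords", {
  land <- generate_landscape(landscape_config(nrow = 10, ncol = 10,
                                              noise_amp = 0), seed = 3)
  g <- land$grid
  for (v in c("precip", "t_summer", "t_winter")) {
    fit <- lm(land$covariates[[v]] ~ g$row + g$col)
    expect_lt(max(abs(residuals(fit))), 1e-8)
  }
})

test_that("hub distance is monotone along grid axes away from a single hub", {
  land <- generate_landscape(landscape_config(nrow = 15, ncol = 15,
                                              n_hubs = 1), seed = 9)
  g <- land$grid
  hub_rc <- g[g$pentad == land$hubs, c("row", "col")]
  d <- matrix(land$covariates$dist_hub_km[order(g$row, g$col)], 15, 15,
              byrow = TRUE)
  # along the hub's row, distance decreases toward the hub column then rises
  row_d <- d[hub_rc$row, ]
  expect_true(all(diff(row_d[seq_len(hub_rc$col)]) <= 1e-9))
  expect_true(all(diff(row_d[hub_rc$col:15]) >= -1e-9))
  col_d <- d[, hub_rc$col]
  expect_true(all(diff(col_d[seq_len(hub_rc$row)]) <= 1e-9))
  expect_true(all(diff(col_d[hub_rc$row:15]) >= -1e-9))
})

test_that("effort counts follow the intended Poisson log-linear model", {
  # intercept-only: sample mean converges to exp(b0) = 5
  land <- generate_landscape(landscape_config(nrow = 100, ncol = 100),
                             seed = 21)
  co0 <- effort_coefficients(b0 = log(5), b_loghub = 0, b_road = 0,
                             b_prot = 0, b_urban = 0, b_cult = 0,
                             b_precip = 0, b_tsummer = 0, b_twinter = 0)
  eff <- generate_effort(land, co0, seed = 22)
  n <- nrow(eff)
  expect_gt(n, 9000)
  expect_lt(abs(mean(eff$visits) - 5), 3 * sqrt(5 / n))

  # pure hub-distance decay: slope of log mean count on log distance is -1
  co1 <- effort_coefficients(b0 = 4, b_loghub = -1, b_road = 0, b_prot = 0,
                             b_urban = 0, b_cult = 0, b_precip = 0,
                             b_tsummer = 0, b_twinter = 0)
  eff1 <- generate_effort(land, co1, seed = 23)
  ld <- log(land$covariates$dist_hub_km[match(eff1$pentad,
                                              land$covariates$pentad)])
  bins <- cut(ld, breaks = quantile(ld, seq(0, 1, 0.1)), include.lowest = TRUE)
  mu <- tapply(eff1$visits, bins, mean)
  mid <- tapply(ld, bins, mean)
  slope <- coef(lm(log(mu) ~ mid))[2]
  expect_lt(abs(slope + 1), 0.1)

  # determinism
  expect_identical(generate_effort(land, co1, seed = 23)$visits, eff1$visits)
})

test_that("effort generation refuses pentads sitting on a hub", {
  land <- generate_landscape(cfg_small, seed = 2)
  land$covariates$dist_hub_km[5] <- 0
  land$hubs <- character(0) # pretend no pentad is excluded
  expect_error(generate_effort(land, seed = 1), "hub")
})

test_that("community generation honours pools, sharing and occupancy", {
  land <- generate_landscape(cfg_small, seed = 4)
  zones <- setNames(rep(c("z1", "z2"), length.out = nrow(land$grid)),
                    land$grid$pentad)

  # occupancy 1: every pool species occupies every zone pentad
  comm <- generate_community(land, zones,
                             list(richness = c(z1 = 30L, z2 = 30L),
                                  occupancy = 1, shared_fraction = 0),
                             seed = 8)
  for (z in c("z1", "z2")) {
    rows <- names(zones)[zones == z]
    own <- comm$zone_of_species == z
    expect_true(all(comm$occupancy[rows, own]))
    expect_false(any(comm$occupancy[rows, !own & !is.na(comm$zone_of_species)]))
  }

  # shared fraction 1 with equal richness: one common widespread pool
  comm2 <- generate_community(land, zones,
                              list(richness = c(z1 = 25L, z2 = 25L),
                                   occupancy = 0.5, shared_fraction = 1),
                              seed = 8)
  expect_equal(sum(is.na(comm2$zone_of_species)), 25)
  expect_equal(ncol(comm2$occupancy), 25)

  # occupancy 0.3 with richness 100: mean per-pentad richness near 30
  zones3 <- setNames(rep("z1", nrow(land$grid)), land$grid$pentad)
  comm3 <- generate_community(land, zones3,
                              list(richness = c(z1 = 100L), occupancy = 0.3,
                                   shared_fraction = 0),
                              seed = 9)
  mean_rich <- mean(rowSums(comm3$occupancy))
  n_cells <- nrow(comm3$occupancy) * 100
  se <- sqrt(0.3 * 0.7 / n_cells) * 100
  expect_lt(abs(mean_rich - 30), 3 * se)
})

test_that("checklists reflect detection: no false positives, known misses", {
  land <- generate_landscape(cfg_small, seed = 4)
  zones <- setNames(rep("z1", nrow(land$grid)), land$grid$pentad)
  comm <- generate_community(land, zones,
                             list(richness = c(z1 = 40L), occupancy = 0.5,
                                  shared_fraction = 0), seed = 1)
  eff <- data.frame(pentad = land$grid$pentad,
                    visits = rep(3L, nrow(land$grid)))

  # p_det = 1: every visit lists the full pentad occupancy
  out <- generate_checklists(eff, comm$occupancy, p_det = 1, seed = 2)
  cl <- out$checklists
  for (i in sample(nrow(cl), 20)) {
    expect_setequal(cl$species[[i]],
                    colnames(comm$occupancy)[comm$occupancy[cl$pentad[i], ]])
  }

  # detected species are always a subset of occupants (no false positives)
  out2 <- generate_checklists(eff, comm$occupancy, p_det = 0.4, seed = 3)
  ok <- vapply(seq_len(nrow(out2$checklists)), function(i) {
    all(comm$occupancy[out2$checklists$pentad[i],
                       out2$checklists$species[[i]]])
  }, logical(1))
  expect_true(all(ok))

  # zero visits everywhere: empty table
  out3 <- generate_checklists(transform(eff, visits = 0L), comm$occupancy,
                              p_det = 0.5, seed = 4)
  expect_equal(nrow(out3$checklists), 0)

  expect_error(generate_checklists(eff, comm$occupancy, p_det = 0), "p_det")
})

test_that("miss probability over repeated visits matches the closed form", {
  # occupancy forced to 1 so every species is present in every pentad;
  # with 10 visits at p_det = 0.5 a species is never seen w.p. 2^-10
  land <- generate_landscape(landscape_config(nrow = 25, ncol = 20), seed = 4)
  zones <- setNames(rep("z1", nrow(land$grid)), land$grid$pentad)
  comm <- generate_community(land, zones,
                             list(richness = c(z1 = 100L), occupancy = 1,
                                  shared_fraction = 0), seed = 1)
  eff <- data.frame(pentad = land$grid$pentad,
                    visits = rep(10L, nrow(land$grid)))
  out <- generate_checklists(eff, comm$occupancy, p_det = 0.5, seed = 6)
  seen <- matrix(FALSE, nrow(land$grid), 100,
                 dimnames = dimnames(comm$occupancy))
  for (i in seq_len(nrow(out$checklists))) {
    seen[out$checklists$pentad[i], out$checklists$species[[i]]] <- TRUE
  }
  p_hat <- mean(!seen)
  p_true <- 2^-10
  n <- length(seen)
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
})

test_that("the full simulated atlas is deterministic and self-consistent", {
  a1 <- simulate_atlas(landscape_config(nrow = 14, ncol = 14), seed = 31)
  a2 <- simulate_atlas(landscape_config(nrow = 14, ncol = 14), seed = 31)
  expect_identical(a1$checklists, a2$checklists)
  expect_identical(a1$truth$richness, a2$truth$richness)
  # every detection is of an occupying species
  ok <- vapply(seq_len(nrow(a1$checklists)), function(i) {
    all(a1$truth$occupancy[a1$checklists$pentad[i],
                           a1$checklists$species[[i]]])
  }, logical(1))
  expect_true(all(ok))
})
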