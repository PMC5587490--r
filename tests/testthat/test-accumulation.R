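test_that("incidence pools all of a pentad's lists at each threshold", {
  pent <- c("2600_2200", "2600_2205", "2600_2210")
  cl <- as_checklist_table(
    c("2600_2200", "2600_2200", "2600_2205"),
    c("v1", "v2", "v3"),
    list(c("a", "b"), c("b", "c"), c("a")))
  inc <- incidence_matrix(cl, threshold = 1)
  expect_equal(dim(inc), c(2, 3))
  expect_true(all(inc["2600_2200", c("a", "b", "c")]))
  expect_identical(unname(inc["2600_2205", ]), c(TRUE, FALSE, FALSE))
  # threshold 2 keeps only the twice-visited pentad
  inc2 <- incidence_matrix(cl, threshold = 2)
  expect_equal(rownames(inc2), "2600_2200")
})

test_that("Mao Tau matches its algebraic identities and brute force", {
  # N = 3 pentads, species with f = (2, 1)
  inc <- rbind(c(1, 1), c(1, 0), c(0, 0)) == 1
  cur <- mao_tau(inc)
  expect_equal(cur$S[2], 5 / 3, tolerance = 1e-12)
  expect_equal(cur$S[1], sum(colSums(inc)) / 3, tolerance = 1e-12)
  expect_equal(cur$S[3], attr(cur, "S_obs"))

  set.seed(53)
  for (r in 1:5) {
    m <- random_incidence(sample(5:9, 1), sample(5:30, 1))
    cur <- mao_tau(m)
    for (n in seq_len(nrow(m))) {
      expect_equal(cur$S[n], brute_force_accumulation(m, n),
                   tolerance = 1e-10)
    }
    # endpoint and monotone/concave shape
    expect_equal(cur$S[nrow(m)], sum(colSums(m) > 0))
    expect_true(all(diff(cur$S) >= -1e-12))
    if (nrow(m) > 2) expect_true(all(diff(diff(cur$S)) <= 1e-9))
  }
  expect_error(mao_tau(matrix(2, 2, 2)), "binary")
})

test_that("Mao Tau agrees with vegan's exact accumulation curve", {
  skip_if_not_installed("vegan")
  set.seed(59)
  m <- random_incidence(30, 80)
  cur <- mao_tau(m)
  ref <- vegan::specaccum(m * 1, method = "exact")
  expect_equal(cur$S, as.numeric(ref$richness), tolerance = 1e-8)
})

test_that("the permutation curve is seeded, flat for one pentad, near exact", {
  m1 <- matrix(c(TRUE, TRUE, FALSE), 1, 3)
  p1 <- permutation_accumulation(m1, n_runs = 10, seed = 1)
  expect_equal(p1$S, 2)

  set.seed(61)
  m <- random_incidence(15, 40)
  a <- permutation_accumulation(m, n_runs = 200, seed = 7)
  b <- permutation_accumulation(m, n_runs = 200, seed = 7)
  expect_identical(a$S, b$S)
  ex <- mao_tau(m)
  se <- a$S_sd / sqrt(200)
  live <- a$S_sd > 0
  expect_true(all(abs(a$S - ex$S)[live] <= 3 * se[live]))
  # where every run saturated, the exact curve is within rounding of S_obs
  expect_true(all(abs(a$S - ex$S)[!live] < 0.05))
  expect_error(permutation_accumulation(m, n_runs = 0), "n_runs")
})

test_that("model curves satisfy their defining identities", {
  # Clench half-saturation: S(B) = Asym / 2
  expect_equal(atlaseffort:::.model_fun$clench(10, c(Asym = 200, B = 10)), 100)
  # Lomolino midpoint: S(xmid) = Asym / 2 regardless of slope
  expect_equal(atlaseffort:::.model_fun$lomolino(20, c(Asym = 250, xmid = 20,
                                                       slope = 6)), 125)
  # Weibull scale point: S(scale) = Asym (1 - 1/e)
  expect_equal(atlaseffort:::.model_fun$weibull(30, c(Asym = 100, scale = 30,
                                                      shape = 2)),
               100 * (1 - exp(-1)))
})

test_that("noiseless Lomolino data are recovered near machine precision", {
  n <- 1:40
  s <- lomolino_curve(n, 250, 20, 6)
  cur <- structure(data.frame(n = n, S = s), method = "exact",
                   S_obs = floor(max(s)), N = 40,
                   class = c("accumulation_curve", "data.frame"))
  fit <- fit_richness_model(cur, "lomolino")
  expect_true(fit$converged)
  expect_equal(unname(fit$par["Asym"]), 250, tolerance = 1e-6)
  expect_equal(unname(fit$par["xmid"]), 20, tolerance = 1e-6)
  expect_equal(unname(fit$par["slope"]), 6, tolerance = 1e-6)
})

test_that("Lomolino fits agree with vegan's parametrization up to log base", {
  skip_if_not_installed("vegan")
  set.seed(67)
  m <- random_incidence(35, 120, p = 0.25)
  cur <- mao_tau(m)
  fit <- fit_richness_model(cur, "lomolino")
  ref <- vegan::fitspecaccum(vegan::specaccum(m * 1, method = "exact"),
                             model = "lomolino")
  refc <- coef(ref)
  expect_equal(unname(fit$par["Asym"]), unname(refc["Asym"]), tolerance = 1e-3)
  expect_equal(unname(fit$par["xmid"]), unname(refc["xmid"]), tolerance = 1e-3)
  # vegan uses a natural-log exponent: slope_10 = slope_e ^ ln 10
  expect_equal(unname(fit$par["slope"]), unname(refc["slope"])^log(10),
               tolerance = 1e-3)
})

test_that("non-convergent fits are flagged, not fatal", {
  cur <- structure(data.frame(n = 1:3, S = c(1, 2, 3)), method = "exact",
                   S_obs = 3, N = 3,
                   class = c("accumulation_curve", "data.frame"))
  fit <- fit_richness_model(cur, "lomolino")
  expect_false(fit$converged)
  expect_true(is.na(fit$S_est))
})

test_that("completeness ranks zones ascending with failures last", {
  f_ok <- function(sobs, sest) {
    structure(list(model = "lomolino", par = NULL, S_obs = sobs, S_est = sest,
                   rss = 1, completeness = 100 * sobs / sest,
                   converged = TRUE, message = "converged"),
              class = "richness_fit")
  }
  f_bad <- structure(list(model = "lomolino", par = NULL, S_obs = 10,
                          S_est = NA_real_, rss = NA_real_,
                          completeness = NA_real_, converged = FALSE,
                          message = "x"), class = "richness_fit")
  rk <- completeness_rank(list(zc = f_ok(87, 100), za = f_ok(50, 100),
                               zb = f_bad))
  expect_identical(rk$zone_id, c("za", "zc", "zb"))
  expect_equal(rk$completeness[2], 87)
  expect_true(is.na(rk$completeness[3]))
  # relabeling zones permutes rows but not the ordering rule
  rk2 <- completeness_rank(list(q1 = f_ok(50, 100), q2 = f_ok(87, 100)))
  expect_identical(rk2$zone_id, c("q1", "q2"))
})

test_that("a saturated simulated zone is nearly complete", {
  # every species seen: high occupancy, many visits, perfect detection
  land <- generate_landscape(landscape_config(nrow = 8, ncol = 8), seed = 71)
  zones <- setNames(rep("z", 64), land$grid$pentad)
  comm <- generate_community(land, zones,
                             list(richness = c(z = 60L), occupancy = 0.6,
                                  shared_fraction = 0), seed = 2)
  eff <- data.frame(pentad = land$grid$pentad, visits = 8L)
  out <- generate_checklists(eff, comm$occupancy, p_det = 0.9, seed = 3)
  inc <- incidence_matrix(out$checklists)
  fit <- fit_richness_model(mao_tau(inc), "lomolino")
  expect_true(fit$converged)
  expect_gte(fit$completeness, 99)
})
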