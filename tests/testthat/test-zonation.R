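make_climate <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(pentad = sprintf("p%03d", seq_len(n)),
             precip = runif(n, 100, 900),
             t_summer = runif(n, 18, 33),
             t_winter = runif(n, 2, 15))
}

test_that("climate PCA matches an independent eigendecomposition", {
  cov <- make_climate(500, seed = 2)
  p <- climate_pca(cov)
  x <- scale(as.matrix(cov[, c("precip", "t_summer", "t_winter")]))
  eig <- eigen(cor(as.matrix(cov[, c("precip", "t_summer", "t_winter")])))
  for (k in 1:3) {
    v <- eig$vectors[, k]
    if (v[1] < 0) v <- -v # package sign convention: precip loading >= 0
    expect_lt(max(abs(p$loadings[, k] - v)), 1e-8)
  }
  expect_equal(p$variance_explained, eig$values / 3, tolerance = 1e-10)
  expect_equal(sum(p$variance_explained), 1, tolerance = 1e-10)
  # scores are centered and consistent with the loadings
  expect_lt(max(abs(colMeans(p$scores))), 1e-10)
  expect_lt(max(abs(p$scores - x %*% p$loadings)), 1e-8)
})

test_that("PCA variance split is analytic for a duplicated variable", {
  n <- 400
  set.seed(3)
  z <- rnorm(n)
  cov <- data.frame(pentad = sprintf("p%03d", 1:n),
                    precip = 5 * z + 100, t_summer = -2 * z + 20,
                    t_winter = rnorm(n))
  # precip and t_summer perfectly (anti)correlated, t_winter independent:
  # eigenvalues of the correlation matrix are (2, 1, 0) in expectation
  p <- climate_pca(cov)
  expect_equal(p$variance_explained[1], 2 / 3, tolerance = 0.05)
})

test_that("PCA is invariant to rescaling and rejects degenerate input", {
  cov <- make_climate(200, seed = 5)
  p1 <- climate_pca(cov)
  cov2 <- transform(cov, precip = precip * 1000)
  p2 <- climate_pca(cov2)
  expect_equal(p1$loadings, p2$loadings, tolerance = 1e-12)
  expect_equal(p1$scores, p2$scores, tolerance = 1e-10)
  cov3 <- transform(cov, t_winter = 7)
  expect_error(climate_pca(cov3), "t_winter")
})

test_that("climate classes are equal-width bins with a closed top edge", {
  set.seed(4)
  s <- runif(500, 0, 10); s[1] <- 0; s[2] <- 10 - 1e-12
  cls <- assign_climate_classes(s, 10)
  expect_identical(cls, setNames(pmin(10L, 1L + as.integer(floor(s))),
                                 names(s)))
  expect_equal(cls[[1]], 1L)
  expect_equal(assign_climate_classes(c(0, 5, 10), 10)[[3]], 10L)
  expect_error(assign_climate_classes(rep(1, 5)), "equal")
  expect_error(assign_climate_classes(s, 1), "n_classes")
})

test_that("biome assignment is argmax with documented tie-breaks", {
  bf <- data.frame(pentad = c("2600_2200", "2605_2200"),
                   biome_A = c(0.6, 0.5), biome_B = c(0.4, 0.5))
  expect_warning(b <- assign_biome(bf), "tied")
  expect_identical(unname(b), c("A", "A"))
  bf$biome_B[2] <- 0.6
  expect_identical(unname(assign_biome(bf)), c("A", "B"))
  bf[1, 2:3] <- 0
  expect_error(assign_biome(bf), "all-zero")
})

test_that("marginal biomes dissolve into their queen neighbourhood", {
  # 3x3 block of pentads; centre is Forest, ring is Savanna
  lat <- rep(seq(-26, by = -5 / 60, length.out = 3), each = 3)
  lon <- rep(seq(22, by = 5 / 60, length.out = 3), times = 3)
  pent <- encode_pentad(lat, lon)
  bf <- data.frame(pentad = pent, biome_Savanna = 1, biome_Forest = 0)
  bf[5, c("biome_Savanna", "biome_Forest")] <- c(0.2, 0.8)
  b <- assign_biome(bf, reassign = "Forest")
  expect_identical(unname(b[5]), "Savanna")
  expect_true(all(b == "Savanna"))

  # an isolated island falls back to nearest non-reassigned pentad
  far <- c(pent, "3000_3000")
  bf2 <- data.frame(pentad = far, biome_Savanna = c(rep(1, 9), 0),
                    biome_Forest = c(rep(0, 9), 1))
  expect_warning(b2 <- assign_biome(bf2, reassign = "Forest"), "isolated")
  expect_identical(unname(b2[10]), "Savanna")
})

test_that("pooling leaves adequate zones alone and merges forced cases", {
  # all zones already large: fixed point
  biome <- setNames(rep(c("A", "B"), each = 100), sprintf("p%03d", 1:200))
  cls <- setNames(rep(c(1L, 2L, 1L, 2L), each = 50), names(biome))
  counts <- setNames(rep(10L, 100), names(biome)[seq(1, 200, 2)])
  part <- build_zones(biome, cls, counts)
  zs <- attr(part, "zones")
  expect_equal(nrow(zs), 4)
  expect_setequal(zs$zone_id, c("A:1", "A:2", "B:1", "B:2"))

  # a tiny class 4 zone is forced into its neighbour class 3
  biome2 <- setNames(rep("A", 104), sprintf("q%03d", 1:104))
  cls2 <- setNames(rep(c(3L, 4L), c(100, 4)), names(biome2))
  counts2 <- setNames(rep(10L, 52), names(biome2)[1:52])
  part2 <- build_zones(biome2, cls2, counts2)
  expect_identical(attr(part2, "zones")$zone_id, "A:3+4")

  # a biome too small to ever reach the threshold raises the error
  biome3 <- setNames(rep(c("A", "B"), c(100, 2)), sprintf("r%03d", 1:102))
  cls3 <- setNames(rep(1L, 102), names(biome3))
  counts3 <- setNames(rep(10L, 50), names(biome3)[1:50])
  expect_error(build_zones(biome3, cls3, counts3), "biome 'B'")
})

test_that("the engineered 43-zone layout pools to exactly 27 zones", {
  fx <- fixture_43_zones()
  # before pooling: 43 distinct biome x class combinations
  expect_equal(length(unique(paste(fx$biome, fx$classes))), 43)
  part <- build_zones(fx$biome, fx$classes, fx$counts)
  zs <- attr(part, "zones")
  expect_equal(nrow(zs), 27)
  # partition property: zone sizes add to the pentad total
  expect_equal(sum(zs$n_pentads), length(fx$biome))
  expect_false(any(duplicated(part$pentad)))
  # every pooled zone id merges classes within one biome only
  expect_true(all(zs$biome == sub(":.*$", "", zs$zone_id)))
  # expected frequencies all reached the threshold
  s10 <- sum(fx$counts >= 10)
  expect_true(all(zs$n_pentads / length(fx$biome) * s10 >= 5))
})

test_that("pooling is monotone in the minimum expected frequency", {
  set.seed(12)
  for (rep in 1:5) {
    n <- 400
    biome <- setNames(sample(c("A", "B"), n, TRUE), sprintf("s%03d", 1:n))
    cls <- setNames(sample(1:6, n, TRUE, prob = c(8, 4, 2, 1, 1, 1) / 17),
                    names(biome))
    counts <- setNames(rep(10L, 120), sample(names(biome), 120))
    part <- tryCatch(build_zones(biome, cls, counts), error = function(e) NULL)
    if (is.null(part)) next
    zs <- attr(part, "zones")
    expect_true(all(zs$n_pentads / n * 120 >= 5))
    expect_equal(sum(zs$n_pentads), n)
  }
})
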