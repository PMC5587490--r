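# Independent oracles and fixture builders shared across the suite.

# brute-force sample-based rarefaction: mean richness over ALL n-subsets
brute_force_accumulation <- function(inc, n) {
  inc <- inc == 1 | inc == TRUE
  sites <- seq_len(nrow(inc))
  subs <- utils::combn(sites, n, simplify = FALSE)
  mean(vapply(subs, function(s) {
    sum(colSums(inc[s, , drop = FALSE]) > 0)
  }, numeric(1)))
}

# random binary incidence matrix with no empty species columns
random_incidence <- function(n_sites, n_species, p = 0.4) {
  m <- matrix(runif(n_sites * n_species) < p, n_sites, n_species)
  keep <- colSums(m) > 0
  if (!any(keep)) m[1, 1] <- TRUE else m <- m[, keep, drop = FALSE]
  m
}

# direct G formula, written independently of the package
g_oracle <- function(o, e) {
  t <- o * log(o / e)
  2 * sum(t[o > 0])
}

# evaluate the three accumulation models at given parameters
lomolino_curve <- function(n, asym, xmid, slope) {
  asym / (1 + slope^(log10(xmid / n)))
}

# checklist fixture: k visits spread over given pentads, each visit
# drawing a random subset of a species pool
random_checklists <- function(pentads, n_visits, pool = sprintf("sp%02d", 1:20),
                              p = 0.3) {
  pent <- sample(pentads, n_visits, replace = TRUE)
  sp <- lapply(seq_len(n_visits), function(i) {
    s <- pool[runif(length(pool)) < p]
    if (!length(s)) s <- sample(pool, 1)
    s
  })
  as_checklist_table(pent, sprintf("v%04d", seq_len(n_visits)), sp)
}

# the engineered 43-zone layout that pools to 27: seven biomes, sixteen
# deliberately tiny zones each flanked by large ones, so each tiny zone
# merges exactly once into a large neighbour under the pooling rule
fixture_43_zones <- function() {
  layout <- list(
    A = list(classes = 1:7, tiny = c(2, 4, 6)),
    B = list(classes = 1:6, tiny = c(2, 5)),
    C = list(classes = 1:6, tiny = c(2, 5)),
    D = list(classes = 1:6, tiny = c(2, 5)),
    E = list(classes = 1:6, tiny = c(2, 5)),
    F = list(classes = 1:6, tiny = c(2, 5)),
    G = list(classes = 1:6, tiny = c(2, 4, 6))
  )
  biome <- character(0); cls <- integer(0)
  for (b in names(layout)) {
    for (k in layout[[b]]$classes) {
      n <- if (k %in% layout[[b]]$tiny) 2L else 100L
      biome <- c(biome, rep(b, n))
      cls <- c(cls, rep(k, n))
    }
  }
  pent <- sprintf("p%04d", seq_along(biome)) # build_zones needs labels only
  names(cls) <- pent
  biome <- stats::setNames(biome, pent)
  # 300 strictly-sampled pentads (>= 10 lists); which ones is irrelevant
  # to pooling, which depends only on zone sizes and the total
  counts <- stats::setNames(rep(10L, 300L), pent[seq_len(300L)])
  list(biome = biome, classes = cls, counts = counts)
}
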