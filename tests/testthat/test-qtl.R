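mini_map <- function(positions, group = 1, ids = sprintf("m%02d", seq_along(positions))) {
  m <- data.frame(group = group, marker = ids, position = positions,
                  stringsAsFactors = FALSE)
  class(m) <- c("genetic_map", "data.frame")
  m
}

test_that("genotype probabilities are degenerate at markers, normalized everywhere", {
  map <- mini_map(c(0, 2))
  ids <- c("i1", "i2", "i3")
  calls <- matrix(c("A", "H", "B", "A", "H", "B"), 2, 3, byrow = TRUE,
                  dimnames = list(c("m01", "m02"), ids))
  gp <- genotype_probabilities(map, calls, step = 1)
  expect_equal(nrow(gp$grid), 3)
  at0 <- gp$prob[[which(gp$grid$position == 0)]]
  expect_equal(at0["i1", ], c(AA = 1, AB = 0, BB = 0))
  expect_equal(at0["i3", ], c(AA = 0, AB = 0, BB = 1))
  # every row of every position sums to 1
  for (P in gp$prob) expect_equal(rowSums(P), setNames(rep(1, 3), ids))
  # midpoint between two AA markers 2 cM apart: P(AA) > 0.99
  mid <- gp$prob[[which(gp$grid$position == 1)]]
  expect_gt(mid["i1", "AA"], 0.99)
  # missing flank: conditioning falls back to the informative side
  calls_na <- calls
  calls_na["m02", "i1"] <- NA
  gp2 <- genotype_probabilities(map, calls_na, step = 1)
  expect_equal(gp2$prob[[1]]["i1", "AA"], 1)
  expect_gt(gp2$prob[[3]]["i1", "AA"], 0.9)  # beyond 2 cM of an AA call
})

test_that("interval mapping at an observed marker equals the regression oracle", {
  set.seed(55)
  n <- 131
  ids <- sprintf("i%03d", 1:n)
  g <- c(rep("A", 44), rep("H", 52), rep("B", 35))
  calls <- rbind(m01 = g, m02 = sample(g))
  colnames(calls) <- ids
  map <- mini_map(c(0, 30))
  y <- setNames(rnorm(n, mean = c(A = 79.5, H = 82.2, B = 86.9)[g], sd = 3), ids)
  sc <- scan_im(map, calls, y, step = 30)
  # oracle: direct Haley-Knott regression on the observed marker scores
  x <- c(A = 1, H = 0, B = -1)[g]
  z <- c(A = 0, H = 1, B = 0)[g]
  fit1 <- lm(y ~ x + z)
  rss0 <- sum((y - mean(y))^2)
  rss1 <- sum(resid(fit1)^2)
  lod_oracle <- (n / 2) * log10(rss0 / rss1)
  i <- which(sc$position == 0)
  expect_equal(sc$lod[i], lod_oracle, tolerance = 1e-9)
  expect_equal(sc$additive[i], unname(coef(fit1)["x"]), tolerance = 1e-9)
  expect_equal(sc$dominance[i], unname(coef(fit1)["z"]), tolerance = 1e-9)
  # LOD is invariant under affine transformation of the phenotype
  sc2 <- scan_im(map, calls, 3 * y + 100, step = 30)
  expect_equal(sc2$lod, sc$lod, tolerance = 1e-9)
})

test_that("effect estimates reproduce the class-mean parameterization", {
  n <- 131
  ids <- sprintf("i%03d", 1:n)
  g <- c(rep("A", 44), rep("H", 52), rep("B", 35))
  calls <- rbind(m01 = g, m02 = g)
  colnames(calls) <- ids
  map <- mini_map(c(0, 50))
  set.seed(66)
  noise <- rnorm(n, sd = 2)
  for (cl in c("A", "H", "B")) noise[g == cl] <- noise[g == cl] - mean(noise[g == cl])
  y <- setNames(c(A = 79.5, H = 82.2, B = 86.9)[g] + noise, ids)
  sc <- scan_im(map, calls, y, step = 50)
  eff <- qtl_effects(sc, 1, 0)
  # a = (mu_AA - mu_BB)/2, d = mu_AB - (mu_AA + mu_BB)/2
  expect_equal(eff$additive, (79.5 - 86.9) / 2, tolerance = 1e-9)
  expect_equal(eff$dominance, 82.2 - (79.5 + 86.9) / 2, tolerance = 1e-9)
  # constant phenotype across classes: zero effects
  y0 <- setNames(80 + noise, ids)
  sc0 <- scan_im(map, calls, y0, step = 50)
  eff0 <- qtl_effects(sc0, 1, 0)
  expect_equal(eff0$additive, 0, tolerance = 0.5)
  expect_lt(sc0$lod[sc0$position == 0], 1.5)
})

test_that("permutation threshold follows the order-statistic convention", {
  max_lods <- (1:1000) / 100
  expect_equal(lod_threshold(max_lods, alpha = 0.05), 9.50)
  expect_equal(lod_threshold(max_lods, alpha = 0), 10.0)
  # monotone non-increasing in alpha
  alphas <- c(0, 0.01, 0.05, 0.1, 0.5)
  th <- vapply(alphas, function(a) lod_threshold(max_lods, a), 0)
  expect_true(all(diff(th) <= 0))
})

test_that("permutation scan is deterministic under seed and refuses tiny n_perm", {
  cfg <- small_config(seed = 77)
  truth <- simulate_f2_genotypes(cfg)
  codes <- geno_codes(truth$genotypes)
  map <- truth$map
  phen <- simulate_phenotypes(truth, cfg)
  y <- setNames(phen$maturity_time, phen$individual)
  gp <- genotype_probabilities(map, codes, step = 4)
  t1 <- permutation_threshold(map, codes, y, n_perm = 50, method = "im",
                              step = 4, seed = 9, gp = gp)
  t2 <- permutation_threshold(map, codes, y, n_perm = 50, method = "im",
                              step = 4, seed = 9, gp = gp)
  expect_identical(t1$max_lods, t2$max_lods)
  expect_error(permutation_threshold(map, codes, y, n_perm = 10, gp = gp,
                                     step = 4), "20")
})

test_that("support intervals bracket the peak and collapse at drop = 0", {
  cfg <- small_config(seed = 88)
  truth <- simulate_f2_genotypes(cfg)
  codes <- geno_codes(truth$genotypes)
  phen <- simulate_phenotypes(truth, cfg)
  y <- setNames(phen$maturity_time, phen$individual)
  sc <- scan_im(truth$map, codes, y, step = 2)
  i <- which.max(sc$lod)
  ci <- support_interval(sc, sc$group[i], sc$position[i], drop = 1)
  expect_lte(ci[1], sc$position[i])
  expect_gte(ci[2], sc$position[i])
  ci0 <- support_interval(sc, sc$group[i], sc$position[i], drop = 0)
  expect_equal(ci0[1], ci0[2])
  # peaks table carries effects, interval and flanking markers
  pk <- find_peaks(sc, threshold = 3)
  expect_gt(nrow(pk), 0)
  expect_true(all(pk$ci_lo <= pk$position & pk$position <= pk$ci_hi))
  expect_true(all(!is.na(pk$marker_left) | !is.na(pk$marker_right)))
})

test_that("cofactors strengthen the focal QTL when a second QTL segregates", {
  # stochastic matched-seed comparison: cofactors absorbing the second
  # (unlinked) QTL's variance should raise the LOD at the focal QTL
  diffs <- vapply(99:103, function(seed) {
    cfg <- sim_config(n_individuals = 150, n_linkage_groups = 2,
                      markers_per_group = 12, marker_spacing = 8,
                      qtl_spec = list(list(group = 1, position = 40,
                                           additive = -7.2, dominance = -3.3),
                                      list(group = 2, position = 40,
                                           additive = -5, dominance = 0)),
                      flowering_qtl_spec = list(), heritability = 0.4,
                      censor_day = 1000, seed = seed)
    truth <- simulate_f2_genotypes(cfg)
    codes <- geno_codes(truth$genotypes)
    phen <- simulate_phenotypes(truth, cfg)
    y <- setNames(phen$maturity_time, phen$individual)
    gp <- genotype_probabilities(truth$map, codes, step = 2)
    im <- scan_im(truth$map, codes, y, gp = gp)
    cim <- scan_cim(truth$map, codes, y, gp = gp, n_cofactors = 2, window = 25)
    at_q <- im$group == 1 & im$position == 40
    cim$lod[at_q] - im$lod[at_q]
  }, 0)
  expect_gte(sum(diffs >= 0), 4)   # at least 4 of 5 matched seeds
  expect_gt(mean(diffs), 0)
})
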