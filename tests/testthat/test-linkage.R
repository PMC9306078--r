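test_that("duplicate collapsing is missing-tolerant and keeps the most complete marker", {
  ids <- c("i1", "i2", "i3", "i4")
  calls <- rbind(m1 = c("A", "H", "B", NA),
                 m2 = c("A", "H", "B", "B"),
                 m3 = c("A", "H", "A", "B"))
  colnames(calls) <- ids
  ms <- marker_set(calls, source = "gamma")
  out <- collapse_duplicate_markers(ms)
  # m1 and m2 are compatible (missing-tolerant); m2 has fewer missing values;
  # m3 conflicts with both at i3
  expect_setequal(rownames(out$calls), c("m2", "m3"))
  # exact duplicates: one kept, tie broken by id
  dup <- rbind(a2 = c("A", "H", "B", "A"), a1 = c("A", "H", "B", "A"))
  colnames(dup) <- ids
  out2 <- collapse_duplicate_markers(marker_set(dup, source = "gamma"))
  expect_identical(rownames(out2$calls), "a1")
})

test_that("segregation distortion filter applies the chi-square rule per marker type", {
  # (30, 60, 30) fits 1:2:1 perfectly
  perfect <- distortion_test(c(30, 60, 30))
  expect_equal(perfect$statistic, 0)
  expect_equal(perfect$p_value, 1)
  # mildly distorted counts (44, 52, 35): X2 ~ 6.80, P ~ 0.033 -> retained at 0.001
  mid <- distortion_test(c(44, 52, 35))
  expect_equal(mid$statistic, 6.80, tolerance = 1e-2)
  expect_equal(mid$p_value, 0.0334, tolerance = 1e-2)
  # grossly distorted counts are removed
  bad <- distortion_test(c(100, 40, 10))
  expect_lt(bad$p_value, 0.001)

  build_calls <- function(counts) {
    c(rep("A", counts[1]), rep("H", counts[2]), rep("B", counts[3]))
  }
  calls <- rbind(ok1 = c(build_calls(c(30, 60, 30)), rep(NA, 11)),
                 ok2 = build_calls(c(44, 52, 35)),
                 bad = build_calls(c(90, 31, 10)),
                 tiny = c(rep("A", 5), rep(NA, 126)))
  colnames(calls) <- sprintf("i%03d", 1:131)
  ms <- marker_set(calls, source = "gamma")
  out <- segregation_distortion_filter(ms, alpha = 0.001, min_calls = 20)
  expect_setequal(rownames(out$calls), c("ok1", "ok2"))
  # dominant markers are tested against 3:1
  dom <- matrix(c(rep("C", 90), rep("A", 30)), 1, 120,
                dimnames = list("morph", sprintf("i%03d", 1:120)))
  msd <- marker_set(dom, source = "default", type = "dominant")
  outd <- segregation_distortion_filter(msd)
  expect_equal(n_markers(outd), 1)
  expect_equal(outd$info$distortion_p, 1)
})

test_that("recombination MLE: identical, unlinked and linked marker pairs", {
  set.seed(101)
  informative <- sample(c("A", "H", "B"), 150, TRUE, prob = c(0.25, 0.5, 0.25))
  same <- estimate_recombination(informative, informative)
  expect_equal(same$r, 0)
  expect_gt(same$lod, 0)
  # independent markers at n = 10000: r ~ 0.5, LOD ~ 0
  g1 <- sample(c("A", "H", "B"), 10000, TRUE, prob = c(0.25, 0.5, 0.25))
  g2 <- sample(c("A", "H", "B"), 10000, TRUE, prob = c(0.25, 0.5, 0.25))
  indep <- estimate_recombination(g1, g2)
  expect_gt(indep$r, 0.45)
  expect_lt(indep$lod, 2)
  expect_error(estimate_recombination(c("A", NA), c(NA, "B")), "undefined pair")
})

test_that("recombination MLE is unbiased at r = 0.1 over replicates", {
  set.seed(202)
  n <- 150
  r_true <- 0.1
  est <- replicate(500, {
    a1 <- rbinom(n, 1, 0.5)
    b1 <- ifelse(rbinom(n, 1, r_true) == 1, 1 - a1, a1)
    a2 <- rbinom(n, 1, 0.5)
    b2 <- ifelse(rbinom(n, 1, r_true) == 1, 1 - a2, a2)
    g1 <- c("A", "H", "B")[a1 + a2 + 1]
    g2 <- c("A", "H", "B")[b1 + b2 + 1]
    estimate_recombination(g1, g2)$r
  })
  expect_lt(abs(mean(est) - r_true), 0.01)
})

test_that("grouping recovers simulated linkage groups and honours thresholds", {
  cfg <- small_config(seed = 33)
  truth <- simulate_f2_genotypes(cfg)
  codes <- geno_codes(truth$genotypes)
  pl <- pairwise_linkage(codes)
  groups <- group_markers(pl)
  expect_length(groups, 3)
  expect_true(all(vapply(groups, length, 0L) == 12))
  # recovered groups match the true chromosome assignment
  for (g in groups) {
    expect_length(unique(truth$map$group[match(g, truth$map$marker)]), 1)
  }
  # impossible LOD threshold isolates every marker
  expect_length(group_markers(pl, lod_min = Inf), nrow(codes))
  # r = 0 pairs always join
  x2 <- codes[c(1, 1), ]
  rownames(x2) <- c("c1", "c2")
  expect_length(group_markers(pairwise_linkage(x2)), 1)
})

test_that("ordering recovers the true order up to reversal, invariant to shuffling", {
  cfg <- sim_config(n_individuals = 150, n_linkage_groups = 1,
                    markers_per_group = 10, marker_spacing = 5,
                    qtl_spec = list(), flowering_qtl_spec = list(), seed = 44)
  truth <- simulate_f2_genotypes(cfg)
  codes <- geno_codes(truth$genotypes)
  pl <- pairwise_linkage(codes)
  ord <- order_markers(pl, runs = 20, seed = 1)
  true_order <- truth$map$marker
  expect_true(identical(ord$marker, true_order) ||
                identical(ord$marker, rev(true_order)))
  expect_equal(ord$position[1], 0)
  expect_true(all(diff(ord$position) >= 0))
  # objective equals the sum of adjacent r, positions the Kosambi cumsum
  r_adj <- vapply(seq_len(9), function(i) {
    pl$r[ord$marker[i], ord$marker[i + 1]]
  }, 0)
  expect_equal(max(ord$position), sum(kosambi_distance(r_adj)))
  # shuffled input gives the identical ordered result
  shuf <- sample(rownames(codes))
  ord2 <- order_markers(pl, shuf, runs = 20, seed = 1)
  expect_identical(ord2$marker, ord$marker)
  # two markers: length is the pairwise Kosambi distance
  two <- order_markers(pl, rownames(codes)[1:2], runs = 1, seed = 1)
  expect_equal(max(two$position),
               kosambi_distance(pl$r[rownames(codes)[1], rownames(codes)[2]]))
})

test_that("gap filter removes markers beyond oversized gaps and is idempotent", {
  map <- data.frame(group = 1, marker = c("m1", "m2", "m3", "m4"),
                    position = c(0, 5, 30, 35), stringsAsFactors = FALSE)
  class(map) <- c("genetic_map", "data.frame")
  out <- gap_filter(map, max_gap = 20)
  # 25 cM gap: the far side loses its markers (tie broken to the right block)
  expect_identical(out$marker, c("m1", "m2"))
  expect_identical(attr(out, "removed"), c("m3", "m4"))
  # all gaps small: unchanged
  ok <- data.frame(group = 1, marker = c("a", "b", "c"),
                   position = c(0, 10, 20), stringsAsFactors = FALSE)
  class(ok) <- c("genetic_map", "data.frame")
  expect_identical(gap_filter(ok, 20)$marker, ok$marker)
  # idempotence
  twice <- gap_filter(out, 20)
  expect_identical(twice$marker, out$marker)
  expect_identical(twice$position, out$position)
})

test_that("map summary reproduces the length / marker-count arithmetic", {
  mk_map <- function(n, total_len) {
    m <- data.frame(group = 1, marker = sprintf("m%04d", 1:n),
                    position = seq(0, total_len, length.out = n),
                    stringsAsFactors = FALSE)
    class(m) <- c("genetic_map", "data.frame")
    m
  }
  s1 <- summarize_map(mk_map(666, 1179.8))
  expect_equal(s1$average_distance, 1.77, tolerance = 1e-2)
  s2 <- summarize_map(mk_map(529, 2051.8))
  expect_equal(s2$average_distance, 3.88, tolerance = 1e-2)
  m <- mk_map(2, 10)
  expect_equal(summarize_map(m)$average_distance, 5.0)
  expect_equal(summarize_map(m)$total_length, 10)
})

test_that("map bridging reports group correspondence and injected faults", {
  map <- data.frame(group = rep(1:2, each = 5),
                    marker = sprintf("m%02d", 1:10),
                    position = rep(seq(0, 40, 10), 2), stringsAsFactors = FALSE)
  class(map) <- c("genetic_map", "data.frame")
  same <- bridge_maps(map, map)
  expect_equal(same$n_inconsistent, 0)
  expect_equal(nrow(same$bridge), 10)
  # deliberately move one marker to the other group in map B
  mapb <- map
  mapb$group[mapb$marker == "m03"] <- 2
  fault <- bridge_maps(map, mapb)
  expect_equal(fault$n_inconsistent, 1)
  # disjoint maps produce an empty report
  mapc <- map
  mapc$marker <- paste0("x", mapc$marker)
  empty <- bridge_maps(map, mapc)
  expect_equal(nrow(empty$bridge), 0)
  expect_equal(empty$n_inconsistent, 0)
})

test_that("two samples from one genome bridge with no cross-group markers", {
  cfg_a <- small_config(seed = 71)
  cfg_b <- small_config(seed = 72)
  truth_a <- simulate_f2_genotypes(cfg_a)
  truth_b <- simulate_f2_genotypes(cfg_b)   # same genome, independent cross
  map_a <- build_genetic_map(geno_codes(truth_a$genotypes), runs = 5, seed = 1)
  map_b <- build_genetic_map(geno_codes(truth_b$genotypes), runs = 5, seed = 2)
  br <- bridge_maps(map_a, map_b)
  expect_equal(nrow(br$bridge), 36)
  expect_equal(br$n_inconsistent, 0)
})
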