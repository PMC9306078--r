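test_that("config validation enforces the depth and genome invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(marker_spacing = 55), "50")
  expect_error(sim_config(depth_model = list(mu_absent = 60, mu_het = 50,
                                             mu_hom = 100, dispersion = 0.02,
                                             per_marker_scale_sd = 0)),
               "mu_absent < mu_het")
  expect_error(sim_config(heritability = 1.2), "heritability")
  expect_error(sim_config(qtl_spec = list(list(group = 1, position = 500,
                                               additive = 1, dominance = 0))),
               "position")
})

test_that("F2 genotypes segregate 1:2:1 and recombine at the Kosambi rate", {
  cfg <- sim_config(n_individuals = 10000, n_linkage_groups = 1,
                    markers_per_group = 2, marker_spacing = 10,
                    qtl_spec = list(), flowering_qtl_spec = list(), seed = 5)
  truth <- simulate_f2_genotypes(cfg)
  # marginal frequencies: 3 SE of (0.25, 0.50, 0.25) at n = 10000
  f <- table(factor(truth$genotypes[1, ], levels = 0:2)) / 10000
  expect_lt(abs(f[[1]] - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))
  expect_lt(abs(f[[2]] - 0.50), 3 * sqrt(0.5 * 0.5 / 10000))
  expect_lt(abs(f[[3]] - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))
  # realized gamete recombinant fraction ~ Kosambi inverse of 10 cM = 0.0987
  r_true <- kosambi_inverse(10)
  est <- estimate_recombination(geno_codes(truth$genotypes)[1, ],
                                geno_codes(truth$genotypes)[2, ])
  expect_lt(abs(est$r - r_true), 3 * sqrt(r_true * (1 - r_true) / 20000))
})

test_that("zero marker spacing yields identical genotype columns", {
  cfg <- sim_config(n_individuals = 200, n_linkage_groups = 1,
                    markers_per_group = 3, marker_spacing = 0,
                    qtl_spec = list(), flowering_qtl_spec = list(), seed = 2)
  truth <- simulate_f2_genotypes(cfg)
  expect_true(all(truth$genotypes[1, ] == truth$genotypes[2, ]))
  expect_true(all(truth$genotypes[2, ] == truth$genotypes[3, ]))
})

test_that("read depths track dosage means and are deterministic under seed", {
  cfg <- sim_config(n_individuals = 150, n_linkage_groups = 1,
                    markers_per_group = 30, marker_spacing = 5,
                    qtl_spec = list(), flowering_qtl_spec = list(),
                    depth_model = list(mu_absent = 0, mu_het = 50, mu_hom = 100,
                                       dispersion = 0, per_marker_scale_sd = 0),
                    seed = 9)
  truth <- simulate_f2_genotypes(cfg)
  depths <- simulate_read_depths(truth, cfg)
  dosage <- truth$genotypes
  sp1 <- depths$source_parent == 1L
  dosage[sp1, ] <- 2L - truth$genotypes[sp1, ]
  # Poisson limit: per-dosage sample means within 5% of (0, 50, 100)
  expect_equal(mean(depths$counts[dosage == 0L]), 0)
  expect_lt(abs(mean(depths$counts[dosage == 1L]) / 50 - 1), 0.05)
  expect_lt(abs(mean(depths$counts[dosage == 2L]) / 100 - 1), 0.05)
  # class means monotone in dosage for every marker
  for (m in sample(rownames(depths$counts), 5)) {
    mns <- tapply(depths$counts[m, ], dosage[m, ], mean)
    expect_true(all(diff(mns) > 0))
  }
  # bit-identical on re-run
  depths2 <- simulate_read_depths(truth, cfg)
  expect_identical(depths$counts, depths2$counts)
  expect_identical(depths$parent1_counts, depths2$parent1_counts)
})

test_that("default caller emulation honours threshold, fraction and error rate", {
  cfg <- sim_config(n_individuals = 100, n_linkage_groups = 2,
                    markers_per_group = 25, marker_spacing = 5,
                    qtl_spec = list(), flowering_qtl_spec = list(),
                    default_caller = list(presence_threshold = 10,
                                          codominant_fraction = 0.4,
                                          error_rate = 0),
                    seed = 3)
  truth <- simulate_f2_genotypes(cfg)
  depths <- simulate_read_depths(truth, cfg)
  defaults <- simulate_default_calls(depths, truth, cfg)
  # threshold boundary: count 9 -> absent, count 10 -> present
  expect_true(all(defaults$dominant[depths$counts == 9] == "A"))
  expect_true(all(defaults$dominant[depths$counts == 10] == "P"))
  # error_rate = 0: default co-dominant calls equal truth exactly
  codes <- geno_codes(truth$genotypes)
  got <- defaults$codominant$calls
  expect_identical(got, codes[rownames(got), ])
  expect_equal(nrow(got), round(0.4 * 50))

  # error_rate = 0.05: corrupted fraction within 3 SE of 0.05
  cfg2 <- sim_config(n_individuals = 100, n_linkage_groups = 2,
                     markers_per_group = 25, marker_spacing = 5,
                     qtl_spec = list(), flowering_qtl_spec = list(),
                     default_caller = list(presence_threshold = 10,
                                           codominant_fraction = 0.4,
                                           error_rate = 0.05),
                     seed = 3)
  defaults2 <- simulate_default_calls(depths, truth, cfg2)
  got2 <- defaults2$codominant$calls
  n_calls <- length(got2)
  frac <- mean(got2 != codes[rownames(got2), ])
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n_calls))
})

test_that("phenotypes follow the additive/dominance parameterization", {
  cfg <- sim_config(n_individuals = 400, n_linkage_groups = 1,
                    markers_per_group = 5, marker_spacing = 10,
                    qtl_spec = list(list(group = 1, position = 20,
                                         additive = -7.2, dominance = -3.3)),
                    flowering_qtl_spec = list(),
                    heritability = 1, censor_day = 1000, baseline = 90,
                    seed = 4)
  truth <- simulate_f2_genotypes(cfg)
  phen <- simulate_phenotypes(truth, cfg)
  qmk <- truth$map$marker[truth$map$position == 20]
  g <- truth$genotypes[qmk, ]
  mns <- tapply(phen$maturity_time, g, mean)
  # noise-free class means: homozygote difference exactly 2a, het offset d
  expect_equal(unname(mns[["0"]] - mns[["2"]]), 2 * (-7.2))
  expect_equal(unname(mns[["1"]] - (mns[["0"]] + mns[["2"]]) / 2), -3.3)
})

test_that("null effects give genotype-independent phenotypes and censoring truncates", {
  cfg <- sim_config(n_individuals = 2000, n_linkage_groups = 1,
                    markers_per_group = 4, marker_spacing = 10,
                    qtl_spec = list(), flowering_qtl_spec = list(),
                    censor_day = 1000, seed = 6)
  truth <- simulate_f2_genotypes(cfg)
  phen <- simulate_phenotypes(truth, cfg)
  g <- truth$genotypes[1, ]
  expect_lt(abs(cor(phen$maturity_time, g)), 0.08)  # ~3.5 SE at n = 2000
  # censor_day below the baseline censors everyone at the end day
  cfg2 <- sim_config(n_individuals = 50, n_linkage_groups = 1,
                     markers_per_group = 4, marker_spacing = 10,
                     qtl_spec = list(), flowering_qtl_spec = list(),
                     baseline = 85, censor_day = 40, seed = 6)
  truth2 <- simulate_f2_genotypes(cfg2)
  phen2 <- simulate_phenotypes(truth2, cfg2)
  expect_true(all(phen2$censored))
  expect_true(all(phen2$maturity_time == 40))
  # heritability 1 with no genetic variance is rejected
  cfg3 <- sim_config(n_individuals = 50, n_linkage_groups = 1,
                     markers_per_group = 4, marker_spacing = 10,
                     qtl_spec = list(), flowering_qtl_spec = list(),
                     heritability = 1, seed = 6)
  truth3 <- simulate_f2_genotypes(cfg3)
  expect_error(simulate_phenotypes(truth3, cfg3), "genetic variance")
})

test_that("morphological marker segregates 3:1 and co-segregates with its locus", {
  cfg <- sim_config(n_individuals = 10000, n_linkage_groups = 1,
                    markers_per_group = 3, marker_spacing = 10,
                    qtl_spec = list(), flowering_qtl_spec = list(), seed = 8)
  truth <- simulate_f2_genotypes(cfg)
  morph <- simulate_morphological_marker(truth)
  frac <- mean(morph$calls == "C")
  expect_lt(abs(frac - 0.75), 3 * sqrt(0.75 * 0.25 / 10000))
  # perfect co-segregation with the carrier classes of its co-dominant locus
  g <- truth$genotypes[morph$locus, ]
  expect_true(all((morph$calls == "C") == (g >= 1)))
  # mappable as a dominant locus: tight linkage to the flanking marker
  codes <- geno_codes(truth$genotypes)
  est <- estimate_recombination(morph$calls, codes[2, ])
  expect_lt(est$r, 0.15)
  expect_gt(est$lod, 3)
})
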