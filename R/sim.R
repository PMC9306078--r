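#' Configuration for the synthetic F2 data generator
#'
#' Bundles every parameter of the simulated study: population and genome
#' layout, QTL effects on the two phenology traits, trait noise, phenotype
#' censoring, the amplicon read-depth model, and the emulated default caller.
#' Defaults describe a buckwheat-style F2 of 150 individuals over 8 linkage
#' groups, one major maturity QTL (additive effect -7.19 days after sowing,
#' dominance -3.28, explaining ~21% of trait variance) and one flowering QTL,
#' with the field experiment ending (and maturity censored) at 105 DAS.
#'
#' @param n_individuals number of F2 individuals.
#' @param n_linkage_groups number of chromosomes/linkage groups.
#' @param markers_per_group co-dominant amplicon markers per group.
#' @param marker_spacing spacing of adjacent markers in cM, in `[0, 50)`.
#' @param qtl_spec list of maturity-time QTLs, each a list with elements
#'   `group`, `position` (cM), `additive` and `dominance` (trait units; the
#'   additive effect is carried by the seed-parent A allele, so a negative
#'   value means the A allele decreases the trait).
#' @param flowering_qtl_spec same structure, for flowering time.
#' @param heritability fraction of maturity-time variance explained by its
#'   QTLs, in `[0, 1]`.
#' @param flowering_heritability same, for flowering time.
#' @param baseline,flowering_baseline trait intercepts in days after sowing.
#' @param resid_sd_floor residual standard deviation (DAS) used when a trait
#'   has no genetic variance (e.g. all effects zero).
#' @param censor_day day after sowing at which the experiment ends; maturity
#'   beyond it is right-censored.
#' @param depth_model list with `mu_absent`, `mu_het`, `mu_hom` (mean reads for
#'   allele dosage 0/1/2 of the marker's source parent, must be increasing),
#'   `dispersion` (negative-binomial overdispersion; 0 gives Poisson) and
#'   `per_marker_scale_sd` (sd of the lognormal per-marker depth scale).
#' @param default_caller list with `presence_threshold` (reads needed for a
#'   dominant "present" call), `codominant_fraction` (fraction of loci that
#'   also receive default co-dominant calls) and `error_rate` (corruption rate
#'   of those calls).
#' @param seed integer seed; every generator stage derives its stream from it.
#' @return a validated list of class `"sim_config"`.
#' @seealso [simulate_f2_genotypes()], [simulate_read_depths()],
#'   [simulate_phenotypes()]
#' @export
sim_config <- function(n_individuals = 150L,
                       n_linkage_groups = 8L,
                       markers_per_group = 20L,
                       marker_spacing = 5,
                       qtl_spec = list(list(group = 6, position = 45,
                                            additive = -7.19, dominance = -3.28)),
                       flowering_qtl_spec = list(list(group = 3, position = 45,
                                                      additive = -6.52, dominance = -0.03)),
                       heritability = 0.21,
                       flowering_heritability = 0.15,
                       baseline = 85,
                       flowering_baseline = 35,
                       resid_sd_floor = 8,
                       censor_day = 105,
                       depth_model = list(mu_absent = 2, mu_het = 50, mu_hom = 100,
                                          dispersion = 0.02, per_marker_scale_sd = 0.25),
                       default_caller = list(presence_threshold = 10,
                                             codominant_fraction = 0.1,
                                             error_rate = 0.02),
                       seed = 1L) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_linkage_groups = as.integer(n_linkage_groups),
              markers_per_group = as.integer(markers_per_group),
              marker_spacing = marker_spacing,
              qtl_spec = qtl_spec,
              flowering_qtl_spec = flowering_qtl_spec,
              heritability = heritability,
              flowering_heritability = flowering_heritability,
              baseline = baseline,
              flowering_baseline = flowering_baseline,
              resid_sd_floor = resid_sd_floor,
              censor_day = censor_day,
              depth_model = depth_model,
              default_caller = default_caller,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_individuals >= 1, cfg$n_linkage_groups >= 1,
            cfg$markers_per_group >= 1)
  if (cfg$marker_spacing < 0 || cfg$marker_spacing >= 50) {
    stop("invalid config: marker spacing must lie in [0, 50) cM ",
         "(adjacent recombination must stay below 0.5)")
  }
  dm <- cfg$depth_model
  if (any(c(dm$mu_absent, dm$mu_het, dm$mu_hom) < 0)) {
    stop("invalid config: depth means must be non-negative")
  }
  if (!(dm$mu_absent < dm$mu_het && dm$mu_het < dm$mu_hom)) {
    stop("invalid config: depth means must satisfy mu_absent < mu_het < mu_hom")
  }
  if (dm$dispersion < 0 || dm$per_marker_scale_sd < 0) {
    stop("invalid config: dispersion and per_marker_scale_sd must be >= 0")
  }
  for (h in c(cfg$heritability, cfg$flowering_heritability)) {
    if (h < 0 || h > 1) stop("invalid config: heritability must lie in [0, 1]")
  }
  glen <- (cfg$markers_per_group - 1) * cfg$marker_spacing
  for (q in c(cfg$qtl_spec, cfg$flowering_qtl_spec)) {
    if (q$group < 1 || q$group > cfg$n_linkage_groups) {
      stop("invalid config: QTL group out of range")
    }
    if (q$position < 0 || q$position > glen) {
      stop("invalid config: QTL position outside its linkage group")
    }
  }
  dc <- cfg$default_caller
  if (dc$codominant_fraction < 0 || dc$codominant_fraction > 1 ||
      dc$error_rate < 0 || dc$error_rate > 1) {
    stop("invalid config: default-caller fractions must lie in [0, 1]")
  }
  invisible(cfg)
}

#' Simulate F2 genotypes along a known genetic map
#'
#' Each individual is the union of two independently simulated gametes. A
#' gamete is a Markov chain over the ordered markers of each linkage group:
#' the first allele is drawn at random from the two parental alleles and each
#' adjacent interval recombines with probability `kosambi_inverse(spacing)`
#' (no interference between intervals). Marginal genotype frequencies are
#' therefore 1:2:1 (AA:AB:BB) at every marker. Genotypes are coded as the
#' count of pollen-parent (B) alleles: 0 = AA, 1 = AB, 2 = BB.
#'
#' @param config a [sim_config()].
#' @return an object of class `"sim_truth"`: list with `genotypes` (integer
#'   marker x individual matrix, values 0/1/2), `map` (a `genetic_map` data
#'   frame with columns `group`, `marker`, `position`), and `config`.
#' @export
simulate_f2_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_individuals
  G <- config$n_linkage_groups
  M <- config$markers_per_group
  r <- kosambi_inverse(config$marker_spacing)
  if (r >= 0.5) stop("invalid config: adjacent recombination fraction >= 0.5")

  geno <- vector("list", G)
  for (g in seq_len(G)) {
    alleles <- matrix(0L, nrow = 2L * n, ncol = M)
    alleles[, 1] <- stats::rbinom(2L * n, 1L, 0.5)
    if (M > 1) {
      for (j in 2:M) {
        flip <- stats::rbinom(2L * n, 1L, r)
        alleles[, j] <- ifelse(flip == 1L, 1L - alleles[, j - 1L], alleles[, j - 1L])
      }
    }
    geno[[g]] <- alleles[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
      alleles[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  }
  genotypes <- t(do.call(cbind, geno))  # markers x individuals
  marker_ids <- sprintf("AMP%07d", seq_len(G * M))
  rownames(genotypes) <- marker_ids
  colnames(genotypes) <- sprintf("F2_%03d", seq_len(n))
  map <- data.frame(group = rep(seq_len(G), each = M),
                    marker = marker_ids,
                    position = rep((seq_len(M) - 1) * config$marker_spacing, G),
                    stringsAsFactors = FALSE)
  class(map) <- c("genetic_map", "data.frame")
  structure(list(genotypes = genotypes, map = map, config = config),
            class = "sim_truth")
}

#' Simulate an amplicon read-depth matrix from true genotypes
#'
#' Each marker tracks the amplicon of one parent (its "source parent", drawn
#' at random): read depth depends on the individual's dosage (0/1/2) of that
#' parent's allele. Counts are gamma-mixed Poisson (negative binomial with
#' size `1/dispersion`; Poisson when `dispersion = 0`) around
#' `mu_dosage * scale_m`, where `scale_m` is a per-marker lognormal depth
#' scale with unit mean. Parent columns are generated from the fully
#' homozygous parental genotypes.
#'
#' @param truth a [simulate_f2_genotypes()] result.
#' @param config the matching [sim_config()].
#' @return an object of class `"depth_matrix"`: list with `counts` (marker x
#'   individual integer matrix), `parent1_counts`, `parent2_counts` (per
#'   marker), and `source_parent` (1 = seed parent A, 2 = pollen parent B).
#' @export
simulate_read_depths <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(config$seed + 1L)
  geno <- truth$genotypes
  M <- nrow(geno)
  n <- ncol(geno)
  dm <- config$depth_model
  mu_vec <- c(dm$mu_absent, dm$mu_het, dm$mu_hom)

  source_parent <- sample(1:2, M, replace = TRUE)
  sdlog <- dm$per_marker_scale_sd
  scale_m <- exp(stats::rnorm(M, mean = -sdlog^2 / 2, sd = sdlog))

  # dosage of the source parent's allele; genotypes count B alleles
  dosage <- geno
  sp1 <- source_parent == 1L
  dosage[sp1, ] <- 2L - geno[sp1, , drop = FALSE]
  mu <- mu_vec[dosage + 1L] * scale_m[row(geno)]
  counts <- draw_counts(mu, dm$dispersion)
  dim(counts) <- dim(geno)
  dimnames(counts) <- dimnames(geno)

  p1_dosage <- ifelse(source_parent == 1L, 2L, 0L)  # parent1 is AA everywhere
  p2_dosage <- 2L - p1_dosage
  parent1 <- draw_counts(mu_vec[p1_dosage + 1L] * scale_m, dm$dispersion)
  parent2 <- draw_counts(mu_vec[p2_dosage + 1L] * scale_m, dm$dispersion)
  names(parent1) <- names(parent2) <- names(source_parent) <- rownames(geno)

  structure(list(counts = counts,
                 parent1_counts = parent1,
                 parent2_counts = parent2,
                 source_parent = source_parent),
            class = "depth_matrix")
}

draw_counts <- function(mu, dispersion) {
  if (dispersion > 0) {
    stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  } else {
    stats::rpois(length(mu), lambda = mu)
  }
}

#' Emulate the default dominant/co-dominant caller output
#'
#' The proprietary caller's behaviour is emulated, not reverse-engineered:
#' the dominant call is "P" (present) iff the read count reaches
#' `presence_threshold`, and a random `codominant_fraction` of loci carry
#' default co-dominant calls equal to the true genotype corrupted at rate
#' `error_rate` (a corrupted call becomes one of the other two codes).
#'
#' @inheritParams simulate_read_depths
#' @param depths a [simulate_read_depths()] result.
#' @return list with `dominant` (marker x individual character matrix of
#'   "P"/"A") and `codominant` (a [marker_set] with source `"default"`
#'   covering the selected loci).
#' @export
simulate_default_calls <- function(depths, truth, config = truth$config) {
  stopifnot(inherits(depths, "depth_matrix"), inherits(truth, "sim_truth"))
  set.seed(config$seed + 2L)
  dc <- config$default_caller
  counts <- depths$counts
  dominant <- ifelse(counts >= dc$presence_threshold, "P", "A")

  M <- nrow(counts)
  n_codom <- round(dc$codominant_fraction * M)
  codom_markers <- sort(sample(rownames(counts), n_codom))
  codes <- c("A", "H", "B")
  calls <- matrix(codes[truth$genotypes[codom_markers, , drop = FALSE] + 1L],
                  nrow = n_codom, dimnames = list(codom_markers, colnames(counts)))
  if (dc$error_rate > 0 && length(calls) > 0) {
    err <- stats::runif(length(calls)) < dc$error_rate
    if (any(err)) {
      wrong <- vapply(calls[err], function(cc) sample(setdiff(codes, cc), 1L), "")
      calls[err] <- wrong
    }
  }
  codominant <- marker_set(calls, source = "default",
                           source_parent = depths$source_parent[codom_markers])
  list(dominant = dominant, codominant = codominant)
}

# genetic values of one trait given a QTL spec: AA -> +a, AB -> +d, BB -> -a
trait_genetic_values <- function(truth, qtl_spec) {
  gv <- numeric(ncol(truth$genotypes))
  for (q in qtl_spec) {
    grp <- truth$map[truth$map$group == q$group, ]
    if (nrow(grp) == 0) stop("QTL group absent from true map")
    mk <- grp$marker[which.min(abs(grp$position - q$position))]
    g <- truth$genotypes[mk, ]
    gv <- gv + c(q$additive, q$dominance, -q$additive)[g + 1L]
  }
  gv
}

#' Simulate censored phenology phenotypes
#'
#' Maturity and flowering times are `baseline + genetic value + noise`, where
#' the genetic value sums, over the trait's QTLs, `+a` for the seed-parent
#' homozygote (AA), `d` for the heterozygote and `-a` for the pollen-parent
#' homozygote (BB). Noise is Gaussian, scaled so that the genetic fraction of
#' the total variance equals the trait heritability; with zero genetic
#' variance the residual sd falls back to `resid_sd_floor`. Maturity beyond
#' `censor_day` is right-censored: flagged and truncated to `censor_day`.
#'
#' @inheritParams simulate_read_depths
#' @return a data frame (class `"phenotype_table"`) with columns `individual`,
#'   `flowering_time`, `maturity_time`, `censored`.
#' @export
simulate_phenotypes <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(config$seed + 3L)
  n <- ncol(truth$genotypes)
  maturity <- config$baseline +
    sim_trait_values(truth, config$qtl_spec, config$heritability,
                     config$resid_sd_floor)
  flowering <- config$flowering_baseline +
    sim_trait_values(truth, config$flowering_qtl_spec,
                     config$flowering_heritability, config$resid_sd_floor)
  censored <- maturity > config$censor_day
  maturity[censored] <- config$censor_day
  out <- data.frame(individual = colnames(truth$genotypes),
                    flowering_time = flowering,
                    maturity_time = maturity,
                    censored = censored,
                    stringsAsFactors = FALSE)
  class(out) <- c("phenotype_table", "data.frame")
  out
}

sim_trait_values <- function(truth, qtl_spec, h2, resid_sd_floor) {
  gv <- trait_genetic_values(truth, qtl_spec)
  var_g <- stats::var(gv)
  if (var_g > 0) {
    if (h2 == 0) {
      stop("heritability 0 with nonzero genetic effects; set effects to zero instead")
    }
    noise_sd <- sqrt(var_g * (1 - h2) / h2)
  } else {
    if (h2 == 1) stop("heritability 1 requires nonzero genetic variance")
    noise_sd <- resid_sd_floor
  }
  gv + stats::rnorm(length(gv), sd = noise_sd)
}

#' Simulate a dominant morphological marker
#'
#' Models a floral-morph locus where the pollen-parent allele is dominant (as
#' for the long-homostyle self-compatibility allele over pin): carriers of at
#' least one B allele at the designated locus show the dominant phenotype,
#' coded `"C"` (not AA), and recessive homozygotes are coded `"A"`. The
#' phenotype classes segregate 3:1 and the column can be mapped as a dominant
#' locus alongside the co-dominant markers.
#'
#' @inheritParams simulate_read_depths
#' @param locus marker id whose genotypes drive the morphology; defaults to
#'   the first marker of the first linkage group.
#' @param name id under which the marker is reported.
#' @return list with `calls` (named character vector, codes "C"/"A"), `locus`,
#'   `name`, and `type = "dominant"`.
#' @export
simulate_morphological_marker <- function(truth, locus = NULL,
                                          name = "Flower_type") {
  stopifnot(inherits(truth, "sim_truth"))
  if (is.null(locus)) locus <- truth$map$marker[1]
  if (!locus %in% rownames(truth$genotypes)) stop("unknown locus: ", locus)
  g <- truth$genotypes[locus, ]
  calls <- ifelse(g >= 1L, "C", "A")
  names(calls) <- colnames(truth$genotypes)
  list(calls = calls, locus = locus, name = name, type = "dominant")
}
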