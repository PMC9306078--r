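# Interval-mapping machinery -------------------------------------------------

# Conditional 3-locus table: T[gL, gR, gQ] = P(QTL genotype | flanks), from
# the per-gamete Markov chain under the map-function-consistent
# no-interference model. Gametes are independent; the F2 genotype is the sum
# of two gamete alleles at each locus.
cond_table3 <- function(r1, r2) {
  trans <- function(a, b, r) if (a == b) 1 - r else r
  J <- array(0, c(3, 3, 3))  # gL, gQ, gR
  hap <- expand.grid(aL = 0:1, aQ = 0:1, aR = 0:1)
  freq <- apply(hap, 1, function(h) {
    0.5 * trans(h[1], h[2], r1) * trans(h[2], h[3], r2)
  })
  for (i in 1:8) {
    for (j in 1:8) {
      gL <- hap$aL[i] + hap$aL[j]
      gQ <- hap$aQ[i] + hap$aQ[j]
      gR <- hap$aR[i] + hap$aR[j]
      J[gL + 1, gQ + 1, gR + 1] <- J[gL + 1, gQ + 1, gR + 1] + freq[i] * freq[j]
    }
  }
  Tt <- array(NA_real_, c(3, 3, 3))  # gL, gR, gQ
  for (gL in 1:3) {
    for (gR in 1:3) {
      denom <- sum(J[gL, , gR])
      if (denom > 0) Tt[gL, gR, ] <- J[gL, , gR] / denom
    }
  }
  Tt
}

# Conditional on a single flanking marker at recombination r
cond_table2 <- function(r) {
  J <- matrix(f2_joint9(r), 3, 3, byrow = TRUE)  # gM rows, gQ cols
  sweep(J, 1, rowSums(J), `/`)
}

#' Genotype-class probabilities along the map
#'
#' At every grid position (a `step`-cM lattice union the marker positions of
#' each linkage group), computes P(AA), P(AB), P(BB) for each individual given
#' its nearest informative flanking marker genotypes, with recombination
#' fractions obtained from the Kosambi inverse of the map distances and no
#' interference between the two intervals. At an observed marker position the
#' probabilities are degenerate; individuals missing a flank are conditioned
#' on one side only, or fall back to the Mendelian prior (0.25, 0.50, 0.25).
#'
#' @param map a `genetic_map`.
#' @param genotypes `marker_set` or call matrix covering the map's markers
#'   (codes A/H/B; dominant codes are treated as missing here).
#' @param step grid spacing in cM.
#' @return object of class `"genotype_probs"`: list with `grid` (data frame
#'   `group`, `position`, `marker`), `prob` (list of n x 3 matrices, columns
#'   AA/AB/BB), and `individuals`.
#' @export
genotype_probabilities <- function(map, genotypes, step = 1) {
  stopifnot(inherits(map, "genetic_map"))
  calls <- get_calls(genotypes)
  individuals <- colnames(calls)
  n <- length(individuals)
  grid_rows <- list()
  probs <- list()
  prior <- c(0.25, 0.5, 0.25)
  for (grp in unique(map$group)) {
    gmap <- map[map$group == grp, , drop = FALSE]
    gmap <- gmap[order(gmap$position), , drop = FALSE]
    mk <- gmap$marker
    present <- mk %in% rownames(calls)
    if (!all(present)) stop("map markers missing from genotype matrix: ",
                            paste(mk[!present][1], "..."))
    g <- matrix(match(calls[mk, , drop = FALSE], c("A", "H", "B")),
                nrow = length(mk))  # 1..3 or NA
    pos <- gmap$position
    M <- length(mk)
    obs <- !is.na(g)
    li <- matrix(0L, M, n)
    li[1, ] <- ifelse(obs[1, ], 1L, 0L)
    if (M > 1) for (j in 2:M) li[j, ] <- ifelse(obs[j, ], j, li[j - 1L, ])
    ri <- matrix(0L, M, n)
    ri[M, ] <- ifelse(obs[M, ], M, 0L)
    if (M > 1) for (j in (M - 1):1) ri[j, ] <- ifelse(obs[j, ], j, ri[j + 1L, ])

    gpos <- sort(unique(c(seq(0, max(pos), by = step), pos)))
    for (p in gpos) {
      j <- findInterval(p, pos)
      L <- if (j >= 1) li[j, ] else rep(0L, n)
      Rt <- if (j < M) ri[j + 1L, ] else rep(0L, n)
      # at an exact marker position the marker itself is its own left flank
      P <- matrix(prior, n, 3, byrow = TRUE)
      key <- paste(L, Rt)
      cache <- new.env(parent = emptyenv())
      for (k in unique(key)) {
        rows <- which(key == k)
        lk <- L[rows[1]]
        rk <- Rt[rows[1]]
        if (lk == 0L && rk == 0L) next
        if (lk > 0L && rk > 0L) {
          r1 <- kosambi_inverse(p - pos[lk])
          r2 <- kosambi_inverse(pos[rk] - p)
          Tt <- cond_table3(r1, r2)
          pv <- Tt[cbind(g[lk, rows], g[rk, rows], rep(1L, length(rows)))]
          block <- cbind(Tt[cbind(g[lk, rows], g[rk, rows], 1L)],
                         Tt[cbind(g[lk, rows], g[rk, rows], 2L)],
                         Tt[cbind(g[lk, rows], g[rk, rows], 3L)])
          nan_rows <- !is.finite(block[, 1])
          if (any(nan_rows)) {  # impossible flank pair: condition on left only
            T2 <- cond_table2(r1)
            block[nan_rows, ] <- T2[g[lk, rows[nan_rows]], , drop = FALSE]
          }
          P[rows, ] <- block
        } else if (lk > 0L) {
          T2 <- cond_table2(kosambi_inverse(p - pos[lk]))
          P[rows, ] <- T2[g[lk, rows], , drop = FALSE]
        } else {
          T2 <- cond_table2(kosambi_inverse(pos[rk] - p))
          P[rows, ] <- T2[g[rk, rows], , drop = FALSE]
        }
      }
      grid_rows[[length(grid_rows) + 1L]] <-
        data.frame(group = grp, position = p,
                   marker = if (p %in% pos) mk[match(p, pos)] else NA_character_,
                   stringsAsFactors = FALSE)
      rownames(P) <- individuals
      colnames(P) <- c("AA", "AB", "BB")
      probs[[length(probs) + 1L]] <- P
    }
  }
  structure(list(grid = do.call(rbind, grid_rows), prob = probs,
                 individuals = individuals),
            class = "genotype_probs")
}

scan_design <- function(gp, i, individuals) {
  P <- gp$prob[[i]][individuals, , drop = FALSE]
  cbind(x = P[, "AA"] - P[, "BB"], z = P[, "AB"])
}

#' Interval mapping scan (Haley-Knott regression)
#'
#' At every grid position, regresses the phenotype on the expected additive
#' score `x = P(AA) - P(BB)` and dominance score `z = P(AB)`;
#' `LOD = (n/2) log10(RSS0 / RSS1)` against the intercept-only model. The
#' additive effect is the `x` coefficient (`(mu_AA - mu_BB)/2`; negative
#' means the seed-parent allele decreases the trait), the dominance effect
#' the `z` coefficient, and R2 the percent RSS reduction.
#'
#' @param map a `genetic_map`.
#' @param genotypes `marker_set` or call matrix.
#' @param phenotype named numeric vector (names = individual ids).
#' @param step grid spacing in cM.
#' @param gp optional precomputed [genotype_probabilities()].
#' @return a `qtl_scan` data frame with columns `group`, `position`, `marker`,
#'   `lod`, `additive`, `dominance`, `r2`, and attributes `n`, `method`.
#' @export
scan_im <- function(map, genotypes, phenotype, step = 1, gp = NULL) {
  prep <- scan_prep(map, genotypes, phenotype, step, gp)
  y <- prep$y
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  if (rss0 <= 0) stop("zero phenotype variance")
  res <- lapply(seq_len(nrow(prep$gp$grid)), function(i) {
    X <- cbind(1, scan_design(prep$gp, i, prep$individuals))
    fit <- stats::lm.fit(X, y)
    rss1 <- sum(fit$residuals^2)
    co <- fit$coefficients
    data.frame(lod = (n / 2) * log10(rss0 / rss1),
               additive = unname(co[2]), dominance = unname(co[3]),
               r2 = 100 * (rss0 - rss1) / rss0)
  })
  out <- cbind(prep$gp$grid, do.call(rbind, res))
  attr(out, "n") <- n
  attr(out, "method") <- "im"
  class(out) <- c("qtl_scan", "data.frame")
  out
}

#' Composite interval mapping scan
#'
#' As [scan_im()], with forward-selected marker cofactors absorbing background
#' QTL variance. Cofactors are chosen once on the observed phenotype (each
#' marker contributes an additive and a dominance column, missing calls mean
#' imputed); at each test position, cofactors within `window` cM on the same
#' group are excluded, and the LOD compares the cofactor model with and
#' without the positional QTL terms.
#'
#' @inheritParams scan_im
#' @param n_cofactors maximum number of marker cofactors.
#' @param window exclusion window around the test position in cM.
#' @return a `qtl_scan` data frame (attribute `cofactors` lists the selected
#'   markers).
#' @export
scan_cim <- function(map, genotypes, phenotype, step = 1, n_cofactors = 5L,
                     window = 10, gp = NULL) {
  prep <- scan_prep(map, genotypes, phenotype, step, gp)
  y <- prep$y
  n <- length(y)
  if (sum((y - mean(y))^2) <= 0) stop("zero phenotype variance")
  cof <- select_cofactors(map, prep$calls, y, prep$individuals, n_cofactors)
  res <- lapply(seq_len(nrow(prep$gp$grid)), function(i) {
    pos <- prep$gp$grid$position[i]
    grp <- prep$gp$grid$group[i]
    use <- !(cof$group == grp & abs(cof$position - pos) <= window)
    X0 <- cbind(1, cof$scores[, rep(use, each = 2), drop = FALSE])
    X1 <- cbind(X0, scan_design(prep$gp, i, prep$individuals))
    fit0 <- stats::lm.fit(X0, y)
    fit1 <- stats::lm.fit(X1, y)
    rss0 <- sum(fit0$residuals^2)
    rss1 <- sum(fit1$residuals^2)
    co <- fit1$coefficients
    k <- length(co)
    data.frame(lod = (n / 2) * log10(rss0 / rss1),
               additive = unname(co[k - 1]), dominance = unname(co[k]),
               r2 = 100 * (rss0 - rss1) / rss0)
  })
  out <- cbind(prep$gp$grid, do.call(rbind, res))
  attr(out, "n") <- n
  attr(out, "method") <- "cim"
  attr(out, "cofactors") <- cof$markers
  class(out) <- c("qtl_scan", "data.frame")
  out
}

scan_prep <- function(map, genotypes, phenotype, step, gp) {
  calls <- get_calls(genotypes)
  phenotype <- phenotype[!is.na(phenotype)]
  individuals <- intersect(colnames(calls), names(phenotype))
  if (length(individuals) < 30) {
    stop("at least 30 phenotyped, genotyped individuals required")
  }
  if (is.null(gp)) gp <- genotype_probabilities(map, calls, step = step)
  list(gp = gp, y = unname(phenotype[individuals]), individuals = individuals,
       calls = calls)
}

# additive/dominance scores of observed marker genotypes, mean-imputed
marker_scores <- function(calls, individuals) {
  g <- t(calls[, individuals, drop = FALSE])
  x <- matrix(NA_real_, nrow(g), ncol(g))
  x[g == "A"] <- 1
  x[g == "H"] <- 0
  x[g == "B"] <- -1
  z <- matrix(NA_real_, nrow(g), ncol(g))
  z[g == "A" | g == "B"] <- 0
  z[g == "H"] <- 1
  impute <- function(m) {
    mu <- colMeans(m, na.rm = TRUE)
    mu[!is.finite(mu)] <- 0
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- mu[idx[, 2]]
    m
  }
  list(x = impute(x), z = impute(z))
}

select_cofactors <- function(map, calls, y, individuals, n_cofactors) {
  mk <- map$marker[map$marker %in% rownames(calls)]
  sc <- marker_scores(calls[mk, , drop = FALSE], individuals)
  chosen <- integer(0)
  X <- matrix(1, length(y), 1)
  rss_cur <- sum(stats::lm.fit(X, y)$residuals^2)
  for (step_i in seq_len(min(n_cofactors, length(mk)))) {
    best <- NULL
    best_rss <- rss_cur - 1e-10
    for (j in setdiff(seq_along(mk), chosen)) {
      Xj <- cbind(X, sc$x[, j], sc$z[, j])
      rss <- sum(stats::lm.fit(Xj, y)$residuals^2)
      if (rss < best_rss) {
        best_rss <- rss
        best <- j
      }
    }
    if (is.null(best)) break
    chosen <- c(chosen, best)
    X <- cbind(X, sc$x[, best], sc$z[, best])
    rss_cur <- best_rss
  }
  scores <- matrix(numeric(0), nrow = length(y), ncol = 0)
  for (j in chosen) scores <- cbind(scores, sc$x[, j], sc$z[, j])
  # column layout: pairs (x, z) per cofactor, in selection order
  scores <- scores[, as.vector(rbind(seq_along(chosen) * 2 - 1,
                                     seq_along(chosen) * 2)), drop = FALSE]
  idx <- match(mk[chosen], map$marker)
  list(markers = mk[chosen], group = map$group[idx],
       position = map$position[idx], scores = scores)
}

#' Genome-wide permutation LOD threshold
#'
#' Permutes the phenotype labels `n_perm` times, rescans the genome for each
#' permutation, and returns the `ceiling((1 - alpha) * n_perm)`-th order
#' statistic of the per-permutation genome-wide maximum LOD. For the CIM
#' method, cofactors are those selected on the observed phenotype and are held
#' fixed across permutations. Deterministic under `seed` and monotone
#' non-increasing in `alpha`.
#'
#' @inheritParams scan_cim
#' @param n_perm number of permutations (at least 20).
#' @param alpha genome-wide significance level.
#' @param method `"im"` or `"cim"`.
#' @param seed integer seed for the permutations.
#' @return list with `threshold`, `max_lods`, `alpha`, `n_perm`.
#' @export
permutation_threshold <- function(map, genotypes, phenotype, n_perm = 1000L,
                                  alpha = 0.05, method = c("im", "cim"),
                                  step = 1, n_cofactors = 5L, window = 10,
                                  seed = 1L, gp = NULL) {
  method <- match.arg(method)
  if (n_perm < 20) stop("refusing to estimate a threshold from fewer than 20 permutations")
  prep <- scan_prep(map, genotypes, phenotype, step, gp)
  y <- prep$y
  n <- length(y)
  set.seed(seed)
  Y <- vapply(seq_len(n_perm), function(i) y[sample.int(n)], numeric(n))
  css <- sum((y - mean(y))^2)
  if (css <= 0) stop("zero phenotype variance")
  sum_y2 <- sum(y^2)
  correction <- sum(y)^2 / n

  cof <- if (method == "cim") {
    select_cofactors(map, prep$calls, y, prep$individuals, n_cofactors)
  } else NULL

  P <- nrow(prep$gp$grid)
  lod <- matrix(NA_real_, P, n_perm)
  for (i in seq_len(P)) {
    XQ <- scan_design(prep$gp, i, prep$individuals)
    if (method == "im") {
      X1 <- cbind(1, XQ)
      rss0 <- css
      Q1 <- thin_q(X1)
      rss1 <- sum_y2 - colSums(crossprod(Q1, Y)^2)
    } else {
      pos <- prep$gp$grid$position[i]
      grp <- prep$gp$grid$group[i]
      use <- !(cof$group == grp & abs(cof$position - pos) <= window)
      X0 <- cbind(1, cof$scores[, rep(use, each = 2), drop = FALSE])
      X1 <- cbind(X0, XQ)
      Q0 <- thin_q(X0)
      Q1 <- thin_q(X1)
      rss0 <- sum_y2 - colSums(crossprod(Q0, Y)^2)
      rss1 <- sum_y2 - colSums(crossprod(Q1, Y)^2)
    }
    lod[i, ] <- (n / 2) * log10(pmax(rss0, 1e-300) / pmax(rss1, 1e-300))
  }
  max_lods <- apply(lod, 2, max)
  list(threshold = lod_threshold(max_lods, alpha), max_lods = max_lods,
       alpha = alpha, n_perm = n_perm)
}

thin_q <- function(X) {
  qx <- qr(X)
  qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
}

#' Threshold from permutation maximum LODs
#'
#' The `ceiling((1 - alpha) * n)`-th order statistic of the genome-wide
#' maximum LODs; `alpha = 0` gives the overall maximum.
#'
#' @param max_lods per-permutation genome-wide maximum LOD scores.
#' @param alpha significance level in `[0, 1)`.
#' @return the LOD threshold.
#' @export
lod_threshold <- function(max_lods, alpha = 0.05) {
  stopifnot(length(max_lods) > 0, alpha >= 0, alpha < 1)
  s <- sort(max_lods)
  s[ceiling((1 - alpha) * length(s))]
}

#' QTL effect estimates at a scan position
#'
#' @param scan a `qtl_scan`.
#' @param group,position the peak location.
#' @return list with `additive` (`(mu_AA - mu_BB)/2`), `dominance`
#'   (`mu_AB - (mu_AA + mu_BB)/2`) and `r2` (percent variance explained).
#' @export
qtl_effects <- function(scan, group, position) {
  i <- which(scan$group == group & abs(scan$position - position) < 1e-9)
  if (length(i) == 0) stop("position not on the scan grid")
  i <- i[1]
  list(additive = scan$additive[i], dominance = scan$dominance[i],
       r2 = scan$r2[i])
}

#' LOD-drop support interval around a peak
#'
#' The widest contiguous region of the peak's linkage group whose LOD stays
#' within `drop` of the peak LOD.
#'
#' @param scan a `qtl_scan`.
#' @param group,position the peak location.
#' @param drop LOD drop defining the interval.
#' @return numeric `c(lo, hi)` in cM.
#' @export
support_interval <- function(scan, group, position, drop = 1.0) {
  g <- scan[scan$group == group, , drop = FALSE]
  g <- g[order(g$position), , drop = FALSE]
  i <- which(abs(g$position - position) < 1e-9)
  if (length(i) == 0) stop("position not on the scan grid")
  i <- i[1]
  cut <- g$lod[i] - drop
  lo <- i
  while (lo > 1 && g$lod[lo - 1] >= cut) lo <- lo - 1
  hi <- i
  while (hi < nrow(g) && g$lod[hi + 1] >= cut) hi <- hi + 1
  c(g$position[lo], g$position[hi])
}

#' Locate QTL peaks above a threshold
#'
#' Greedy peak extraction: repeatedly takes the highest remaining scan
#' position above `threshold`, records it with its effect estimates, support
#' interval and closest flanking markers, and masks positions within
#' `min_sep` cM on the same group.
#'
#' @param scan a `qtl_scan`.
#' @param threshold genome-wide LOD threshold.
#' @param min_sep minimum separation between peaks on one group (cM).
#' @param drop LOD drop for the support interval.
#' @param map optional `genetic_map` for flanking-marker lookup (defaults to
#'   the scan's own marker rows).
#' @return data frame of peaks (`group`, `position`, `lod`, `additive`,
#'   `dominance`, `r2`, `ci_lo`, `ci_hi`, `marker_left`, `marker_right`).
#' @export
find_peaks <- function(scan, threshold, min_sep = 20, drop = 1.0, map = NULL) {
  avail <- scan$lod > threshold
  peaks <- list()
  while (any(avail, na.rm = TRUE)) {
    i <- which(avail)[which.max(scan$lod[avail])]
    ci <- support_interval(scan, scan$group[i], scan$position[i], drop)
    mrow <- scan$group == scan$group[i] & !is.na(scan$marker)
    mpos <- scan$position[mrow]
    mids <- scan$marker[mrow]
    left <- mids[mpos <= scan$position[i]]
    right <- mids[mpos >= scan$position[i]]
    peaks[[length(peaks) + 1L]] <- data.frame(
      group = scan$group[i], position = scan$position[i], lod = scan$lod[i],
      additive = scan$additive[i], dominance = scan$dominance[i],
      r2 = scan$r2[i], ci_lo = ci[1], ci_hi = ci[2],
      marker_left = if (length(left)) left[length(left)] else NA_character_,
      marker_right = if (length(right)) right[1] else NA_character_,
      stringsAsFactors = FALSE)
    avail <- avail & !(scan$group == scan$group[i] &
                         abs(scan$position - scan$position[i]) < min_sep)
  }
  if (length(peaks) == 0) {
    return(data.frame(group = integer(0), position = numeric(0),
                      lod = numeric(0), additive = numeric(0),
                      dominance = numeric(0), r2 = numeric(0),
                      ci_lo = numeric(0), ci_hi = numeric(0),
                      marker_left = character(0), marker_right = character(0)))
  }
  do.call(rbind, peaks)
}
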