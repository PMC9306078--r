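#' Initialize a three-component mixture for one locus
#'
#' Read depths at a co-dominant amplicon locus in an F2 are expected to be
#' trimodal (allele dosage 0/1/2 of the source parent), so the mixture starts
#' from the Mendelian mixing proportions (0.25, 0.50, 0.25) and component
#' locations at 0 and the 50% and 75% quantiles of the counts. For the normal
#' family the starting means are exactly those targets with a common starting
#' sd equal to the sd of the counts. For the gamma family, pre-initial shape
#' and scale are moment-matched (`shape = m^2/s^2`, `scale = s^2/m`) to target
#' means (0, q50, q75) and target sds (sd/3, sd/2, sd/2); the zero-mean
#' component's pre-initials are 0. Offsets of +1.0 (shape) and +0.5 (scale)
#' then give the initial EM values, so the zero-mean component starts at
#' shape 1.0, scale 0.5.
#'
#' @param counts non-negative read counts of one locus (NAs dropped).
#' @param family `"gamma"` or `"normal"`.
#' @param min_counts minimum number of non-missing counts required.
#' @return an object of class `"mixture_init"`; if the counts are degenerate
#'   (zero variance) the locus is flagged `estimable = FALSE`.
#' @export
initialize_mixture <- function(counts, family = c("gamma", "normal"),
                               min_counts = 20L) {
  family <- match.arg(family)
  counts <- counts[!is.na(counts)]
  if (length(counts) < min_counts) {
    stop("at least ", min_counts, " non-missing counts required")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  sd_total <- stats::sd(counts)
  if (!is.finite(sd_total) || sd_total <= 0) {
    return(structure(list(family = family, estimable = FALSE),
                     class = "mixture_init"))
  }
  q50 <- unname(stats::quantile(counts, 0.50))
  q75 <- unname(stats::quantile(counts, 0.75))
  pi <- c(0.25, 0.50, 0.25)
  init <- list(family = family, estimable = TRUE, pi = pi,
               q50 = q50, q75 = q75, sd_total = sd_total)
  if (family == "normal") {
    init$mean <- c(0, q50, q75)
    init$sd <- rep(sd_total, 3)
  } else {
    m <- c(0, q50, q75)
    s <- c(sd_total / 3, sd_total / 2, sd_total / 2)
    pre_shape <- ifelse(m > 0, m^2 / s^2, 0)
    pre_scale <- ifelse(m > 0, s^2 / m, 0)
    init$pre_shape <- pre_shape
    init$pre_scale <- pre_scale
    init$shape <- pre_shape + 1.0
    init$scale <- pre_scale + 0.5
  }
  structure(init, class = "mixture_init")
}

#' Fit a three-component mixture to one locus by EM
#'
#' Alternates posterior responsibilities (E step) and weighted
#' maximum-likelihood parameter updates (M step) until the relative
#' log-likelihood change drops below `tol` or `max_iter` iterations (default
#' 5000) are reached. Under the gamma family, counts are shifted by +0.5
#' before fitting because the gamma density is degenerate at zero; genotype
#' assignment depends only on posteriors, so the shift is never undone.
#' Numerical failure (non-finite likelihood, a mixing proportion below
#' `1/(10 n)`, or component variance underflow) yields a non-converged fit
#' rather than an error, so a per-marker loop never aborts.
#'
#' @param counts non-negative read counts of one locus.
#' @param init a [initialize_mixture()] result (built from `counts` if
#'   omitted).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap.
#' @return an object of class `"mixture_fit"` with elements `family`,
#'   `converged`, `pi`, `params` (per-component data frame incl. the component
#'   mean on the fitted scale), `loglik` (trace), `iterations`, `posteriors`
#'   (n x 3, rows summing to 1), and `shift`.
#' @export
fit_mixture_em <- function(counts, init = NULL, tol = 1e-8, max_iter = 5000L) {
  counts <- counts[!is.na(counts)]
  if (is.null(init)) {
    init <- tryCatch(initialize_mixture(counts, "gamma"), error = function(e) e)
    if (inherits(init, "error")) stop(conditionMessage(init))
  }
  if (!isTRUE(init$estimable)) {
    return(unconverged_fit(init$family, length(counts), "non-estimable counts"))
  }
  family <- init$family
  shift <- if (family == "gamma") 0.5 else 0
  x <- counts + shift
  n <- length(x)
  pi <- init$pi
  if (family == "normal") {
    mu <- init$mean
    sigma <- init$sd
  } else {
    shape <- init$shape
    scale <- init$scale
  }
  trace <- numeric(0)
  converged <- FALSE
  failure <- NULL
  it <- 0L
  ll_old <- -Inf
  post <- NULL
  repeat {
    it <- it + 1L
    dens <- if (family == "normal") {
      vapply(1:3, function(k) stats::dnorm(x, mu[k], sigma[k]), numeric(n))
    } else {
      vapply(1:3, function(k) stats::dgamma(x, shape = shape[k], scale = scale[k]),
             numeric(n))
    }
    wd <- sweep(dens, 2, pi, `*`)
    rs <- rowSums(wd)
    if (any(!is.finite(rs)) || any(rs <= 0)) {
      failure <- "non-finite likelihood"
      break
    }
    post <- wd / rs
    ll <- sum(log(rs))
    trace <- c(trace, ll)
    if (it > 1L && abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    if (it >= max_iter) break
    # M step
    nk <- colSums(post)
    pi_new <- nk / n
    if (any(pi_new < 1 / (10 * n))) {
      failure <- "component collapse"
      break
    }
    if (family == "normal") {
      mu_new <- colSums(post * x) / nk
      var_new <- colSums(post * (x - rep(mu_new, each = n))^2) / nk
      if (any(var_new < 1e-10)) {
        failure <- "variance underflow"
        break
      }
      mu <- mu_new
      sigma <- sqrt(var_new)
    } else {
      ok <- TRUE
      for (k in 1:3) {
        est <- gamma_weighted_mle(x, post[, k])
        if (is.null(est)) {
          ok <- FALSE
          break
        }
        shape[k] <- est$shape
        scale[k] <- est$scale
      }
      if (!ok) {
        failure <- "degenerate gamma component"
        break
      }
    }
    pi <- pi_new
  }
  if (!is.null(failure)) {
    return(unconverged_fit(family, n, failure, iterations = it, loglik = trace))
  }
  if (family == "normal") {
    params <- data.frame(component = 1:3, mean = mu, sd = sigma)
    comp_means <- mu
  } else {
    # report component means on the original count scale (undo the +0.5 shift)
    params <- data.frame(component = 1:3, shape = shape, scale = scale,
                         mean = shape * scale - shift)
    comp_means <- shape * scale - shift
  }
  structure(list(family = family, converged = converged, pi = pi,
                 params = params, component_means = comp_means,
                 loglik = trace, iterations = it, posteriors = post,
                 shift = shift, n = n, failure = NULL),
            class = "mixture_fit")
}

unconverged_fit <- function(family, n, failure, iterations = 0L,
                            loglik = numeric(0)) {
  structure(list(family = family, converged = FALSE, pi = NULL, params = NULL,
                 component_means = NULL, loglik = loglik,
                 iterations = iterations, posteriors = NULL,
                 shift = if (family == "gamma") 0.5 else 0, n = n,
                 failure = failure),
            class = "mixture_fit")
}

# Weighted gamma MLE: solve log(a) - digamma(a) = log(wmean) - wmean(log x)
gamma_weighted_mle <- function(x, w) {
  W <- sum(w)
  if (W <= 0) return(NULL)
  m <- sum(w * x) / W
  lbar <- sum(w * log(x)) / W
  s <- log(m) - lbar
  if (!is.finite(s) || s <= 1e-12) return(NULL)
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:100) {
    f <- log(a) - digamma(a) - s
    fp <- 1 / a - trigamma(a)
    step <- f / fp
    a_new <- a - step
    if (!is.finite(a_new) || a_new <= 0) a_new <- a / 2
    if (abs(a_new - a) < 1e-12 * (a + 1e-12)) {
      a <- a_new
      break
    }
    a <- a_new
  }
  if (!is.finite(a) || a <= 0) return(NULL)
  list(shape = a, scale = m / a)
}

#' Posterior responsibilities for new counts under a fitted mixture
#'
#' @param fit a converged [fit_mixture_em()] result.
#' @param counts new non-negative counts (the gamma shift is applied
#'   automatically).
#' @return matrix `length(counts)` x 3 of posterior probabilities.
#' @export
predict_mixture <- function(fit, counts) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (!fit$converged) stop("mixture fit did not converge")
  x <- counts + fit$shift
  dens <- if (fit$family == "normal") {
    vapply(1:3, function(k) stats::dnorm(x, fit$params$mean[k], fit$params$sd[k]),
           numeric(length(x)))
  } else {
    vapply(1:3, function(k) stats::dgamma(x, shape = fit$params$shape[k],
                                          scale = fit$params$scale[k]),
           numeric(length(x)))
  }
  dens <- matrix(dens, ncol = 3)
  wd <- sweep(dens, 2, fit$pi, `*`)
  rs <- rowSums(wd)
  out <- wd / rs
  out[rs <= 0 | !is.finite(rs), ] <- NA_real_
  out
}

#' Assign genotype calls from a fitted mixture
#'
#' Components are ordered by fitted mean: the lowest-mean component is the
#' homozygote lacking the source parent's amplicon allele, the middle is the
#' heterozygote and the highest carries two copies. Each observation receives
#' the maximum-posterior code; posterior ties (within `tie_tol`) are set to
#' missing rather than broken arbitrarily, to avoid injecting phantom
#' recombinations into the map. Calls use A = seed-parent homozygote,
#' H = heterozygote, B = pollen-parent homozygote.
#'
#' @param fit a converged [fit_mixture_em()] result.
#' @param source_parent 1 if the marker's amplicon tracks the seed parent (A),
#'   2 if the pollen parent (B).
#' @param posteriors optional posterior matrix (e.g. from
#'   [predict_mixture()]); defaults to the fit's own.
#' @param tie_tol posterior difference below which the top two components are
#'   declared tied.
#' @return character vector of calls in `{"A", "H", "B", NA}`.
#' @export
assign_genotypes <- function(fit, source_parent = 1L, posteriors = NULL,
                             tie_tol = 1e-9) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (!fit$converged) stop("mixture fit did not converge")
  stopifnot(source_parent %in% c(1L, 2L))
  post <- if (is.null(posteriors)) fit$posteriors else posteriors
  ord <- order(fit$component_means)
  dosage_of_comp <- integer(3)
  dosage_of_comp[ord] <- 0:2
  calls <- character(nrow(post))
  for (i in seq_len(nrow(post))) {
    p <- post[i, ]
    if (any(is.na(p))) {
      calls[i] <- NA_character_
      next
    }
    o <- order(p, decreasing = TRUE)
    if (p[o[1]] - p[o[2]] <= tie_tol) {
      calls[i] <- NA_character_
      next
    }
    dosage <- dosage_of_comp[o[1]]
    g <- if (source_parent == 1L) 2L - dosage else dosage  # B-allele count
    calls[i] <- c("A", "H", "B")[g + 1L]
  }
  calls
}

#' Call co-dominant genotypes for every marker in a depth matrix
#'
#' Fits the per-locus three-component mixture independently at each marker
#' (the loop is order-independent by contract), infers the source parent from
#' the parent read counts (the parent with the larger count carries the
#' amplicon), assigns maximum-posterior genotypes, calls both parents through
#' the same fit and flags markers whose parents are not called as the
#' expected AA / BB homozygotes. Markers whose EM did not converge are
#' removed, as are loci with degenerate counts.
#'
#' @param depths a `depth_matrix` (see [simulate_read_depths()] or
#'   [read_depth_matrix()]).
#' @param family `"gamma"` or `"normal"`.
#' @param tol,max_iter EM settings, see [fit_mixture_em()].
#' @param individual_scale optional per-individual depth normalization
#'   factors; counts are divided by them before fitting (default: none).
#' @return a [marker_set] of the converged markers, with `parental_ok` flags
#'   and an attribute `"fits"` (per-marker parameter data frame).
#' @export
call_codominant <- function(depths, family = c("gamma", "normal"),
                            tol = 1e-8, max_iter = 5000L,
                            individual_scale = NULL) {
  family <- match.arg(family)
  stopifnot(inherits(depths, "depth_matrix"))
  counts <- depths$counts
  if (!is.null(individual_scale)) {
    stopifnot(length(individual_scale) == ncol(counts),
              all(individual_scale > 0))
    counts <- sweep(counts, 2, individual_scale, `/`)
  }
  M <- nrow(counts)
  calls <- matrix(NA_character_, M, ncol(counts), dimnames = dimnames(counts))
  converged <- logical(M)
  parental_ok <- logical(M)
  source_parent <- integer(M)
  fit_rows <- vector("list", M)
  for (m in seq_len(M)) {
    cm <- counts[m, ]
    init <- tryCatch(initialize_mixture(cm, family), error = function(e) NULL)
    if (is.null(init)) next
    fit <- fit_mixture_em(cm, init, tol = tol, max_iter = max_iter)
    converged[m] <- fit$converged
    if (!fit$converged) next
    sp <- if (depths$parent1_counts[m] >= depths$parent2_counts[m]) 1L else 2L
    source_parent[m] <- sp
    calls[m, ] <- assign_genotypes(fit, sp)
    ppost <- predict_mixture(fit, c(depths$parent1_counts[m],
                                    depths$parent2_counts[m]))
    pcalls <- assign_genotypes(fit, sp, posteriors = ppost)
    parental_ok[m] <- !is.na(pcalls[1]) && !is.na(pcalls[2]) &&
      pcalls[1] == "A" && pcalls[2] == "B"
    fit_rows[[m]] <- cbind(data.frame(marker = rownames(counts)[m],
                                      iterations = fit$iterations,
                                      loglik = trailing(fit$loglik)),
                           mixture_param_row(fit))
  }
  keep <- which(converged)
  ms <- marker_set(calls[keep, , drop = FALSE], source = family,
                   source_parent = source_parent[keep])
  ms$info$parental_ok <- parental_ok[keep]
  ms$info$converged <- TRUE
  ms$history <- rbind(ms$history,
                      data.frame(step = "em_convergence", n_before = M,
                                 n_removed = M - length(keep),
                                 n_after = length(keep),
                                 stringsAsFactors = FALSE))
  attr(ms, "fits") <- do.call(rbind, fit_rows[keep])
  ms
}

trailing <- function(x) if (length(x)) x[length(x)] else NA_real_

mixture_param_row <- function(fit) {
  p <- fit$params
  if (fit$family == "normal") {
    data.frame(pi1 = fit$pi[1], pi2 = fit$pi[2], pi3 = fit$pi[3],
               mean1 = p$mean[1], mean2 = p$mean[2], mean3 = p$mean[3],
               sd1 = p$sd[1], sd2 = p$sd[2], sd3 = p$sd[3])
  } else {
    data.frame(pi1 = fit$pi[1], pi2 = fit$pi[2], pi3 = fit$pi[3],
               shape1 = p$shape[1], shape2 = p$shape[2], shape3 = p$shape[3],
               scale1 = p$scale[1], scale2 = p$scale[2], scale3 = p$scale[3])
  }
}
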