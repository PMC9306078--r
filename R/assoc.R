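#' Tukey-Kramer all-pairs comparisons
#'
#' All pairwise mean comparisons with studentized-range adjustment, valid for
#' unequal group sizes. The statistic depends on the data only through the
#' group sizes, means and the pooled within-group variance
#' `MSW = sum((n_k - 1) s_k^2) / (N - K)`, so the function accepts either raw
#' observations (`values` + `groups`) or printed summary triplets (`n`,
#' `mean`, `sd`) and gives identical results for matched inputs:
#' `q_ij = |m_i - m_j| / sqrt((MSW/2)(1/n_i + 1/n_j))`, with the adjusted P
#' from the studentized-range distribution with K groups and N - K df.
#'
#' @param values raw observations (omit when using summaries).
#' @param groups group labels parallel to `values`.
#' @param n,mean,sd per-group summary statistics (named vectors; omit when
#'   using raw data).
#' @return data frame of pairwise contrasts: `group_i`, `group_j`, `diff`
#'   (`mean_j - mean_i`), `se`, `q`, `p_adj`, `stars` (significance at
#'   0.05/0.01/0.001). If the pooled variance is zero, P is 0 for unequal
#'   means and `NA` for equal means, with attribute `degenerate = TRUE`.
#' @examples
#' tukey_kramer(n = c(AA = 44, AB = 52, BB = 35),
#'              mean = c(79.5, 82.2, 86.9),
#'              sd = c(6.5, 8.9, 11.4))
#' @export
tukey_kramer <- function(values = NULL, groups = NULL, n = NULL, mean = NULL,
                         sd = NULL) {
  if (!is.null(values)) {
    stopifnot(!is.null(groups), length(values) == length(groups))
    ok <- !is.na(values) & !is.na(groups)
    values <- values[ok]
    groups <- as.character(groups[ok])
    labs <- sort(unique(groups))  # deterministic contrast order
    n <- vapply(labs, function(g) sum(groups == g), 0)
    mean <- vapply(labs, function(g) base::mean(values[groups == g]), 0)
    sd <- vapply(labs, function(g) stats::sd(values[groups == g]), 0)
  } else {
    stopifnot(!is.null(n), !is.null(mean), !is.null(sd),
              length(n) == length(mean), length(mean) == length(sd))
    labs <- names(n)
    if (is.null(labs)) labs <- paste0("g", seq_along(n))
  }
  if (length(labs) < 2) stop("at least 2 groups required")
  if (any(n < 2)) stop("every group needs n >= 2")
  K <- length(labs)
  N <- sum(n)
  df <- N - K
  msw <- sum((n - 1) * sd^2) / df
  pairs <- utils::combn(K, 2)
  degenerate <- msw <= 0
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    diff <- mean[j] - mean[i]
    se <- sqrt((msw / 2) * (1 / n[i] + 1 / n[j]))
    if (degenerate) {
      p <- if (abs(diff) == 0) NA_real_ else 0
      q <- if (abs(diff) == 0) NA_real_ else Inf
    } else {
      q <- abs(diff) / se
      p <- stats::ptukey(q, nmeans = K, df = df, lower.tail = FALSE)
    }
    data.frame(group_i = labs[i], group_j = labs[j], diff = unname(diff),
               se = unname(se), q = unname(q), p_adj = unname(p),
               stars = p_stars(p), stringsAsFactors = FALSE)
  }))
  attr(out, "msw") <- msw
  attr(out, "df") <- df
  attr(out, "degenerate") <- degenerate
  out
}

p_stars <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' Genotype-class summary of a trait at one marker
#'
#' Per genotype class (AA, AB, BB): plant count, trait mean and sample
#' standard deviation (n - 1 denominator), plus all Tukey-Kramer pairwise
#' contrasts. Individuals with missing genotype are excluded; right-censored
#' individuals are excluded by default (`censor_policy = "exclude"`) or kept
#' at their truncated value (`"include"`).
#'
#' @param genotype named character vector of calls (A/H/B, `NA` missing) at
#'   the marker.
#' @param phenotype named numeric trait values (days after sowing).
#' @param censored optional named logical censoring flags.
#' @param censor_policy `"exclude"` or `"include"`.
#' @return object of class `"class_summary"`: list with `classes` (data frame
#'   `class`, `n`, `mean`, `sd`), `contrasts` (see [tukey_kramer()]), and
#'   `n_total`.
#' @export
class_summary <- function(genotype, phenotype, censored = NULL,
                          censor_policy = c("exclude", "include")) {
  censor_policy <- match.arg(censor_policy)
  ids <- intersect(names(genotype), names(phenotype))
  g <- genotype[ids]
  y <- phenotype[ids]
  keep <- !is.na(g) & !is.na(y) & g %in% c("A", "H", "B")
  if (!is.null(censored) && censor_policy == "exclude") {
    keep <- keep & !censored[ids]
  }
  g <- g[keep]
  y <- y[keep]
  lab <- c(A = "AA", H = "AB", B = "BB")[g]
  classes <- data.frame(class = c("AA", "AB", "BB"),
                        n = vapply(c("AA", "AB", "BB"),
                                   function(cl) sum(lab == cl), 0L),
                        mean = vapply(c("AA", "AB", "BB"), function(cl) {
                          if (any(lab == cl)) mean(y[lab == cl]) else NA_real_
                        }, 0),
                        sd = vapply(c("AA", "AB", "BB"), function(cl) {
                          if (sum(lab == cl) > 1) stats::sd(y[lab == cl]) else NA_real_
                        }, 0),
                        stringsAsFactors = FALSE)
  rownames(classes) <- NULL
  nonempty <- classes$class[classes$n >= 2]
  if (length(nonempty) < 2) stop("at least 2 genotype classes with n >= 2 required")
  contrasts <- tukey_kramer(values = y, groups = lab)
  structure(list(classes = classes, contrasts = contrasts,
                 n_total = length(y)),
            class = "class_summary")
}

#' @export
print.class_summary <- function(x, ...) {
  cat("trait by genotype class (n =", x$n_total, "analyzed)\n")
  print(x$classes, row.names = FALSE)
  cat("\nTukey-Kramer contrasts:\n")
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}

#' Difference between two genotype-class means
#'
#' @param summary a [class_summary()] result.
#' @param class_a,class_b class labels ("AA", "AB", "BB").
#' @param digits rounding of the reported difference (default 1 decimal, the
#'   convention for DAS summaries).
#' @return `mean(class_b) - mean(class_a)` in trait units.
#' @export
class_mean_difference <- function(summary, class_a, class_b, digits = 1) {
  stopifnot(inherits(summary, "class_summary"))
  cl <- summary$classes
  ma <- cl$mean[cl$class == class_a]
  mb <- cl$mean[cl$class == class_b]
  if (length(ma) != 1 || length(mb) != 1 || is.na(ma) || is.na(mb)) {
    stop("undefined: empty genotype class")
  }
  round(mb - ma, digits)
}

#' Pearson correlation between flowering and maturity time
#'
#' @param flowering,maturity numeric vectors over the same individuals.
#' @param censored optional logical censoring flags for maturity.
#' @param censor_policy `"exclude"` drops censored individuals (default);
#'   `"include"` keeps them at the truncated end-day value.
#' @return Pearson correlation coefficient (`NA` with a warning if either
#'   trait has zero variance).
#' @export
phenotype_correlation <- function(flowering, maturity, censored = NULL,
                                  censor_policy = c("exclude", "include")) {
  censor_policy <- match.arg(censor_policy)
  stopifnot(length(flowering) == length(maturity))
  keep <- !is.na(flowering) & !is.na(maturity)
  if (!is.null(censored) && censor_policy == "exclude") keep <- keep & !censored
  x <- flowering[keep]
  y <- maturity[keep]
  if (length(x) < 3) stop("at least 3 complete pairs required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}
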