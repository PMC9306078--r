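# Two-locus F2 probability machinery ----------------------------------------
#
# Observation categories over the 3 underlying genotypes (0/1/2 B alleles):
#   A = {0}, H = {1}, B = {2}, C = {1,2} (dominant, not-AA), D = {0,1} (not-BB)
# A category partitions the genotype space per marker, so the likelihood of a
# category pair is the sum of the corresponding cells of the two-locus
# genotype table. Individuals are two independent gametes; coupling-phase F1
# gamete haplotypes over two loci have frequencies
# ((1-r)/2, r/2, r/2, (1-r)/2).

.cat_codes <- c(A = 1L, H = 2L, B = 3L, C = 4L, D = 5L)
.cat_sets <- list(1L, 2L, 3L, c(2L, 3L), c(1L, 2L))

.f2_tables <- local({
  hap <- cbind(aL = c(0L, 0L, 1L, 1L), aR = c(0L, 1L, 0L, 1L))
  A9 <- matrix(0, 9, 16)
  for (i in 1:4) {
    for (j in 1:4) {
      gL <- hap[i, 1] + hap[j, 1]
      gR <- hap[i, 2] + hap[j, 2]
      cell <- gL * 3L + gR + 1L
      A9[cell, (i - 1L) * 4L + j] <- A9[cell, (i - 1L) * 4L + j] + 1
    }
  }
  C25 <- matrix(0, 25, 9)
  for (a in 1:5) {
    for (b in 1:5) {
      for (g1 in .cat_sets[[a]]) {
        for (g2 in .cat_sets[[b]]) {
          C25[(a - 1L) * 5L + b, (g1 - 1L) * 3L + g2] <- 1
        }
      }
    }
  }
  list(A9 = A9, C25 = C25)
})

# two-locus genotype table as a length-9 vector (row-major in gL)
f2_joint9 <- function(r) {
  w <- c((1 - r) / 2, r / 2, r / 2, (1 - r) / 2)
  as.vector(.f2_tables$A9 %*% as.vector(outer(w, w)))
}

encode_categories <- function(codes) {
  idx <- .cat_codes[codes]
  idx[is.na(codes)] <- NA_integer_
  unname(idx)
}

pair_loglik <- function(n25, r) {
  p25 <- as.vector(.f2_tables$C25 %*% f2_joint9(r))
  obs <- n25 > 0
  sum(n25[obs] * log(p25[obs]))
}

pair_counts <- function(c1, c2) {
  ok <- !is.na(c1) & !is.na(c2)
  tabulate((c1[ok] - 1L) * 5L + c2[ok], nbins = 25L)
}

mle_r_from_counts <- function(n25) {
  ll <- function(r) pair_loglik(n25, r)
  opt <- stats::optimize(ll, c(1e-9, 0.5 - 1e-9), maximum = TRUE)
  ll_half <- ll(0.5)
  r_hat <- opt$maximum
  ll_hat <- opt$objective
  if (ll_half >= ll_hat) {
    r_hat <- 0.5
    ll_hat <- ll_half
  }
  ll_zero <- ll(0)  # -Inf as soon as any recombinant class is observed
  if (is.finite(ll_zero) && ll_zero >= ll_hat) {
    r_hat <- 0
    ll_hat <- ll_zero
  }
  if (r_hat < 1e-6) r_hat <- 0
  lod <- max(0, (ll_hat - ll_half) / log(10))
  list(r = r_hat, lod = lod)
}

#' Maximum-likelihood recombination fraction between two F2 markers
#'
#' Computes the ML estimate of the recombination fraction `r` under the F2
#' intercross model (coupling phase, the ambiguous double-heterozygote class
#' handled exactly through the category likelihood), clipped to `[0, 0.5]`,
#' together with the linkage LOD = log10 likelihood ratio against `r = 0.5`.
#' Dominant observations (codes "C" = not-AA, "D" = not-BB) are supported.
#'
#' @param g1,g2 character call vectors over the same individuals (codes A, H,
#'   B, C, D or `NA`).
#' @return list with `r`, `lod`, and `n` (jointly non-missing individuals).
#' @export
estimate_recombination <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  c1 <- encode_categories(g1)
  c2 <- encode_categories(g2)
  n25 <- pair_counts(c1, c2)
  n_obs <- sum(n25)
  if (n_obs < 2) stop("undefined pair: fewer than 2 jointly non-missing individuals")
  est <- mle_r_from_counts(n25)
  list(r = est$r, lod = est$lod, n = n_obs)
}

#' All pairwise recombination fractions and linkage LODs
#'
#' Category pair counts are accumulated with indicator cross-products, then
#' each pair's `r` is estimated by maximum likelihood as in
#' [estimate_recombination()].
#'
#' @param x a `marker_set` or call matrix.
#' @return object of class `"pairwise_linkage"`: list with `markers`, symmetric
#'   matrices `r` and `lod`, and `n` (jointly observed counts).
#' @export
pairwise_linkage <- function(x) {
  calls <- get_calls(x)
  M <- nrow(calls)
  if (M < 2) stop("at least two markers required")
  codes <- matrix(encode_categories(calls), nrow = M, dimnames = dimnames(calls))
  present <- sort(unique(as.vector(codes[!is.na(codes)])))
  ind <- lapply(present, function(k) {
    I <- t(codes == k)  # individuals x markers
    I[is.na(I)] <- FALSE
    storage.mode(I) <- "double"
    I
  })
  names(ind) <- as.character(present)
  N <- list()
  for (a in seq_along(present)) {
    for (b in seq_along(present)) {
      N[[paste(present[a], present[b])]] <- crossprod(ind[[a]], ind[[b]])
    }
  }
  r_mat <- matrix(NA_real_, M, M, dimnames = list(rownames(calls), rownames(calls)))
  lod_mat <- r_mat
  n_mat <- matrix(0L, M, M, dimnames = dimnames(r_mat))
  diag(r_mat) <- 0
  diag(lod_mat) <- Inf
  for (i in seq_len(M - 1)) {
    for (j in (i + 1):M) {
      n25 <- numeric(25)
      for (a in present) {
        for (b in present) {
          n25[(a - 1L) * 5L + b] <- N[[paste(a, b)]][i, j]
        }
      }
      n_obs <- sum(n25)
      n_mat[i, j] <- n_mat[j, i] <- n_obs
      if (n_obs < 2) next
      est <- mle_r_from_counts(n25)
      r_mat[i, j] <- r_mat[j, i] <- est$r
      lod_mat[i, j] <- lod_mat[j, i] <- est$lod
    }
  }
  structure(list(markers = rownames(calls), r = r_mat, lod = lod_mat, n = n_mat),
            class = "pairwise_linkage")
}

#' Partition markers into linkage groups
#'
#' Single-linkage transitive closure over marker pairs with `r <= r_max` and
#' `LOD >= lod_min`. Groups are returned largest first.
#'
#' @param pairwise a [pairwise_linkage()] result.
#' @param r_max maximum recombination fraction for a linking edge.
#' @param lod_min minimum linkage LOD for a linking edge.
#' @return list of character vectors of marker ids.
#' @export
group_markers <- function(pairwise, r_max = 0.35, lod_min = 3) {
  stopifnot(inherits(pairwise, "pairwise_linkage"))
  M <- length(pairwise$markers)
  adj <- !is.na(pairwise$r) & pairwise$r <= r_max & pairwise$lod >= lod_min
  diag(adj) <- FALSE
  comp <- integer(M)
  cur <- 0L
  for (s in seq_len(M)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  groups <- split(pairwise$markers, comp)
  groups <- groups[order(-vapply(groups, length, 0L),
                         vapply(groups, function(g) g[1], ""))]
  unname(groups)
}

#' Order the markers of one linkage group
#'
#' Finds the marker order minimizing the sum of adjacent recombination
#' fractions: greedy nearest-neighbour seriation from a random start followed
#' by 2-opt refinement, restarted `runs` times with different seeds, best
#' solution kept. The result is invariant to the input order of `markers`
#' (ids are sorted before seeding) and oriented canonically so that the first
#' marker id is lexicographically no greater than the last. Positions are
#' cumulative Kosambi distances of the adjacent recombination estimates.
#'
#' @param pairwise a [pairwise_linkage()] result covering the group.
#' @param markers marker ids of the group (default: all in `pairwise`).
#' @param runs number of random restarts.
#' @param seed integer seed for the restarts.
#' @return data frame with columns `marker`, `position` (cM, starting at 0)
#'   and attribute `"objective"` (sum of adjacent r).
#' @export
order_markers <- function(pairwise, markers = pairwise$markers, runs = 50L,
                          seed = 1L) {
  stopifnot(inherits(pairwise, "pairwise_linkage"))
  markers <- sort(markers)
  m <- length(markers)
  if (m < 2) stop("a group must contain at least 2 markers")
  R <- pairwise$r[markers, markers, drop = FALSE]
  R[is.na(R)] <- 0.5
  if (m == 2) {
    best_path <- 1:2
  } else {
    obj <- function(p) sum(R[cbind(p[-m], p[-1])])
    set.seed(seed)
    starts <- sample.int(m, runs, replace = TRUE)
    best_path <- NULL
    best_obj <- Inf
    for (s in starts) {
      path <- greedy_path(R, s)
      path <- two_opt(R, path)
      o <- obj(path)
      if (o < best_obj - 1e-12) {
        best_obj <- o
        best_path <- path
      }
    }
  }
  ordered <- markers[best_path]
  if (ordered[1] > ordered[length(ordered)]) ordered <- rev(ordered)
  r_adj <- R[cbind(match(ordered[-m], markers), match(ordered[-1], markers))]
  d <- kosambi_distance(pmin(r_adj, 0.5 - 1e-9))
  out <- data.frame(marker = ordered, position = c(0, cumsum(d)),
                    stringsAsFactors = FALSE)
  attr(out, "objective") <- sum(r_adj)
  out
}

greedy_path <- function(R, start) {
  m <- nrow(R)
  path <- start
  left <- setdiff(seq_len(m), start)
  while (length(left)) {
    tail_r <- R[path[length(path)], left]
    head_r <- R[path[1], left]
    if (min(tail_r) <= min(head_r)) {
      k <- left[which.min(tail_r)]
      path <- c(path, k)
    } else {
      k <- left[which.min(head_r)]
      path <- c(k, path)
    }
    left <- setdiff(left, k)
  }
  path
}

# 2-opt on a path: reversing p[i..j] replaces edges (i-1,i) and (j,j+1);
# the adjacent-r objective never increases across iterations
two_opt <- function(R, path) {
  m <- length(path)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in 1:(m - 1)) {
      for (j in i:(m - 1)) {
        a <- if (i > 1) R[path[i - 1], path[i]] else 0
        b <- if (j < m) R[path[j], path[j + 1]] else 0
        a2 <- if (i > 1) R[path[i - 1], path[j]] else 0
        b2 <- if (j < m) R[path[i], path[j + 1]] else 0
        if (a2 + b2 < a + b - 1e-12) {
          path[i:j] <- rev(path[i:j])
          improved <- TRUE
        }
      }
    }
  }
  path
}

#' Construct a genetic linkage map from co-dominant calls
#'
#' Runs [pairwise_linkage()], [group_markers()] and [order_markers()] and
#' assembles a `genetic_map` data frame (columns `group`, `marker`,
#' `position`). Groups are numbered largest first; singleton groups are not
#' placed on the map and are recorded in the `"unplaced"` attribute.
#'
#' @param x a `marker_set` or call matrix.
#' @param r_max,lod_min grouping thresholds, see [group_markers()].
#' @param runs,seed ordering restarts, see [order_markers()].
#' @return a `genetic_map` data frame.
#' @export
build_genetic_map <- function(x, r_max = 0.35, lod_min = 3, runs = 50L,
                              seed = 1L) {
  pl <- pairwise_linkage(x)
  groups <- group_markers(pl, r_max = r_max, lod_min = lod_min)
  placed <- Filter(function(g) length(g) >= 2, groups)
  unplaced <- unlist(Filter(function(g) length(g) < 2, groups))
  maps <- lapply(seq_along(placed), function(k) {
    ord <- order_markers(pl, placed[[k]], runs = runs, seed = seed + k)
    data.frame(group = k, marker = ord$marker, position = ord$position,
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, maps)
  class(map) <- c("genetic_map", "data.frame")
  attr(map, "unplaced") <- unplaced
  map
}

#' Remove markers beyond oversized map gaps
#'
#' If the distance between two adjacent markers exceeds `max_gap` cM, the
#' gap-adjacent marker on the smaller side of the split is removed; because
#' positions are cumulative distances, removal merges the two flanking gaps by
#' summation. The rule is re-applied until no gap exceeds `max_gap`
#' (idempotent afterwards); group positions are re-based to start at 0.
#'
#' @param map a `genetic_map`.
#' @param max_gap maximum tolerated adjacent gap in cM.
#' @return the filtered `genetic_map`, with a `"removed"` attribute listing
#'   dropped markers.
#' @export
gap_filter <- function(map, max_gap = 20) {
  stopifnot(inherits(map, "genetic_map"))
  removed <- character(0)
  out <- lapply(split(seq_len(nrow(map)), map$group), function(idx) {
    g <- map[idx, , drop = FALSE]
    g <- g[order(g$position), , drop = FALSE]
    repeat {
      m <- nrow(g)
      if (m < 2) break
      gaps <- diff(g$position)
      bad <- which(gaps > max_gap)
      if (length(bad) == 0) break
      k <- bad[1]
      drop_idx <- if (k < m - k) k else k + 1L  # smaller block's gap-side marker
      removed <<- c(removed, g$marker[drop_idx])
      g <- g[-drop_idx, , drop = FALSE]
    }
    g$position <- g$position - g$position[1]
    g
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("genetic_map", "data.frame")
  attr(res, "removed") <- removed
  res
}

#' Summarize a genetic map
#'
#' Reports group count, usable marker count N, total map length L (sum of
#' group lengths, i.e. of last positions), and the average marker distance
#' L / N.
#'
#' @param map a `genetic_map`.
#' @return list with `n_groups`, `n_markers`, `total_length`,
#'   `average_distance`, and `per_group` (data frame).
#' @export
summarize_map <- function(map) {
  stopifnot(inherits(map, "genetic_map"), nrow(map) > 0)
  per_group <- do.call(rbind, lapply(split(map, map$group), function(g) {
    data.frame(group = g$group[1], n_markers = nrow(g),
               length = max(g$position), stringsAsFactors = FALSE)
  }))
  rownames(per_group) <- NULL
  L <- sum(per_group$length)
  N <- nrow(map)
  list(n_groups = nrow(per_group), n_markers = N, total_length = L,
       average_distance = L / N, per_group = per_group)
}

#' Bridge two maps through shared marker ids
#'
#' For every shared marker, reports its group and position in both maps, the
#' inferred group correspondence (greedy maximum matching on shared-marker
#' counts), and how many shared markers map to an inconsistent group pair.
#'
#' @param map_a,map_b `genetic_map` objects.
#' @param shared marker ids to bridge on (default: ids present in both maps).
#' @return list with `bridge` (per-marker data frame), `correspondence`
#'   (matched group pairs with shared counts) and `n_inconsistent`.
#' @export
bridge_maps <- function(map_a, map_b, shared = NULL) {
  if (is.null(shared)) shared <- intersect(map_a$marker, map_b$marker)
  if (length(shared) == 0) {
    return(list(bridge = data.frame(marker = character(0), group_a = integer(0),
                                    position_a = numeric(0), group_b = integer(0),
                                    position_b = numeric(0)),
                correspondence = data.frame(group_a = integer(0),
                                            group_b = integer(0),
                                            n_shared = integer(0)),
                n_inconsistent = 0L))
  }
  ia <- match(shared, map_a$marker)
  ib <- match(shared, map_b$marker)
  bridge <- data.frame(marker = shared,
                       group_a = map_a$group[ia], position_a = map_a$position[ia],
                       group_b = map_b$group[ib], position_b = map_b$position[ib],
                       stringsAsFactors = FALSE)
  tab <- table(bridge$group_a, bridge$group_b)
  pairs <- list()
  t2 <- tab
  while (any(t2 > 0)) {
    k <- which(t2 == max(t2), arr.ind = TRUE)[1, ]
    pairs[[length(pairs) + 1L]] <-
      data.frame(group_a = as.integer(rownames(t2)[k[1]]),
                 group_b = as.integer(colnames(t2)[k[2]]),
                 n_shared = as.integer(t2[k[1], k[2]]))
    t2[k[1], ] <- 0L
    t2[, k[2]] <- 0L
  }
  correspondence <- do.call(rbind, pairs)
  ok <- paste(bridge$group_a, bridge$group_b) %in%
    paste(correspondence$group_a, correspondence$group_b)
  list(bridge = bridge, correspondence = correspondence,
       n_inconsistent = sum(!ok))
}

# Marker QC ------------------------------------------------------------------

#' Collapse duplicate markers
#'
#' Markers are partitioned into classes whose non-missing calls never conflict
#' (missing-tolerant identity); within each class the marker with the fewest
#' missing values is kept, ties broken by marker id. Scanning order is by
#' sorted id, so the result is deterministic.
#'
#' @param ms a `marker_set`.
#' @return the collapsed `marker_set`.
#' @export
collapse_duplicate_markers <- function(ms) {
  stopifnot(inherits(ms, "marker_set"))
  calls <- ms$calls
  ids <- sort(rownames(calls))
  classes <- list()
  for (id in ids) {
    v <- calls[id, ]
    placed <- FALSE
    for (k in seq_along(classes)) {
      members <- classes[[k]]
      compatible <- all(vapply(members, function(m) {
        w <- calls[m, ]
        !any(v != w, na.rm = TRUE)
      }, logical(1)))
      if (compatible) {
        classes[[k]] <- c(members, id)
        placed <- TRUE
        break
      }
    }
    if (!placed) classes[[length(classes) + 1L]] <- id
  }
  keep <- vapply(classes, function(members) {
    miss <- vapply(members, function(m) sum(is.na(calls[m, ])), 0L)
    members[order(miss, members)][1]
  }, "")
  ms_keep(ms, keep, "collapse_duplicates")
}

#' Chi-square segregation-distortion P value
#'
#' Goodness-of-fit of observed genotype class counts against an expected
#' Mendelian ratio, df = classes - 1, no continuity correction.
#'
#' @param counts observed class counts.
#' @param ratio expected ratio (normalized internally), same length.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
distortion_test <- function(counts, ratio = c(1, 2, 1)) {
  stopifnot(length(counts) == length(ratio), all(counts >= 0), sum(counts) > 0)
  p <- ratio / sum(ratio)
  e <- sum(counts) * p
  x2 <- sum((counts - e)^2 / e)
  df <- length(counts) - 1L
  list(statistic = x2, df = df,
       p_value = stats::pchisq(x2, df, lower.tail = FALSE))
}

#' Filter markers by segregation distortion
#'
#' Tests each marker's non-missing genotype counts against its Mendelian
#' expectation (1:2:1 for co-dominant markers over A/H/B; 3:1 for dominant
#' markers over carrier/recessive classes) and removes markers with
#' `P < alpha`. Markers with fewer than `min_calls` non-missing calls are
#' removed with that reason. P values are recorded on the set.
#'
#' @param ms a `marker_set`.
#' @param alpha removal threshold on the chi-square P value.
#' @param min_calls minimum non-missing calls for a testable marker.
#' @return the filtered `marker_set`.
#' @export
segregation_distortion_filter <- function(ms, alpha = 0.001, min_calls = 20L) {
  stopifnot(inherits(ms, "marker_set"))
  calls <- ms$calls
  p_values <- rep(NA_real_, nrow(calls))
  keep <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    v <- calls[i, ]
    v <- v[!is.na(v)]
    if (length(v) < min_calls) next
    if (ms$info$type[i] == "dominant") {
      carrier <- sum(v %in% c("C", "D"))
      counts <- c(carrier, length(v) - carrier)
      ratio <- c(3, 1)
    } else {
      counts <- c(sum(v == "A"), sum(v == "H"), sum(v == "B"))
      ratio <- c(1, 2, 1)
    }
    res <- distortion_test(counts, ratio)
    p_values[i] <- res$p_value
    keep[i] <- res$p_value >= alpha
  }
  ms$info$distortion_p <- p_values
  ms_keep(ms, rownames(calls)[keep],
          sprintf("segregation_distortion_filter(alpha=%g)", alpha))
}
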