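#' Marker set: co-dominant calls with provenance, QC flags and filter history
#'
#' A `marker_set` holds a marker x individual call matrix (codes `"A"`, `"H"`,
#' `"B"` for co-dominant genotypes, `"C"` = not-AA and `"D"` = not-BB for
#' dominant observations, `NA` for missing), a per-marker info table
#' (provenance, source parent, consensus with the default dominant caller,
#' parental-consistency flag, segregation-distortion P value), and an
#' append-only history of filtering steps with marker counts.
#'
#' @param calls character matrix of calls with marker row names and individual
#'   column names.
#' @param source provenance label(s): `"default"`, `"gamma"` or `"normal"`
#'   (recycled across markers).
#' @param type `"codominant"` or `"dominant"` per marker.
#' @param source_parent optional integer vector (1 or 2) naming which parent's
#'   amplicon each marker tracks.
#' @param info optional pre-built info data frame (internal use).
#' @param history optional pre-existing history data frame (internal use).
#' @return an object of class `"marker_set"`.
#' @export
marker_set <- function(calls, source = "unknown", type = "codominant",
                       source_parent = NA_integer_, info = NULL, history = NULL) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls))) stop("calls must have marker row names")
  if (anyDuplicated(rownames(calls))) stop("duplicate marker ids in calls")
  bad <- !(calls %in% c("A", "H", "B", "C", "D") | is.na(calls))
  if (any(bad)) stop("illegal genotype code(s): ",
                     paste(unique(calls[bad]), collapse = ", "))
  if (is.null(info)) {
    info <- data.frame(marker = rownames(calls),
                       source = rep_len(source, nrow(calls)),
                       type = rep_len(type, nrow(calls)),
                       source_parent = rep_len(source_parent, nrow(calls)),
                       consensus_pct = NA_real_,
                       parental_ok = NA,
                       distortion_p = NA_real_,
                       converged = NA,
                       stringsAsFactors = FALSE)
  }
  stopifnot(identical(info$marker, rownames(calls)))
  if (is.null(history)) {
    history <- data.frame(step = "created", n_before = nrow(calls),
                          n_removed = 0L, n_after = nrow(calls),
                          stringsAsFactors = FALSE)
  }
  structure(list(calls = calls, info = info, history = history),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat("marker_set:", nrow(x$calls), "markers x", ncol(x$calls), "individuals\n")
  src <- table(x$info$source)
  cat("sources:", paste(names(src), src, sep = "=", collapse = ", "), "\n")
  cat("history:\n")
  print(x$history, row.names = FALSE)
  invisible(x)
}

#' Number of markers in a marker set
#' @param x a `marker_set`.
#' @return integer marker count.
#' @export
n_markers <- function(x) nrow(get_calls(x))

# accept a marker_set or a bare call matrix
get_calls <- function(x) {
  if (inherits(x, "marker_set")) x$calls else as.matrix(x)
}

# subset a marker_set to the given marker ids, appending a history row
ms_keep <- function(ms, keep_ids, step) {
  n_before <- nrow(ms$calls)
  keep <- rownames(ms$calls) %in% keep_ids
  ms$calls <- ms$calls[keep, , drop = FALSE]
  ms$info <- ms$info[keep, , drop = FALSE]
  rownames(ms$info) <- NULL
  ms$history <- rbind(ms$history,
                      data.frame(step = step, n_before = n_before,
                                 n_removed = n_before - sum(keep),
                                 n_after = sum(keep), stringsAsFactors = FALSE))
  ms
}

#' Merge redundant marker sets by provenance priority
#'
#' The default caller, the gamma-mixture caller and the normal-mixture caller
#' each produce co-dominant calls for (partially) overlapping loci. For every
#' marker present in more than one set, exactly one call vector survives,
#' chosen in the fixed priority order default > gamma > normal; the merged
#' set's size is the size of the union and provenance is recorded per marker.
#' The merge is idempotent and associative in the stated order.
#'
#' @param default_set,gamma_set,normal_set `marker_set` objects (or `NULL`).
#' @return a merged `marker_set`.
#' @export
priority_merge <- function(default_set = NULL, gamma_set = NULL,
                           normal_set = NULL) {
  sets <- Filter(Negate(is.null), list(default_set, gamma_set, normal_set))
  if (length(sets) == 0) stop("at least one marker set required")
  cols <- colnames(sets[[1]]$calls)
  for (s in sets) {
    if (!identical(colnames(s$calls), cols)) {
      stop("marker sets cover different individuals")
    }
  }
  taken <- character(0)
  calls_list <- list()
  info_list <- list()
  for (s in sets) {
    new <- setdiff(rownames(s$calls), taken)
    if (length(new)) {
      calls_list[[length(calls_list) + 1L]] <- s$calls[new, , drop = FALSE]
      info_list[[length(info_list) + 1L]] <-
        s$info[match(new, s$info$marker), , drop = FALSE]
      taken <- c(taken, new)
    }
  }
  calls <- do.call(rbind, calls_list)
  info <- do.call(rbind, info_list)
  rownames(info) <- NULL
  history <- data.frame(step = "priority_merge",
                        n_before = sum(vapply(sets, function(s) nrow(s$calls), 0L)),
                        n_removed = sum(vapply(sets, function(s) nrow(s$calls), 0L)) -
                          nrow(calls),
                        n_after = nrow(calls), stringsAsFactors = FALSE)
  marker_set(calls, info = info, history = history)
}
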