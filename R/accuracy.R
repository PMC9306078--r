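#' Co-dominant genotyping agreement with a reference call set
#'
#' For every marker present in both matrices, computes the percentage of
#' individuals (non-missing in both) whose three-state codes agree, plus the
#' unweighted average over markers. Used both to score mixture calls against
#' the default caller's co-dominant subset and against simulated truth.
#'
#' @param calls a `marker_set` or call matrix.
#' @param reference a `marker_set` or call matrix covering (a superset of) the
#'   same individuals.
#' @return list with `per_marker` (named percentages), `average`, and
#'   `n_markers`.
#' @export
codominant_accuracy <- function(calls, reference) {
  a <- get_calls(calls)
  b <- get_calls(reference)
  common <- intersect(rownames(a), rownames(b))
  if (length(common) == 0) stop("no overlapping markers between call sets")
  if (!all(colnames(a) %in% colnames(b))) {
    stop("reference does not cover all individuals")
  }
  b <- b[, colnames(a), drop = FALSE]
  per <- vapply(common, function(m) {
    ok <- !is.na(a[m, ]) & !is.na(b[m, ])
    if (!any(ok)) return(NA_real_)
    100 * mean(a[m, ok] == b[m, ok])
  }, numeric(1))
  list(per_marker = per, average = mean(per, na.rm = TRUE),
       n_markers = length(common))
}

#' Dominant genotyping agreement after collapsing heterozygotes
#'
#' Three-state calls are collapsed to two states: the heterozygote is merged
#' into the presence class of the marker's source parent (A and H are
#' "present" for a seed-parent-sourced marker, B and H for a
#' pollen-parent-sourced one), then compared with the default dominant
#' "P"/"A" matrix.
#'
#' @param calls a `marker_set` (whose info carries `source_parent`) or a call
#'   matrix, in which case `source_parent` must be supplied.
#' @param dominant_ref character matrix of "P"/"A" dominant reference calls.
#' @param source_parent optional named integer vector (1 or 2) per marker.
#' @return list with `per_marker`, `average`, `n_markers`.
#' @export
dominant_accuracy <- function(calls, dominant_ref, source_parent = NULL) {
  a <- get_calls(calls)
  if (is.null(source_parent)) {
    if (!inherits(calls, "marker_set")) {
      stop("source_parent required when calls is a bare matrix")
    }
    source_parent <- stats::setNames(calls$info$source_parent, calls$info$marker)
  }
  common <- intersect(rownames(a), rownames(dominant_ref))
  if (length(common) == 0) stop("no overlapping markers between call sets")
  ref <- dominant_ref[common, colnames(a), drop = FALSE]
  per <- vapply(common, function(m) {
    sp <- source_parent[[m]]
    if (is.na(sp)) stop("unknown source parent for marker ", m)
    collapsed <- collapse_to_dominant(a[m, ], sp)
    ok <- !is.na(collapsed) & !is.na(ref[m, ])
    if (!any(ok)) return(NA_real_)
    100 * mean(collapsed[ok] == ref[m, ok])
  }, numeric(1))
  list(per_marker = per, average = mean(per, na.rm = TRUE),
       n_markers = length(common))
}

# collapse 3-state codes to the source parent's presence/absence classes
collapse_to_dominant <- function(codes, source_parent) {
  present <- if (source_parent == 1L) c("A", "H") else c("B", "H")
  out <- ifelse(is.na(codes), NA_character_,
                ifelse(codes %in% present, "P", "A"))
  out
}

#' Filter markers by consensus with the default dominant caller
#'
#' Retains markers whose dominant-collapsed agreement with the default
#' dominant estimation is strictly greater than `threshold` percent. The
#' consensus percentage is computed (via [dominant_accuracy()]) if not already
#' stored on the set.
#'
#' @param ms a `marker_set`.
#' @param dominant_ref dominant reference matrix, required if consensus has
#'   not yet been recorded in `ms$info$consensus_pct`.
#' @param threshold retention threshold in percent (strict inequality).
#' @return the filtered `marker_set` with updated info and history.
#' @export
consensus_filter <- function(ms, dominant_ref = NULL, threshold = 95) {
  stopifnot(inherits(ms, "marker_set"))
  if (all(is.na(ms$info$consensus_pct))) {
    if (is.null(dominant_ref)) {
      stop("consensus not yet computed; supply dominant_ref")
    }
    acc <- dominant_accuracy(ms, dominant_ref)
    ms$info$consensus_pct <- acc$per_marker[ms$info$marker]
  }
  keep <- ms$info$marker[!is.na(ms$info$consensus_pct) &
                           ms$info$consensus_pct > threshold]
  ms_keep(ms, keep, sprintf("consensus_filter(>%g%%)", threshold))
}

#' Filter markers by parental genotype consistency
#'
#' Retains markers where parent 1 (seed parent) is called the A-side
#' homozygote and parent 2 (pollen parent) the B-side homozygote by the same
#' per-locus fit that called the progeny. A missing parent call removes the
#' marker (conservative).
#'
#' @param ms a `marker_set` whose info carries the `parental_ok` flag (set by
#'   [call_codominant()]).
#' @return the filtered `marker_set`.
#' @export
parental_consistency_filter <- function(ms) {
  stopifnot(inherits(ms, "marker_set"))
  if (all(is.na(ms$info$parental_ok))) {
    stop("parental calls not available for this marker set")
  }
  keep <- ms$info$marker[!is.na(ms$info$parental_ok) & ms$info$parental_ok]
  ms_keep(ms, keep, "parental_consistency_filter")
}
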