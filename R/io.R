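# TSV interchange ------------------------------------------------------------
#
# All on-disk formats are one-header-line TSVs; lines starting with '#' are
# metadata comments (the generator records its seed there). Write-then-read
# is the identity for every format.

write_tsv_with_header <- function(df, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_body <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read and write read-depth matrices
#'
#' Rows are markers; columns are `marker`, `source_parent`, `parent1`,
#' `parent2`, then one column per individual. Reading validates that ids are
#' unique and counts are non-negative, naming the offending line on failure.
#'
#' @param depths a `depth_matrix`.
#' @param path file path.
#' @param comments extra header comment lines.
#' @return `read_depth_matrix()` returns a `depth_matrix`;
#'   `write_depth_matrix()` returns the path invisibly.
#' @export
write_depth_matrix <- function(depths, path, comments = character(0)) {
  stopifnot(inherits(depths, "depth_matrix"))
  df <- data.frame(marker = rownames(depths$counts),
                   source_parent = depths$source_parent,
                   parent1 = depths$parent1_counts,
                   parent2 = depths$parent2_counts,
                   depths$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, comments)
}

#' @rdname write_depth_matrix
#' @export
read_depth_matrix <- function(path) {
  df <- read_tsv_body(path)
  need <- c("marker", "source_parent", "parent1", "parent2")
  if (!all(need %in% names(df))) {
    stop("depth matrix must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(df) == 0) stop("empty depth matrix file: ", path)
  dup <- duplicated(df$marker)
  if (any(dup)) stop("duplicate marker id at line ", which(dup)[1] + 1, ": ",
                     df$marker[dup][1])
  ind_cols <- setdiff(names(df), need)
  counts <- as.matrix(df[, ind_cols, drop = FALSE])
  if (!is.numeric(counts) || any(is.na(counts)) || any(counts < 0)) {
    bad <- which(apply(counts, 1, function(r) any(is.na(r) | r < 0)))[1]
    stop("negative or missing count at line ", bad + 1, " (marker ",
         df$marker[bad], ")")
  }
  rownames(counts) <- df$marker
  structure(list(counts = counts,
                 parent1_counts = stats::setNames(df$parent1, df$marker),
                 parent2_counts = stats::setNames(df$parent2, df$marker),
                 source_parent = stats::setNames(df$source_parent, df$marker)),
            class = "depth_matrix")
}

#' Read and write genotype call matrices
#'
#' Rows are markers, columns `marker` then one per individual; codes are
#' `A`, `H`, `B` (co-dominant), `C`, `D` (dominant) and `-` (missing).
#' Reading rejects any other code, naming its line.
#'
#' @param calls a `marker_set` or call matrix.
#' @param path file path.
#' @param comments extra header comment lines.
#' @return `read_genotype_matrix()` returns a character matrix with `NA` for
#'   missing.
#' @export
write_genotype_matrix <- function(calls, path, comments = character(0)) {
  m <- get_calls(calls)
  out <- m
  out[is.na(out)] <- "-"
  df <- data.frame(marker = rownames(m), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, comments)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  df <- read_tsv_body(path)
  if (!"marker" %in% names(df)) stop("genotype matrix must have a 'marker' column")
  if (nrow(df) == 0) stop("empty genotype matrix file: ", path)
  dup <- duplicated(df$marker)
  if (any(dup)) stop("duplicate marker id at line ", which(dup)[1] + 1)
  m <- as.matrix(df[, setdiff(names(df), "marker"), drop = FALSE])
  rownames(m) <- df$marker
  legal <- m %in% c("A", "H", "B", "C", "D", "-")
  if (!all(legal)) {
    bad <- which(!matrix(legal, nrow(m)), arr.ind = TRUE)[1, ]
    stop("illegal genotype code '", m[bad[1], bad[2]], "' at line ",
         bad[1] + 1, " (marker ", rownames(m)[bad[1]], ")")
  }
  m[m == "-"] <- NA_character_
  m
}

#' Read and write genetic maps
#'
#' TSV with columns `group`, `marker`, `position_cM`.
#'
#' @param map a `genetic_map`.
#' @param path file path.
#' @param comments extra header comment lines.
#' @return `read_map()` returns a `genetic_map` data frame.
#' @export
write_map <- function(map, path, comments = character(0)) {
  stopifnot(inherits(map, "genetic_map"))
  df <- data.frame(group = map$group, marker = map$marker,
                   position_cM = map$position, stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, comments)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  df <- read_tsv_body(path)
  need <- c("group", "marker", "position_cM")
  if (!all(need %in% names(df))) {
    stop("map file must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(df) == 0) stop("empty map file: ", path)
  dup <- duplicated(df$marker)
  if (any(dup)) stop("duplicate marker id at line ", which(dup)[1] + 1)
  out <- data.frame(group = df$group, marker = df$marker,
                    position = df$position_cM, stringsAsFactors = FALSE)
  class(out) <- c("genetic_map", "data.frame")
  out
}

#' Read and write phenotype tables
#'
#' TSV with columns `individual`, `flowering_time`, `maturity_time`,
#' `censored` (0/1).
#'
#' @param phen a `phenotype_table` data frame.
#' @param path file path.
#' @param comments extra header comment lines.
#' @return `read_phenotypes()` returns a `phenotype_table`.
#' @export
write_phenotypes <- function(phen, path, comments = character(0)) {
  df <- data.frame(individual = phen$individual,
                   flowering_time = phen$flowering_time,
                   maturity_time = phen$maturity_time,
                   censored = as.integer(phen$censored),
                   stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, comments)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- read_tsv_body(path)
  need <- c("individual", "flowering_time", "maturity_time", "censored")
  if (!all(need %in% names(df))) {
    stop("phenotype file must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(df) == 0) stop("empty phenotype file: ", path)
  if (any(df$maturity_time <= 0 | df$flowering_time <= 0, na.rm = TRUE)) {
    bad <- which(df$maturity_time <= 0 | df$flowering_time <= 0)[1]
    stop("non-positive DAS at line ", bad + 1)
  }
  df$censored <- as.logical(df$censored)
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Write a QTL scan profile
#'
#' TSV with columns `group`, `position_cM`, `marker`, `lod`, `additive`,
#' `dominance`, `r2`.
#'
#' @param scan a `qtl_scan`.
#' @param path file path.
#' @param comments extra header comment lines.
#' @export
write_scan <- function(scan, path, comments = character(0)) {
  df <- data.frame(group = scan$group, position_cM = scan$position,
                   marker = ifelse(is.na(scan$marker), "-", scan$marker),
                   lod = scan$lod, additive = scan$additive,
                   dominance = scan$dominance, r2 = scan$r2,
                   stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, comments)
}

#' Read and write run configurations as YAML
#'
#' Unknown keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param config a [sim_config()].
#' @param path YAML file path.
#' @return `read_run_config()` returns a `sim_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(sim_config, raw)
}
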