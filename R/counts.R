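#' Read a specimen-by-ASV count table
#'
#' Accepts wide CSV (header row of ASV ids, first column specimen ids) or
#' long CSV (`specimen,asv,count`), auto-detected. Absent long-format
#' pairs become zeros.
#'
#' @param path CSV file path.
#' @return A non-negative integer matrix, rownames = specimens,
#'   colnames = features.
#' @export
read_asv_counts <- function(path) {
  if (!file.exists(path)) .usage_error("count file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  is_long <- ncol(df) == 3L && !is.numeric(df[[2L]]) && is.numeric(df[[3L]])
  if (is_long) {
    names(df) <- c("specimen", "asv", "count")
    .check_counts(df$count, path)
    key <- paste(df$specimen, df$asv, sep = "\r")
    if (anyDuplicated(key))
      .format_error("duplicate (specimen, asv) pair at row %d of %s",
                    which(duplicated(key))[1L] + 1L, path)
    specimens <- unique(df$specimen)
    features <- unique(df$asv)
    m <- matrix(0, length(specimens), length(features),
                dimnames = list(specimens, features))
    m[cbind(match(df$specimen, specimens), match(df$asv, features))] <-
      df$count
  } else {
    if (ncol(df) < 2L) .format_error("count CSV %s has no feature columns",
                                     path)
    specimens <- as.character(df[[1L]])
    if (anyDuplicated(specimens))
      .format_error("duplicate specimen id '%s' in %s",
                    specimens[duplicated(specimens)][1L], path)
    m <- as.matrix(df[-1L])
    for (j in seq_len(ncol(m))) .check_counts(m[, j], path)
    storage.mode(m) <- "numeric"
    rownames(m) <- specimens
  }
  if (any(m %% 1 != 0))
    .format_error("non-integer counts in %s", path)
  storage.mode(m) <- "integer"
  m
}

.check_counts <- function(x, path) {
  if (!is.numeric(x))
    .format_error("non-numeric counts in %s", path)
  bad <- which(is.na(x) | x < 0)
  if (length(bad))
    .format_error("negative or missing count at row %d of %s",
                  bad[1L] + 1L, path)
}

#' Write a count table as wide CSV
#' @param table Specimen-by-feature matrix.
#' @param path Output path (written atomically).
#' @return Invisibly, `path`.
#' @export
write_count_table <- function(table, path) {
  df <- data.frame(specimen = rownames(table), table, check.names = FALSE)
  .write_atomic(path, function(tmp)
    utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE))
  invisible(path)
}

#' Collapse ASV counts to phylotype counts
#'
#' Sums member-ASV columns per phylotype. ASVs absent from the assignment
#' accumulate into a reserved `"unclassified"` feature rather than being
#' dropped, so per-specimen totals are conserved exactly and the
#' unassigned mass stays auditable.
#'
#' @param asv_counts Specimen-by-ASV count matrix.
#' @param assignment Named character vector ASV id -> phylotype name, or
#'   a `phylotype_model`.
#' @return Specimen-by-phylotype count matrix.
#' @export
phylotype_counts <- function(asv_counts, assignment) {
  if (inherits(assignment, "phylotype_model"))
    assignment <- assignment$asv_to_phylotype
  grp <- assignment[colnames(asv_counts)]
  grp[is.na(grp)] <- "unclassified"
  out <- t(rowsum(t(asv_counts), group = grp))
  out[, order(colnames(out)), drop = FALSE]
}

#' Per-specimen fraction of reads assigned to a phylotype
#'
#' @inheritParams phylotype_counts
#' @return Named numeric vector in `[0, 1]`; specimens with zero reads
#'   get `NA` (undefined, not 0).
#' @export
assigned_fraction <- function(asv_counts, assignment) {
  if (inherits(assignment, "phylotype_model"))
    assignment <- assignment$asv_to_phylotype
  assigned <- colnames(asv_counts) %in% names(assignment)
  tot <- rowSums(asv_counts)
  frac <- rowSums(asv_counts[, assigned, drop = FALSE]) / tot
  frac[tot == 0] <- NA_real_
  frac
}

#' Normalize counts to a fixed read depth
#'
#' Scales each specimen's row to sum to `depth` pseudo-counts (default
#' 10,000). Values stay real-valued -- no rounding -- so downstream
#' Bray-Curtis distances are exact. Zero-read specimens are dropped with
#' a warning.
#'
#' @param table Specimen-by-feature count matrix.
#' @param depth Target row sum (default 10000).
#' @return Real-valued matrix whose rows sum to `depth`.
#' @export
normalize_counts <- function(table, depth = 10000) {
  stopifnot(depth > 0)
  tot <- rowSums(table)
  zero <- tot == 0
  if (any(zero)) {
    warning(sprintf("dropping %d zero-read specimen(s): %s", sum(zero),
                    paste(utils::head(rownames(table)[zero], 3L),
                          collapse = ", ")))
    table <- table[!zero, , drop = FALSE]
    tot <- tot[!zero]
  }
  table * (depth / tot)
}

#' Pairwise Bray-Curtis dissimilarity between specimens
#'
#' Computed on the values as given (normalize first with
#' [normalize_counts()] for depth-corrected comparisons):
#' `BC(i,j) = sum|x_i - x_j| / sum(x_i + x_j)` over features.
#'
#' @param table Specimen-by-feature matrix with at least 2 specimens.
#' @return Symmetric matrix in `[0, 1]` with zero diagonal; cells for a
#'   pair of all-zero specimens are `NaN` (undefined).
#' @export
bray_curtis <- function(table) {
  if (nrow(table) < 2L)
    .usage_error("bray_curtis needs at least 2 specimens")
  D <- as.matrix(suppressWarnings(vegan::vegdist(table, method = "bray")))
  diag(D) <- 0
  zero <- rowSums(table) == 0
  if (any(zero)) D[zero, zero] <- NaN
  diag(D) <- ifelse(zero, NaN, 0)
  D
}
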