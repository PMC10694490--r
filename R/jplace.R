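.usage_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("phylobin_usage_error", "error")))
}
.format_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("phylobin_format_error", "error")))
}

#' A single ASV's placement record
#'
#' The per-query unit of the jplace format: one row per candidate
#' attachment edge with the engine's likelihood, like_weight_ratio (lwr),
#' distal_length (offset from the distal end of the edge) and
#' pendant_length.
#'
#' @param asv_id Identifier of the ASV.
#' @param rows A data.frame with columns `edge_num`, `likelihood`,
#'   `like_weight_ratio`, `distal_length`, `pendant_length` (likelihood
#'   may be `NA` when the source file lacked it).
#' @param multiplicity Positive multiplicity (jplace `nm`), default 1.
#' @return A `placement_record`.
#' @export
placement_record <- function(asv_id, rows, multiplicity = 1) {
  stopifnot(is.character(asv_id), length(asv_id) == 1L,
            is.data.frame(rows))
  need <- c("edge_num", "like_weight_ratio", "distal_length",
            "pendant_length")
  miss <- setdiff(need, names(rows))
  if (length(miss))
    .format_error("placement record '%s' missing column(s): %s", asv_id,
                  paste(miss, collapse = ", "))
  if (!"likelihood" %in% names(rows)) rows$likelihood <- NA_real_
  if (nrow(rows) < 1L)
    .format_error("placement record '%s' has no rows", asv_id)
  lwr <- rows$like_weight_ratio
  if (any(lwr < -1e-12) || any(lwr > 1 + 1e-6))
    .format_error("record '%s': like_weight_ratio outside [0, 1]", asv_id)
  if (sum(lwr) <= 0)
    .format_error("record '%s': like_weight_ratio sum is not positive",
                  asv_id)
  if (sum(lwr) > 1 + 1e-6)
    .format_error("record '%s': like_weight_ratio sum exceeds 1", asv_id)
  if (any(rows$distal_length < 0) || any(rows$pendant_length < 0))
    .format_error("record '%s': negative distal/pendant length", asv_id)
  if (multiplicity <= 0)
    .format_error("record '%s': non-positive multiplicity", asv_id)
  structure(list(asv_id = asv_id,
                 rows = rows[c("edge_num", "likelihood",
                               "like_weight_ratio", "distal_length",
                               "pendant_length")],
                 multiplicity = as.numeric(multiplicity)),
            class = "placement_record")
}

#' A set of placements on a common reference tree
#'
#' @param tree A [ref_tree][parse_edge_numbered_newick].
#' @param records A list of [placement_record()]s (names taken from the
#'   records' `asv_id`s, which must be unique).
#' @param fields The jplace "fields" order to preserve on write.
#' @param version jplace format version (written as 3).
#' @param metadata Free-form metadata list.
#' @return A `placement_set`.
#' @export
placement_set <- function(tree, records,
                          fields = c("edge_num", "likelihood",
                                     "like_weight_ratio", "distal_length",
                                     "pendant_length"),
                          version = 3L, metadata = list()) {
  stopifnot(inherits(tree, "ref_tree"), is.list(records))
  ids <- vapply(records, function(r) r$asv_id, "")
  if (anyDuplicated(ids))
    .format_error("duplicate ASV id '%s' in placement set",
                  ids[duplicated(ids)][1L])
  names(records) <- ids
  for (r in records) {
    bad <- setdiff(r$rows$edge_num, tree$edge_num)
    if (length(bad))
      .format_error("ASV '%s' placed on edge {%d} absent from tree",
                    r$asv_id, bad[1L])
  }
  structure(list(tree = tree, records = records, fields = fields,
                 version = as.integer(version), metadata = metadata),
            class = "placement_set")
}

#' @export
print.placement_set <- function(x, ...) {
  cat(sprintf("placement_set: %d ASVs on a %d-tip reference tree\n",
              length(x$records), x$tree$n_tip))
  invisible(x)
}

#' Read a jplace file
#'
#' Parses a version-3 jplace JSON file: the edge-numbered reference tree,
#' the "fields" list (rows are mapped by field name, so any field order is
#' accepted), and the per-query placements. Queries named via `"n"` (list
#' of names sharing one row set, one record per name) or `"nm"` (name plus
#' multiplicity) are both supported.
#'
#' @param path Path to a jplace file.
#' @return A [placement_set()].
#' @export
read_jplace <- function(path) {
  if (!file.exists(path)) .usage_error("jplace file not found: %s", path)
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (key in c("tree", "placements", "fields", "version"))
    if (is.null(js[[key]]))
      .format_error("jplace file missing key '%s'", key)
  fields <- unlist(js$fields)
  need <- c("edge_num", "like_weight_ratio", "distal_length",
            "pendant_length")
  miss <- setdiff(need, fields)
  if (length(miss))
    .format_error("jplace fields missing %s (available: %s)",
                  paste(miss, collapse = ", "),
                  paste(fields, collapse = ", "))
  tree <- parse_edge_numbered_newick(js$tree)

  records <- list()
  for (pl in js$placements) {
    p <- pl$p
    if (is.null(p) || length(p) == 0L)
      .format_error("jplace placement with empty 'p' rows")
    rows <- as.data.frame(do.call(rbind, lapply(p, function(row) {
      row <- unlist(row)
      if (length(row) != length(fields))
        .format_error("jplace 'p' row has %d values for %d fields",
                      length(row), length(fields))
      as.numeric(row)
    })))
    names(rows) <- fields
    if (!"likelihood" %in% names(rows)) rows$likelihood <- NA_real_
    rows <- rows[c("edge_num", "likelihood", "like_weight_ratio",
                   "distal_length", "pendant_length")]
    rows$edge_num <- as.integer(rows$edge_num)
    if (!is.null(pl$nm)) {
      for (nm in pl$nm)
        records[[length(records) + 1L]] <-
          placement_record(as.character(nm[[1L]]), rows,
                           multiplicity = as.numeric(nm[[2L]]))
    } else if (!is.null(pl$n)) {
      for (nm in pl$n)
        records[[length(records) + 1L]] <-
          placement_record(as.character(nm), rows)
    } else {
      .format_error("jplace placement without 'n' or 'nm' names")
    }
  }
  placement_set(tree, records, fields = fields,
                version = as.integer(js$version),
                metadata = if (is.null(js$metadata)) list() else js$metadata)
}

#' Write a placement set as a jplace file
#'
#' Emits jplace version 3 with the set's original field order; the written
#' file re-reads to an equivalent [placement_set()].
#'
#' @param pset A [placement_set()].
#' @param path Output path (written atomically).
#' @return Invisibly, `path`.
#' @export
write_jplace <- function(pset, path) {
  stopifnot(inherits(pset, "placement_set"))
  placements <- lapply(pset$records, function(r) {
    rows <- r$rows
    rows$likelihood[is.na(rows$likelihood)] <- 0
    p <- lapply(seq_len(nrow(rows)), function(i)
      lapply(pset$fields, function(f) {
        v <- rows[[f]][i]
        if (f == "edge_num") as.integer(v) else as.numeric(v)
      }))
    list(p = p, nm = list(list(r$asv_id, r$multiplicity)))
  })
  out <- list(version = 3L,
              tree = pset$tree$newick,
              fields = as.list(pset$fields),
              placements = unname(placements),
              metadata = if (length(pset$metadata)) pset$metadata
                         else list(invocation = "phylobin"))
  .write_atomic(path, function(tmp)
    jsonlite::write_json(out, tmp, auto_unbox = TRUE, digits = NA,
                         null = "null"))
  invisible(path)
}

.write_atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  ok <- FALSE
  on.exit(if (!ok) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  ok <- TRUE
  invisible(path)
}

#' Placement mass distribution of one ASV
#'
#' Converts a placement record to its normalized mass distribution: one
#' point per row at (edge_num, distal_length), weighted by
#' like_weight_ratio renormalized to sum 1. Renormalization makes records
#' comparable when engines truncate low-weight edges. Pendant lengths are
#' carried along but excluded from inter-ASV distances by default (they
#' reflect amplicon-versus-reference divergence, which differs
#' systematically by primer and would inflate distances between amplicons
#' of the same allele); distance functions accept `include_pendant = TRUE`
#' for sensitivity analysis.
#'
#' @param record A [placement_record()].
#' @param lwr_floor Rows with like_weight_ratio below this are pruned
#'   before normalization (default 0 = keep all).
#' @param best_only If `TRUE`, collapse to a unit point mass at the
#'   highest-lwr row.
#' @return A `mass_distribution`: data.frame with columns `edge_num`,
#'   `offset`, `weight`, `pendant`; weights sum to 1.
#' @export
to_mass <- function(record, lwr_floor = 0, best_only = FALSE) {
  stopifnot(inherits(record, "placement_record"))
  rows <- record$rows
  if (best_only) rows <- rows[which.max(rows$like_weight_ratio), ]
  if (lwr_floor > 0) {
    keep <- rows$like_weight_ratio >= lwr_floor
    if (any(keep)) rows <- rows[keep, ]
  }
  tot <- sum(rows$like_weight_ratio)
  if (tot <= 0)
    .format_error("record '%s': all like_weight_ratios are zero",
                  record$asv_id)
  m <- data.frame(edge_num = rows$edge_num,
                  offset = rows$distal_length,
                  weight = rows$like_weight_ratio / tot,
                  pendant = rows$pendant_length)
  m <- m[m$weight > 0, ]
  structure(m, class = c("mass_distribution", "data.frame"))
}

#' Construct a mass distribution directly
#'
#' @param edge_num Integer edge numbers.
#' @param offset Offsets from the distal end of each edge.
#' @param weight Positive weights; normalized to sum 1.
#' @param pendant Optional pendant lengths (default 0).
#' @return A `mass_distribution`.
#' @export
mass_distribution <- function(edge_num, offset, weight,
                              pendant = rep(0, length(edge_num))) {
  stopifnot(length(edge_num) == length(offset),
            length(offset) == length(weight), all(weight > 0))
  structure(data.frame(edge_num = as.integer(edge_num),
                       offset = as.numeric(offset),
                       weight = weight / sum(weight),
                       pendant = as.numeric(pendant)),
            class = c("mass_distribution", "data.frame"))
}
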