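#' Read an ASV-by-reference identity hit table
#'
#' Tabular output of a global identity search of repository 16S alleles
#' against ASVs (e.g. vsearch usearch_global): columns `asv_id`, `ref_id`,
#' `pct_id` (percent identity in `[0, 100]`). TSV or CSV, sniffed from
#' the first line.
#'
#' @param path File path.
#' @return A data.frame with the three columns above.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) .usage_error("hit table not found: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) .format_error("hit table needs asv_id, ref_id, pct_id")
  names(df)[1:3] <- c("asv_id", "ref_id", "pct_id")
  .validate_hits(df[1:3])
}

.validate_hits <- function(hits) {
  stopifnot(is.data.frame(hits))
  hits$asv_id <- as.character(hits$asv_id)
  hits$ref_id <- as.character(hits$ref_id)
  if (!is.numeric(hits$pct_id) || any(hits$pct_id < 0 | hits$pct_id > 100))
    .format_error("pct_id must be numeric in [0, 100]")
  key <- paste(hits$asv_id, hits$ref_id, sep = "\r")
  if (anyDuplicated(key))
    .format_error("duplicate (asv_id, ref_id) pair '%s'",
                  gsub("\r", ", ", key[duplicated(key)][1L]))
  hits
}

#' Keep only each ASV's bounded best hits
#'
#' For each ASV, establishes the best possible percent identity against
#' the repository and discards hits below it; ties at the maximum are all
#' retained.
#'
#' @param hits Hit table data.frame (`asv_id`, `ref_id`, `pct_id`).
#' @return The filtered hit table.
#' @export
bounded_best_hits <- function(hits) {
  hits <- .validate_hits(hits)
  if (nrow(hits) == 0L) return(hits)
  best <- tapply(hits$pct_id, hits$asv_id, max)
  keep <- hits$pct_id == best[hits$asv_id]
  rownames(hits) <- NULL
  hits[keep, , drop = FALSE]
}

#' References that are a best hit for enough ASVs
#'
#' @param best_hits Output of [bounded_best_hits()].
#' @param min_asvs Minimum number of distinct ASVs a reference must be a
#'   best hit for (default 2).
#' @return Character vector of retained ref_ids.
#' @export
filter_min_support <- function(best_hits, min_asvs = 2L) {
  if (min_asvs < 1L) .usage_error("min_asvs must be >= 1")
  support <- tapply(best_hits$asv_id, best_hits$ref_id,
                    function(a) length(unique(a)))
  sort(names(support)[support >= min_asvs])
}

#' Backfill references for ASVs left uncovered by the support filter
#'
#' For each ASV whose best-hit references were all discarded, one
#' reference from its best-hit set is restored, preferring alleles with no
#' ambiguous bases, then precise taxonomic annotation, then greatest
#' length, then lexicographically smallest ref_id.
#'
#' @param hits Full hit table (pre-best-hit filtering is recomputed
#'   internally).
#' @param meta Reference metadata data.frame: `ref_id`, `length`,
#'   `n_ambiguous`, `has_precise_taxonomy`.
#' @param kept Character vector of already-retained ref_ids.
#' @param per_asv How many references to restore per uncovered ASV
#'   (default 1).
#' @return `kept` plus the backfilled ref_ids (sorted, unique).
#' @export
backfill <- function(hits, meta, kept, per_asv = 1L) {
  hits <- .validate_hits(hits)
  stopifnot(is.data.frame(meta),
            all(c("ref_id", "length", "n_ambiguous",
                  "has_precise_taxonomy") %in% names(meta)))
  if (anyDuplicated(meta$ref_id))
    .format_error("duplicate ref_id in reference metadata")
  bh <- bounded_best_hits(hits)
  additions <- character(0)
  for (asv in unique(bh$asv_id)) {
    refs <- bh$ref_id[bh$asv_id == asv]
    if (any(refs %in% kept)) next
    mi <- meta[match(refs, meta$ref_id), ]
    ord <- order(mi$n_ambiguous != 0,          # zero-ambiguity first
                 !as.logical(mi$has_precise_taxonomy),
                 -mi$length,
                 mi$ref_id)
    additions <- c(additions, refs[ord][seq_len(min(per_asv, length(refs)))])
  }
  sort(unique(c(kept, additions)))
}

#' Recruit reference alleles by bounded best hits
#'
#' Full recruitment pipeline for building an ASV-tailored reference set:
#' floor-filter hits at `min_pct` identity, keep each ASV's bounded best
#' hits, retain references that are a best hit for at least `min_asvs`
#' ASVs, then backfill so every ASV with a hit stays covered. The report
#' logs mean recruited references per ASV against the design objective of
#' roughly 10 alleles per ASV.
#'
#' @param hits Hit table data.frame (`asv_id`, `ref_id`, `pct_id`).
#' @param meta Reference metadata (see [backfill()]).
#' @param min_pct Identity floor in percent (default 80).
#' @param min_asvs Minimum best-hit support (default 2).
#' @return A list: `refs` (sorted recruited ref_ids) and `report` with
#'   `per_asv` (ASV -> recruited best-hit refs), `uncovered` (ASVs with
#'   no hit at or above the floor) and `mean_refs_per_asv`.
#' @export
recruit <- function(hits, meta, min_pct = 80, min_asvs = 2L) {
  hits <- .validate_hits(hits)
  if (nrow(hits) == 0L) .usage_error("recruit: empty hit table")
  all_asvs <- unique(hits$asv_id)
  floored <- hits[hits$pct_id >= min_pct, , drop = FALSE]
  uncovered <- setdiff(all_asvs, unique(floored$asv_id))
  if (nrow(floored) == 0L)
    return(list(refs = character(0),
                report = list(per_asv = list(), uncovered = sort(uncovered),
                              mean_refs_per_asv = NA_real_)))
  bh <- bounded_best_hits(floored)
  kept <- filter_min_support(bh, min_asvs)
  refs <- backfill(floored, meta, kept)
  per_asv <- lapply(split(bh$ref_id, bh$asv_id),
                    function(r) sort(intersect(r, refs)))
  mean_refs <- mean(lengths(per_asv))
  message(sprintf("recruit: %d references; mean %.2f refs/ASV (objective ~10)",
                  length(refs), mean_refs))
  list(refs = refs,
       report = list(per_asv = per_asv, uncovered = sort(uncovered),
                     mean_refs_per_asv = mean_refs))
}
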