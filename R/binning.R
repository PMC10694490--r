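## minimal union-find
.uf_new <- function(n) seq_len(n)
.uf_find <- function(uf, i) {
  while (uf[i] != i) i <- uf[i]
  i
}
.uf_union <- function(uf, i, j) {
  ri <- .uf_find(uf, i); rj <- .uf_find(uf, j)
  if (ri != rj) uf[ri] <- rj
  uf
}

#' Pre-group ASVs by shared placement edges
#'
#' The "divide" step: two ASVs are joined whenever they share at least one
#' mass-bearing placement edge, and pre-groups are the connected
#' components of that relation (so joining is transitive). ASVs whose
#' placements touch disjoint parts of the tree land in different
#' pre-groups and are never compared exhaustively.
#'
#' @param pset A [placement_set()].
#' @return A list of `pre_group`s, each a list with `members` (ASV ids),
#'   `mass_edges` (union of the members' mass-bearing edge numbers) and
#'   `lca_node`.
#' @export
pregroup <- function(pset) {
  stopifnot(inherits(pset, "placement_set"))
  recs <- pset$records
  if (length(recs) == 0L) .usage_error("pregroup: empty placement set")
  edge_sets <- lapply(recs, function(r)
    unique(r$rows$edge_num[r$rows$like_weight_ratio > 0]))
  uf <- .uf_new(length(recs))
  owner <- new.env(parent = emptyenv())
  for (i in seq_along(recs)) {
    for (e in edge_sets[[i]]) {
      key <- as.character(e)
      j <- get0(key, envir = owner)
      if (is.null(j)) assign(key, i, envir = owner)
      else uf <- .uf_union(uf, i, j)
    }
  }
  comp <- vapply(seq_along(recs), function(i) .uf_find(uf, i), 0L)
  lapply(split(seq_along(recs), comp), function(idx) {
    members <- names(recs)[idx]
    list(members = members,
         mass_edges = sort(unique(unlist(edge_sets[idx]))),
         lca_node = placement_lca(pset$tree, recs[idx]))
  })
}

#' Merge pre-groups whose LCAs are closer than the threshold
#'
#' Pre-groups whose lowest common ancestors lie closer together in
#' phylogenetic distance than the clustering threshold cannot safely be
#' clustered apart, so they are combined (transitively) before exhaustive
#' within-group distances are computed. Merging is strict: groups are
#' joined iff their LCA separation is `< threshold`.
#'
#' When one merged group's clade is nested inside another's, the LCA
#' separation no longer lower-bounds cross-pair distances; such nesting is
#' reported via a message so divergence from the exhaustive computation
#' can be audited.
#'
#' @param tree A `ref_tree`.
#' @param groups Output of [pregroup()].
#' @param threshold Positive clustering distance.
#' @return A list of merged `pre_group`s.
#' @export
merge_pregroups <- function(tree, groups, threshold) {
  stopifnot(threshold > 0)
  n <- length(groups)
  if (n <= 1L) return(groups)
  lcas <- vapply(groups, `[[`, 0L, "lca_node")
  uf <- .uf_new(n)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (.node_dist(tree, lcas[i], lcas[j]) < threshold)
      uf <- .uf_union(uf, i, j)
  }
  comp <- vapply(seq_len(n), function(i) .uf_find(uf, i), 0L)
  merged <- lapply(split(seq_len(n), comp), function(idx) {
    list(members = unlist(lapply(groups[idx], `[[`, "members"),
                          use.names = FALSE),
         mass_edges = sort(unique(unlist(lapply(groups[idx], `[[`,
                                                "mass_edges")))),
         lca_node = lca(tree, lcas[idx]))
  })
  ## audit: nested clades among merged groups break the separation bound
  if (length(merged) > 1L) {
    ml <- vapply(merged, `[[`, 0L, "lca_node")
    for (i in seq_along(ml)) for (j in seq_along(ml)) {
      if (i != j && .lca2(tree, ml[i], ml[j]) == ml[i] && ml[i] != ml[j]) {
        message(sprintf(
          "merge_pregroups: group %d's clade nests inside group %d's; divide-and-conquer may diverge from the exhaustive computation here",
          j, i))
        break
      }
    }
  }
  merged
}

## strict flat cut: perform merges with linkage height < threshold
.flat_cut <- function(D, threshold, linkage) {
  n <- nrow(D)
  if (n == 1L) return(stats::setNames(1L, rownames(D)))
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  k <- n - sum(hc$height < threshold)
  stats::cutree(hc, k = k)
}

#' Exhaustive clustering within one (merged) pre-group
#'
#' Hierarchical agglomerative clustering on the full pairwise KR distance
#' matrix of the group's members, merging while the linkage distance is
#' strictly below the threshold, and returning the flat partition at that
#' cut.
#'
#' @param tree A `ref_tree`.
#' @param group A `pre_group`.
#' @param pset The [placement_set()] holding the members' records.
#' @param threshold Positive clustering distance.
#' @param linkage One of "single", "average", "complete".
#' @param ... Passed to [pairwise_matrix()].
#' @return A list of character vectors, each one cluster of member ASV
#'   ids.
#' @export
cluster_group <- function(tree, group, pset, threshold,
                          linkage = c("single", "average", "complete"),
                          ...) {
  linkage <- match.arg(linkage)
  stopifnot(threshold > 0)
  members <- group$members
  if (length(members) == 1L) return(list(members))
  D <- pairwise_matrix(tree, pset$records[members], ...)
  cl <- .flat_cut(D, threshold, linkage)
  unname(split(members, cl))
}

#' Bin ASVs into phylotypes (divide-and-conquer)
#'
#' The core algorithm: ASVs are (1) pre-grouped by shared mass-bearing
#' placement edges, (2) pre-groups whose LCAs are closer than the
#' threshold are merged, (3) pairwise KR distances are computed
#' exhaustively only within each merged group, and (4) each group is
#' agglomeratively clustered at the threshold. The union of the per-group
#' partitions is the phylotype set; cross-group distances are never
#' computed because the LCA-separation bound guarantees they exceed the
#' threshold (for disjoint clades).
#'
#' @param pset A [placement_set()].
#' @param threshold Positive clustering distance (phylogenetic distance
#'   units); ASVs closer than this end up in one phylotype. Typical
#'   values: 0.1, 0.5, 1.
#' @param linkage Agglomerative linkage; "single" (the default) matches
#'   the operational definition that sequence variants less than the
#'   threshold apart are clustered together.
#' @param counts Optional specimen-by-ASV count matrix used to order
#'   phylotype names by descending total read count.
#' @param ... Passed to [pairwise_matrix()] (e.g. `best_only`,
#'   `include_pendant`).
#' @return A `phylotype_model`: list with `threshold`, `linkage`,
#'   `tree_digest`, `phylotypes` (name -> member ASV ids),
#'   `asv_to_phylotype`, and `phylotype_lca` (name -> node id).
#' @export
bin_phylotypes <- function(pset, threshold,
                           linkage = c("single", "average", "complete"),
                           counts = NULL, ...) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(pset, "placement_set"), threshold > 0)
  groups <- merge_pregroups(pset$tree, pregroup(pset), threshold)
  parts <- list()
  for (g in groups)
    parts <- c(parts, cluster_group(pset$tree, g, pset, threshold,
                                    linkage, ...))
  .finish_model(pset, parts, threshold, linkage, counts)
}

#' Exhaustive brute-force binning (verification oracle)
#'
#' The O(n^2) computation the divide-and-conquer avoids: the full pairwise
#' KR matrix over all records, one agglomerative clustering at the
#' threshold, and the same naming pipeline. Kept as the correctness
#' reference for [bin_phylotypes()]; refuses more than 5,000 records
#' unless `force = TRUE`.
#'
#' @inheritParams bin_phylotypes
#' @param force Override the size guard.
#' @return A `phylotype_model`.
#' @export
brute_force_bin <- function(pset, threshold,
                            linkage = c("single", "average", "complete"),
                            counts = NULL, force = FALSE, ...) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(pset, "placement_set"), threshold > 0)
  n <- length(pset$records)
  if (n > 5000L && !force)
    .usage_error("brute_force_bin: %d records exceeds the 5,000 guard (use force = TRUE)", n)
  D <- pairwise_matrix(pset$tree, pset$records, ...)
  cl <- .flat_cut(D, threshold, linkage)
  parts <- unname(split(names(pset$records), cl))
  .finish_model(pset, parts, threshold, linkage, counts)
}

.finish_model <- function(pset, parts, threshold, linkage, counts) {
  nm <- name_phylotypes(parts, threshold, counts)
  ord <- order(nm)
  parts <- parts[ord]; nm <- nm[ord]
  phylotypes <- stats::setNames(lapply(parts, sort), nm)
  asv_to_pt <- stats::setNames(rep(nm, lengths(phylotypes)),
                               unlist(phylotypes, use.names = FALSE))
  asv_to_pt <- asv_to_pt[names(pset$records)]
  lcas <- vapply(phylotypes, function(m)
    placement_lca(pset$tree, pset$records[m]), 0L)
  structure(list(threshold = threshold, linkage = linkage,
                 tree_digest = pset$tree$digest,
                 phylotypes = phylotypes,
                 asv_to_phylotype = asv_to_pt,
                 phylotype_lca = lcas),
            class = "phylotype_model")
}

#' @export
print.phylotype_model <- function(x, ...) {
  cat(sprintf("phylotype_model: %d phylotypes over %d ASVs (threshold %g, %s linkage)\n",
              length(x$phylotypes), length(x$asv_to_phylotype),
              x$threshold, x$linkage))
  invisible(x)
}

#' Name phylotypes
#'
#' Names follow the convention `pt<TT>__<IIIII>` where `TT` is the
#' zero-padded two-digit code `round(threshold * 10)` and `IIIII` a
#' zero-padded five-digit index starting at 00001 -- e.g. `pt05__00001`
#' for the most abundant phylotype binned at distance 0.5, `pt01__...` at
#' 0.1, `pt10__...` at 1.0. Indices are ordered by descending total read
#' count of the members when a count table is supplied, otherwise by
#' descending member count; ties break on the lexicographically smallest
#' member ASV id.
#'
#' @param partition A list of character vectors of member ASV ids.
#' @param threshold The binning threshold (must be < 10).
#' @param counts Optional specimen-by-ASV count matrix.
#' @param start_index First index to assign (default 1); used when
#'   appending phylotypes to an existing model.
#' @return Character vector of names, parallel to `partition`.
#' @export
name_phylotypes <- function(partition, threshold, counts = NULL,
                            start_index = 1L) {
  if (length(partition) == 0L)
    .usage_error("name_phylotypes: empty partition")
  if (threshold >= 10)
    .usage_error("threshold %g overflows the two-digit name code", threshold)
  size <- if (!is.null(counts)) {
    tot <- colSums(counts)
    vapply(partition, function(m) sum(tot[intersect(m, colnames(counts))]),
           0.0)
  } else lengths(partition)
  first <- vapply(partition, function(m) min(m), "")
  ord <- order(-size, first)
  idx <- integer(length(partition))
  idx[ord] <- seq_along(partition) + start_index - 1L
  sprintf("pt%02d__%05d", round(threshold * 10), idx)
}

#' Serialize a phylotype model to JSON
#'
#' Stores threshold, linkage, tree digest and the name -> member-list
#' mapping (plus per-phylotype LCA node ids); [read_phylotype_model()]
#' restores it.
#'
#' @param model A `phylotype_model`.
#' @param path Output path (written atomically).
#' @return Invisibly, `path`.
#' @export
write_phylotype_model <- function(model, path) {
  stopifnot(inherits(model, "phylotype_model"))
  out <- list(format = "phylobin_model",
              format_version = 1L,
              threshold = model$threshold,
              linkage = model$linkage,
              tree_digest = model$tree_digest,
              phylotype_lca = as.list(model$phylotype_lca),
              phylotypes = lapply(model$phylotypes, as.list))
  .write_atomic(path, function(tmp)
    jsonlite::write_json(out, tmp, auto_unbox = TRUE, digits = NA))
  invisible(path)
}

#' Read a phylotype model from JSON
#' @param path Path written by [write_phylotype_model()].
#' @return A `phylotype_model`.
#' @export
read_phylotype_model <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(js$format) || js$format != "phylobin_model")
    .format_error("%s is not a phylobin model file", path)
  phylotypes <- lapply(js$phylotypes, function(m) sort(unlist(m)))
  asv_to_pt <- stats::setNames(rep(names(phylotypes), lengths(phylotypes)),
                               unlist(phylotypes, use.names = FALSE))
  structure(list(threshold = js$threshold, linkage = js$linkage,
                 tree_digest = js$tree_digest,
                 phylotypes = phylotypes,
                 asv_to_phylotype = asv_to_pt,
                 phylotype_lca = vapply(js$phylotype_lca, as.integer, 0L)),
            class = "phylotype_model")
}

#' Write ASV-to-phylotype assignments as CSV
#' @param assignment Named character vector (names = ASV ids) or a
#'   `phylotype_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_assignments <- function(assignment, path) {
  if (inherits(assignment, "phylotype_model"))
    assignment <- assignment$asv_to_phylotype
  df <- data.frame(asv_id = names(assignment),
                   phylotype_name = unname(assignment))
  .write_atomic(path, function(tmp)
    utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE))
  invisible(path)
}

#' Read ASV-to-phylotype assignments from CSV
#' @param path A two-column CSV `asv_id,phylotype_name`.
#' @return Named character vector.
#' @export
read_assignments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) .format_error("assignment CSV needs two columns")
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}
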