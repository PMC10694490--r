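#' Recompute per-phylotype LCAs from seed placements
#'
#' Step 1 of post-hoc integration: the lowest common ancestor of each
#' existing phylotype's member placements. Equals the model's stored
#' `phylotype_lca` when the model was built from `seed_pset`.
#'
#' @param model A `phylotype_model`.
#' @param seed_pset The [placement_set()] the model was built from (same
#'   tree: digests must match).
#' @return Named integer vector, phylotype name -> node id.
#' @export
phylotype_lcas <- function(model, seed_pset) {
  stopifnot(inherits(model, "phylotype_model"),
            inherits(seed_pset, "placement_set"))
  .check_digest(model, seed_pset)
  missing <- setdiff(names(model$asv_to_phylotype), names(seed_pset$records))
  if (length(missing))
    .format_error("seed placement set lacks model member '%s'", missing[1L])
  vapply(model$phylotypes, function(m)
    placement_lca(seed_pset$tree, seed_pset$records[m]), 0L)
}

.check_digest <- function(model, pset) {
  if (!identical(model$tree_digest, pset$tree$digest))
    stop(errorCondition(
      "tree mismatch: placements were not made on the model's reference tree (phylotypes are only comparable on the same tree)",
      class = c("phylobin_compat_error", "phylobin_format_error", "error")))
}

#' Assign newly placed ASVs to existing phylotypes
#'
#' Steps 2-3 of post-hoc integration: for each new ASV, the KR distance
#' from its placement mass to every existing phylotype's LCA node is
#' computed, and the ASV is assigned to the phylotype with the smallest
#' distance provided that distance is strictly below the threshold (ties
#' break to the lowest phylotype index). ASVs farther than the threshold
#' from every LCA are left unassigned and may be spawned into new
#' phylotypes with [spawn_new_phylotypes()]. Existing memberships are
#' never altered.
#'
#' @param model A `phylotype_model`.
#' @param new_pset A [placement_set()] on the same tree (digest checked;
#'   a mismatch is refused rather than silently mis-harmonized).
#' @param threshold Assignment threshold; defaults to the model's binning
#'   threshold.
#' @param nearest_member If `TRUE`, distance to a phylotype is the
#'   minimum KR distance to any member's placement instead of the
#'   distance to the LCA node (sensitivity-analysis mode; requires
#'   `seed_pset`).
#' @param seed_pset Seed placements, only needed for
#'   `nearest_member = TRUE`.
#' @return A list with `assignments` (named character vector, ASV ->
#'   phylotype name) and `unassigned` (character vector of ASV ids).
#' @export
assign_new <- function(model, new_pset, threshold = model$threshold,
                       nearest_member = FALSE, seed_pset = NULL) {
  stopifnot(inherits(model, "phylotype_model"),
            inherits(new_pset, "placement_set"), threshold > 0)
  .check_digest(model, new_pset)
  tree <- new_pset$tree
  pt_names <- names(model$phylotypes)
  ## evaluate phylotypes in index order so ties break to the lowest index
  pt_names <- pt_names[order(pt_names)]
  assignments <- character(0)
  unassigned <- character(0)
  if (nearest_member) {
    if (is.null(seed_pset))
      .usage_error("nearest_member assignment requires seed_pset")
    .check_digest(model, seed_pset)
  }
  lcas <- model$phylotype_lca[pt_names]
  for (id in names(new_pset$records)) {
    m <- to_mass(new_pset$records[[id]])
    d <- if (nearest_member) {
      vapply(pt_names, function(pt) {
        min(vapply(model$phylotypes[[pt]], function(mem)
          kr_distance(tree, m, to_mass(seed_pset$records[[mem]])), 0.0))
      }, 0.0)
    } else {
      vapply(lcas, function(nd) distance_to_node(tree, m, nd), 0.0)
    }
    best <- which.min(d)      # first minimum = lowest index on ties
    if (d[best] < threshold) {
      assignments[id] <- pt_names[best]
    } else {
      unassigned <- c(unassigned, id)
    }
  }
  list(assignments = assignments, unassigned = unassigned)
}

#' Spawn new phylotypes from unassigned ASVs
#'
#' Bins the unassigned records at the model's threshold and linkage and
#' appends the resulting phylotypes with fresh names continuing the
#' model's index sequence; original phylotypes are untouched.
#'
#' @param model A `phylotype_model`.
#' @param unassigned_pset A [placement_set()] of the unassigned ASVs
#'   (same tree; members must be disjoint from the model's).
#' @return An extended `phylotype_model`.
#' @export
spawn_new_phylotypes <- function(model, unassigned_pset) {
  stopifnot(inherits(model, "phylotype_model"),
            inherits(unassigned_pset, "placement_set"))
  if (length(unassigned_pset$records) == 0L) return(model)
  .check_digest(model, unassigned_pset)
  overlap <- intersect(names(unassigned_pset$records),
                       names(model$asv_to_phylotype))
  if (length(overlap))
    .usage_error("ASV '%s' is already a model member", overlap[1L])
  tree <- unassigned_pset$tree
  groups <- merge_pregroups(tree, pregroup(unassigned_pset),
                            model$threshold)
  parts <- list()
  for (g in groups)
    parts <- c(parts, cluster_group(tree, g, unassigned_pset,
                                    model$threshold, model$linkage))
  max_idx <- max(as.integer(sub("^pt[0-9]+__", "", names(model$phylotypes))))
  nm <- name_phylotypes(parts, model$threshold,
                        start_index = max_idx + 1L)
  if (any(nm %in% names(model$phylotypes)))
    stop("internal error: spawned phylotype name collides", call. = FALSE)
  ord <- order(nm)
  parts <- parts[ord]; nm <- nm[ord]
  new_pts <- stats::setNames(lapply(parts, sort), nm)
  new_lca <- vapply(new_pts, function(m)
    placement_lca(tree, unassigned_pset$records[m]), 0L)
  model$phylotypes <- c(model$phylotypes, new_pts)
  model$phylotype_lca <- c(model$phylotype_lca, new_lca)
  add <- stats::setNames(rep(nm, lengths(new_pts)),
                         unlist(new_pts, use.names = FALSE))
  model$asv_to_phylotype <- c(model$asv_to_phylotype, add)
  model
}
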