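## tree arrays handed to the C++ sweep
.tree_arrays <- function(tree) {
  list(parent = tree$parent, brlen = tree$brlen, postorder = tree$postorder)
}

## mass_distribution -> resolved (node, clamped offset, weight, pendant)
.mass_arrays <- function(tree, m) {
  stopifnot(inherits(m, "mass_distribution"))
  node <- .edge_node(tree, m$edge_num)
  L <- tree$brlen[node]
  off <- m$offset
  bad <- off > L + 1e-6
  if (any(bad))
    stop(sprintf("attachment offset %g exceeds branch length %g on edge {%d}",
                 off[bad][1L], L[bad][1L], m$edge_num[bad][1L]),
         call. = FALSE)
  list(node = node, off = pmin(off, L), w = m$weight, pendant = m$pendant)
}

#' Kantorovich-Rubinstein distance between placement distributions
#'
#' The phylogenetic distance that phylotype binning clusters on: the
#' earth-mover (1-Wasserstein) distance between two placement mass
#' distributions under the reference tree's path metric, akin to weighted
#' UniFrac. With `exponent = 1` it equals the integral, over every tree
#' edge segment delimited by attachment points, of the absolute difference
#' in mass lying distal to the segment times segment length -- i.e. the
#' minimum-cost transport of P onto Q. Computed exactly by a single
#' post-order sweep; no approximation.
#'
#' @param tree A [ref_tree][parse_edge_numbered_newick].
#' @param P,Q [mass_distribution()]s on `tree`.
#' @param exponent Order of the metric (default 1, the standard KR
#'   distance; values > 1 give the Z^p generalization).
#' @param include_pendant If `TRUE`, each distribution's weighted mean
#'   pendant length is added to the transport cost (every unit of mass
#'   pays its row's pendant once); off by default.
#' @return Non-negative distance.
#' @export
kr_distance <- function(tree, P, Q, exponent = 1, include_pendant = FALSE) {
  stopifnot(inherits(tree, "ref_tree"), exponent >= 1)
  a <- .mass_arrays(tree, P)
  b <- .mass_arrays(tree, Q)
  ta <- .tree_arrays(tree)
  d <- kr_pair_cpp(ta$parent, ta$brlen, ta$postorder,
                   a$node, a$off, a$w, b$node, b$off, b$w,
                   as.numeric(exponent))
  if (include_pendant)
    d <- d + sum(a$w * a$pendant) + sum(b$w * b$pendant)
  d
}

#' LCA of the mass-bearing edges of placement records
#'
#' The lowest common ancestor over the distal (child) nodes of every edge
#' carrying placement mass across the given records. This is the anchor
#' node used when merging pre-groups and when assigning new ASVs
#' post hoc.
#'
#' @param tree A `ref_tree`.
#' @param records A single [placement_record()] or a list of them.
#' @return A node id.
#' @export
placement_lca <- function(tree, records) {
  if (inherits(records, "placement_record")) records <- list(records)
  if (length(records) == 0L) .usage_error("placement_lca: empty record set")
  edges <- unique(unlist(lapply(records, function(r)
    r$rows$edge_num[r$rows$like_weight_ratio > 0])))
  if (length(edges) == 0L)
    edges <- unique(unlist(lapply(records, function(r) r$rows$edge_num)))
  lca(tree, .edge_node(tree, edges))
}

## node-to-node path distance (root-edge-free; works for unnumbered root)
.node_dist <- function(tree, a, b) {
  anc <- .lca2(tree, a, b)
  tree$rootdist[a] + tree$rootdist[b] - 2 * tree$rootdist[anc]
}

#' Phylogenetic separation between two groups of records
#'
#' Path distance between the placement LCAs of two groups; the quantity
#' compared against the clustering threshold when deciding whether two
#' pre-groups must be merged before exhaustive within-group distances.
#'
#' @param tree A `ref_tree`.
#' @param groupA,groupB Lists of [placement_record()]s.
#' @return Non-negative distance.
#' @export
lca_separation <- function(tree, groupA, groupB) {
  .node_dist(tree, placement_lca(tree, groupA), placement_lca(tree, groupB))
}

#' KR distance from a mass distribution to a single node
#'
#' Exact point-target identity: the KR distance between `P` and a unit
#' point mass at `node` equals the weighted mean path distance from P's
#' points to the node, making post-hoc assignment linear in the number of
#' placement rows.
#'
#' @param tree A `ref_tree`.
#' @param P A [mass_distribution()].
#' @param node A node id (or leaf name).
#' @param include_pendant Add P's weighted mean pendant length.
#' @return Non-negative distance.
#' @export
distance_to_node <- function(tree, P, node, include_pendant = FALSE) {
  if (is.character(node)) node <- node_of_leaf(tree, node)
  node <- as.integer(node)
  if (length(node) != 1L || is.na(node) || node < 1L || node > tree$n_node)
    stop("unknown node", call. = FALSE)
  a <- .mass_arrays(tree, P)
  d <- sum(a$w * vapply(seq_along(a$node), function(i)
    .point_node_dist(tree, a$node[i], a$off[i], node), 0.0))
  if (include_pendant) d <- d + sum(a$w * a$pendant)
  d
}

#' Pairwise KR distance matrix over placement records
#'
#' @param tree A `ref_tree`.
#' @param records A list of [placement_record()]s or a [placement_set()].
#' @param exponent,include_pendant As in [kr_distance()].
#' @param best_only If `TRUE`, each record is reduced to a point mass at
#'   its best (highest-lwr) placement before distances are computed.
#' @return A symmetric matrix with zero diagonal, dimnames = ASV ids.
#' @export
pairwise_matrix <- function(tree, records, exponent = 1,
                            include_pendant = FALSE, best_only = FALSE) {
  if (inherits(records, "placement_set")) records <- records$records
  if (inherits(records, "placement_record")) records <- list(records)
  if (length(records) == 0L) .usage_error("pairwise_matrix: no records")
  masses <- lapply(records, to_mass, best_only = best_only)
  arrs <- lapply(masses, .mass_arrays, tree = tree)
  node <- unlist(lapply(arrs, `[[`, "node"))
  off <- unlist(lapply(arrs, `[[`, "off"))
  w <- unlist(lapply(arrs, `[[`, "w"))
  starts <- c(0L, cumsum(vapply(arrs, function(a) length(a$node), 0L)))
  ta <- .tree_arrays(tree)
  D <- kr_pairwise_cpp(ta$parent, ta$brlen, ta$postorder,
                       as.integer(node), off, w, as.integer(starts),
                       as.numeric(exponent))
  if (include_pendant) {
    mp <- vapply(arrs, function(a) sum(a$w * a$pendant), 0.0)
    D <- D + outer(mp, mp, `+`)
    diag(D) <- 0
  }
  ids <- unname(vapply(records, function(r) r$asv_id, ""))
  dimnames(D) <- list(ids, ids)
  D
}
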