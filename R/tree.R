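#' @useDynLib phylobin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Reference tree with jplace edge numbering
#'
#' A `ref_tree` is a rooted phylogeny whose every edge carries the integer
#' `{N}` label used by the jplace placement format. It is the coordinate
#' system for all placement distances: ASVs are located as points on its
#' edges, and phylotype binning clusters ASVs by path distance between
#' those points.
#'
#' Internally the tree is stored as flat parent/branch-length vectors
#' indexed by node id (tips first, as in [ape::read.tree()]), which keeps
#' lowest-common-ancestor and path-distance queries cheap. Node ids are
#' deterministic for a given newick string, so results are stable across
#' runs.
#'
#' @param text A newick string in the jplace dialect: branch lengths
#'   mandatory, every edge annotated with a bracketed integer `{N}`. The
#'   annotation is accepted either after the branch length (`A:0.1{0}`,
#'   the common pplacer/epa-ng form) or between the label and the colon
#'   (`A{0}:0.1`), since placement engines differ. The outermost node of
#'   the file is taken as the root; a numbered root edge (e.g. `:0{6};`)
#'   is retained as an edge of the tree.
#'
#' @return An object of class `ref_tree`: a list with elements
#'   \describe{
#'     \item{n_node, n_tip, root}{node counts and root id}
#'     \item{parent}{integer vector, parent id per node (0 for the root)}
#'     \item{brlen}{branch length of the edge above each node
#'       (substitutions/site); the root's entry is its root-edge length,
#'       0 when absent}
#'     \item{edge_num}{jplace edge number of the edge above each node
#'       (`NA` only for an unnumbered root)}
#'     \item{tip_label}{leaf name per node (`NA` for internal nodes)}
#'     \item{rootdist}{sum of branch lengths from each node up to the
#'       root node (excluding the root edge)}
#'   }
#'
#' @examples
#' tr <- parse_edge_numbered_newick(
#'   "((A:0.1{0},B:0.2{1}):0.3{2},(C:0.4{3},D:0.5{4}):0.6{5}):0{6};")
#' tip_to_root_depths(tr)
#' @export
parse_edge_numbered_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty newick string", call. = FALSE)
  if (grepl("@@", text, fixed = TRUE))
    stop("newick labels may not contain '@@'", call. = FALSE)
  if (!grepl("\\{[0-9]+\\}", text))
    stop("newick has no {N} edge numbers; not a jplace tree string",
         call. = FALSE)
  ## single-leaf file: wrap so the leaf hangs off a root node
  if (!grepl("(", text, fixed = TRUE))
    text <- paste0("(", sub(";\\s*$", "", text), ");")

  ## Fold {N} annotations into node labels so ape can parse the rest:
  ##   'A:0.1{0}' -> 'A@@0:0.1'   and   'A{0}:0.1' -> 'A@@0:0.1'
  txt <- gsub(":([0-9eE.+-]+)\\{([0-9]+)\\}", "@@\\2:\\1", text)
  txt <- gsub("\\{([0-9]+)\\}", "@@\\1", txt)
  if (grepl("[{}]", txt))
    stop("malformed {N} edge annotation in newick", call. = FALSE)

  phy <- tryCatch(ape::read.tree(text = txt),
                  error = function(e) NULL)
  if (is.null(phy) || !inherits(phy, "phylo"))
    stop("could not parse newick tree", call. = FALSE)

  n_tip <- length(phy$tip.label)
  n_node <- n_tip + phy$Nnode
  root <- n_tip + 1L

  parent <- integer(n_node)
  brlen <- numeric(n_node)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  brlen[phy$edge[, 2L]] <- phy$edge.length
  if (!is.null(phy$root.edge)) brlen[root] <- phy$root.edge
  if (any(brlen < 0))
    stop("negative branch length in newick tree", call. = FALSE)

  split_tag <- function(lab) {
    m <- regmatches(lab, regexec("^(.*)@@([0-9]+)$", lab))[[1L]]
    if (length(m) == 3L) list(label = m[2L], num = as.integer(m[3L]))
    else list(label = lab, num = NA_integer_)
  }

  edge_num <- rep(NA_integer_, n_node)
  tip_label <- rep(NA_character_, n_node)
  for (i in seq_len(n_tip)) {
    s <- split_tag(phy$tip.label[i])
    if (is.na(s$num))
      stop(sprintf("edge above leaf '%s' has no {N} edge number", s$label),
           call. = FALSE)
    edge_num[i] <- s$num
    tip_label[i] <- s$label
  }
  node_label <- rep(NA_character_, n_node)
  if (!is.null(phy$node.label)) {
    for (j in seq_len(phy$Nnode)) {
      id <- n_tip + j
      lab <- phy$node.label[j]
      if (is.na(lab) || !nzchar(lab)) lab <- ""
      s <- split_tag(lab)
      edge_num[id] <- s$num
      if (nzchar(s$label)) node_label[id] <- s$label
    }
  }
  internal_missing <- which(is.na(edge_num) & seq_len(n_node) != root)
  if (length(internal_missing))
    stop(sprintf("%d internal edge(s) missing {N} edge numbers (e.g. above node %d)",
                 length(internal_missing), internal_missing[1L]), call. = FALSE)
  nums <- edge_num[!is.na(edge_num)]
  if (anyDuplicated(nums))
    stop(sprintf("duplicate edge number {%d}", nums[duplicated(nums)][1L]),
         call. = FALSE)
  if (anyDuplicated(tip_label[seq_len(n_tip)]))
    stop("duplicate leaf names in tree", call. = FALSE)

  ## children lists (in newick sibling order, so serialization round
  ## trips to identical node numbering) + preorder/postorder + depths
  kids <- vector("list", n_node)
  for (k in seq_len(nrow(phy$edge)))
    kids[[phy$edge[k, 1L]]] <- c(kids[[phy$edge[k, 1L]]], phy$edge[k, 2L])
  pre <- integer(n_node)
  depth <- integer(n_node)
  rootdist <- numeric(n_node)
  stack <- root; k <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    k <- k + 1L; pre[k] <- v
    for (ch in kids[[v]]) {
      depth[ch] <- depth[v] + 1L
      rootdist[ch] <- rootdist[v] + brlen[ch]
      stack <- c(stack, ch)
    }
  }

  lookup <- integer(0)
  lookup[as.character(edge_num[!is.na(edge_num)])] <-
    which(!is.na(edge_num))

  tr <- structure(list(
    n_node = n_node, n_tip = n_tip, root = root,
    parent = parent, brlen = brlen, edge_num = edge_num,
    tip_label = tip_label, node_label = node_label,
    children = kids, preorder = pre, postorder = rev(pre),
    depth = depth, rootdist = rootdist, edge_lookup = lookup
  ), class = "ref_tree")
  tr$newick <- write_edge_numbered_newick(tr)
  tr$digest <- tree_digest(tr)
  tr
}

#' Serialize a reference tree back to jplace newick
#'
#' Emits branch lengths with 12 significant digits and the `{N}` edge
#' number after each branch length, so the output parses back to an
#' equivalent tree.
#'
#' @param tree A [ref_tree][parse_edge_numbered_newick].
#' @return A single newick string.
#' @export
write_edge_numbered_newick <- function(tree) {
  stopifnot(inherits(tree, "ref_tree"))
  fmt_len <- function(x) sprintf("%.12g", x)
  build <- function(v) {
    lab <- if (v <= tree$n_tip) tree$tip_label[v]
           else {
             nl <- tree$node_label[v]
             core <- paste0("(", paste(vapply(tree$children[[v]], build, ""),
                                       collapse = ","), ")")
             if (!is.na(nl)) paste0(core, nl) else core
           }
    if (v == tree$root) {
      tag <- if (!is.na(tree$edge_num[v]))
        paste0(":", fmt_len(tree$brlen[v]), "{", tree$edge_num[v], "}")
      else ""
      return(paste0(lab, tag, ";"))
    }
    paste0(lab, ":", fmt_len(tree$brlen[v]), "{", tree$edge_num[v], "}")
  }
  build(tree$root)
}

#' @export
print.ref_tree <- function(x, ...) {
  cat(sprintf("ref_tree: %d tips, %d nodes, %d numbered edges\n",
              x$n_tip, x$n_node, sum(!is.na(x$edge_num))))
  invisible(x)
}

#' Stable digest of a reference tree
#'
#' MD5 of the canonical serialized newick; stored in phylotype models so
#' post-hoc assignment can refuse placements made on a different tree
#' (phylotypes are only comparable when generated against the same
#' phylogeny).
#'
#' @param tree A `ref_tree`.
#' @return A hex digest string.
#' @export
tree_digest <- function(tree) {
  stopifnot(inherits(tree, "ref_tree"))
  nwk <- if (!is.null(tree$newick)) tree$newick
         else write_edge_numbered_newick(tree)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(nwk, tf)
  unname(tools::md5sum(tf))
}

#' Look up the tree node id of a leaf name
#' @param tree A `ref_tree`.
#' @param label Leaf name(s).
#' @return Integer node id(s).
#' @export
node_of_leaf <- function(tree, label) {
  idx <- match(label, tree$tip_label[seq_len(tree$n_tip)])
  if (anyNA(idx))
    stop(sprintf("leaf '%s' not in tree", label[which(is.na(idx))[1L]]),
         call. = FALSE)
  idx
}

#' A point on a tree edge
#'
#' Identifies a location on the reference tree by jplace edge number and
#' offset from the distal (child/leaf-ward) end of that edge -- the same
#' coordinate the jplace `distal_length` field uses. Offsets exceeding
#' the branch length by at most 1e-6 are clamped (placement engines emit
#' tiny overshoots); larger overshoots are errors.
#'
#' @param edge_num Integer jplace edge number.
#' @param offset Non-negative distance from the distal end of the edge.
#' @return A `tree_point` (list with `edge_num`, `offset`).
#' @export
tree_point <- function(edge_num, offset = 0) {
  structure(list(edge_num = as.integer(edge_num), offset = as.numeric(offset)),
            class = "tree_point")
}

## edge number -> child node id, with validation
.edge_node <- function(tree, edge_num) {
  v <- tree$edge_lookup[as.character(edge_num)]
  if (anyNA(v))
    stop(sprintf("edge number {%s} not in tree",
                 edge_num[which(is.na(v))[1L]]), call. = FALSE)
  unname(v)
}

## validate/clamp a tree_point, returning (node, offset)
.resolve_point <- function(tree, p) {
  stopifnot(inherits(p, "tree_point"))
  v <- .edge_node(tree, p$edge_num)
  off <- p$offset
  L <- tree$brlen[v]
  if (off < 0) stop("negative attachment offset", call. = FALSE)
  if (off > L + 1e-6)
    stop(sprintf("attachment offset %g exceeds branch length %g on edge {%d}",
                 off, L, p$edge_num), call. = FALSE)
  list(node = v, offset = min(off, L))
}

#' Lowest common ancestor of a set of nodes
#'
#' @param tree A `ref_tree`.
#' @param nodes Integer node ids, or leaf names (characters).
#' @return The node id of the deepest node that is an ancestor-or-self of
#'   every node in the set.
#' @export
lca <- function(tree, nodes) {
  stopifnot(inherits(tree, "ref_tree"))
  if (is.character(nodes)) nodes <- node_of_leaf(tree, nodes)
  nodes <- as.integer(nodes)
  if (length(nodes) == 0L) stop("empty node set", call. = FALSE)
  if (any(nodes < 1L | nodes > tree$n_node))
    stop("node id out of range", call. = FALSE)
  Reduce(function(a, b) .lca2(tree, a, b), nodes)
}

.lca2 <- function(tree, a, b) {
  while (tree$depth[a] > tree$depth[b]) a <- tree$parent[a]
  while (tree$depth[b] > tree$depth[a]) b <- tree$parent[b]
  while (a != b) { a <- tree$parent[a]; b <- tree$parent[b] }
  a
}

## distance from a resolved point (node v, offset o above v) to a node a.
.point_node_dist <- function(tree, v, o, a) {
  anc <- .lca2(tree, v, a)
  if (anc == a && a != v) {
    ## a is a strict ancestor of v: the point lies between them
    tree$rootdist[v] - o - tree$rootdist[a]
  } else if (anc == v) {
    ## a is v itself or a descendant: up from a to v, then up into the edge
    tree$rootdist[a] - tree$rootdist[v] + o
  } else {
    (tree$rootdist[v] - o - tree$rootdist[anc]) +
      (tree$rootdist[a] - tree$rootdist[anc])
  }
}

#' Path distance between two points on the tree
#'
#' Total branch length along the unique path between two attachment
#' points; the base metric under which placements are compared.
#'
#' @param tree A `ref_tree`.
#' @param p,q [tree_point()]s.
#' @return Non-negative distance (substitutions/site).
#' @export
path_distance <- function(tree, p, q) {
  rp <- .resolve_point(tree, p)
  rq <- .resolve_point(tree, q)
  if (rp$node == rq$node) return(abs(rp$offset - rq$offset))
  anc <- .lca2(tree, rp$node, rq$node)
  if (anc == rp$node) {
    ## q lies below p's edge: climb from q to node rp, then up to the point
    (tree$rootdist[rq$node] - rq$offset - tree$rootdist[rp$node]) + rp$offset
  } else if (anc == rq$node) {
    (tree$rootdist[rp$node] - rp$offset - tree$rootdist[rq$node]) + rq$offset
  } else {
    (tree$rootdist[rp$node] - rp$offset - tree$rootdist[anc]) +
      (tree$rootdist[rq$node] - rq$offset - tree$rootdist[anc])
  }
}

#' Tip-to-root depths
#'
#' Sum of branch lengths from each leaf to the root node. The shape of
#' this distribution is what motivates the choice of binning thresholds:
#' clustering distances are chosen relative to typical tip-to-root depth
#' of the reference phylogeny.
#'
#' @param tree A `ref_tree`.
#' @return A data.frame with columns `leaf_name` and `depth`, one row per
#'   leaf.
#' @export
tip_to_root_depths <- function(tree) {
  stopifnot(inherits(tree, "ref_tree"))
  tips <- seq_len(tree$n_tip)
  data.frame(leaf_name = tree$tip_label[tips],
             depth = tree$rootdist[tips],
             stringsAsFactors = FALSE)
}
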