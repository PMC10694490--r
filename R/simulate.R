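#' Simulate a reference tree
#'
#' Random bifurcating topology by Yule-style sequential attachment (a
#' uniformly chosen leaf is split into a cherry until `n_leaves` tips
#' exist) with independent exponential branch lengths of mean
#' `branch_scale`. Edges receive jplace numbers; the result is a fully
#' valid [ref_tree][parse_edge_numbered_newick] and deterministic for a
#' fixed seed.
#'
#' @param n_leaves Number of tips (>= 2).
#' @param seed Integer RNG seed.
#' @param branch_scale Mean branch length (substitutions/site).
#' @return A `ref_tree` with leaves named `L0001`, `L0002`, ...
#' @export
simulate_tree <- function(n_leaves, seed, branch_scale = 0.1) {
  if (n_leaves < 2L) .usage_error("simulate_tree needs n_leaves >= 2")
  stopifnot(branch_scale > 0)
  withr::with_seed(seed, {
    ## node 1 = root; children list grown by splitting random leaves
    kids <- list(c(2L, 3L), integer(0), integer(0))
    leaves <- c(2L, 3L)
    while (length(leaves) < n_leaves) {
      pick <- leaves[sample.int(length(leaves), 1L)]
      a <- length(kids) + 1L; b <- a + 1L
      kids[[pick]] <- c(a, b)
      kids[[a]] <- integer(0); kids[[b]] <- integer(0)
      leaves <- c(setdiff(leaves, pick), a, b)
    }
    n_nodes <- length(kids)
    brlen <- stats::rexp(n_nodes, rate = 1 / branch_scale)
    is_leaf <- lengths(kids) == 0L
    leaf_name <- character(n_nodes)
    leaf_name[is_leaf] <- sprintf("L%04d", seq_len(sum(is_leaf)))
    counter <- new.env(parent = emptyenv()); counter$k <- -1L
    build <- function(v) {
      counter$k <- counter$k + 1L
      tag <- sprintf(":%.10g{%d}", brlen[v], counter$k)
      if (is_leaf[v]) return(paste0(leaf_name[v], tag))
      paste0("(", paste(vapply(kids[[v]], build, ""), collapse = ","),
             ")", tag)
    }
    inner <- paste(vapply(kids[[1L]], build, ""), collapse = ",")
    counter$k <- counter$k + 1L
    nwk <- sprintf("(%s):0{%d};", inner, counter$k)
    parse_edge_numbered_newick(nwk)
  })
}

#' Simulate placements with known allele of origin
#'
#' Emulates the in-silico validation design: `n_alleles` source leaves
#' are chosen pairwise at least `min_separation` apart (greedy rejection
#' over a shuffled leaf order; an explicit error suggests fewer alleles
#' when impossible), and for every (allele, primer) pair one ASV is
#' emitted whose placement mass lies within path distance `dispersion` of
#' the source leaf -- mimicking how amplicons of one allele amplified
#' with primers targeting different variable regions place into the same
#' small subclade. Point weights come from a symmetric Dirichlet draw.
#'
#' Dispersion is modeled geometrically (mass near the source leaf) rather
#' than by simulating sequences through a placement engine: this isolates
#' the binning algorithm under test with a controllable ground truth.
#'
#' @param tree A `ref_tree`.
#' @param n_alleles Number of source alleles (each a distinct leaf).
#' @param primers Character vector of primer labels; one ASV per
#'   (allele, primer). Default: five primer pairs commonly used for 16S
#'   variable regions.
#' @param dispersion Maximum path distance of any mass point from the
#'   source leaf (0 = point mass at the leaf).
#' @param points_per_placement Candidate attachment rows per ASV.
#' @param min_separation Minimum pairwise path distance between source
#'   leaves.
#' @param seed Integer RNG seed.
#' @return A list: `pset` (a [placement_set()]), `truth` (a data.frame
#'   `asv_id`, `allele`, `primer` -- the truth map accuracy metrics are
#'   computed against).
#' @export
simulate_placements <- function(tree, n_alleles,
                                primers = c("p27f_338r", "p357f_806r",
                                            "p515f_806r", "p515f_926r",
                                            "p968f_1497r"),
                                dispersion = 0.01,
                                points_per_placement = 3L,
                                min_separation = 0.5, seed = 1L) {
  stopifnot(inherits(tree, "ref_tree"), dispersion >= 0,
            points_per_placement >= 1L)
  if (n_alleles > tree$n_tip)
    .usage_error("n_alleles exceeds the number of leaves")
  withr::with_seed(seed, {
    tips <- sample(seq_len(tree$n_tip))
    chosen <- integer(0)
    for (tp in tips) {
      if (length(chosen) == n_alleles) break
      ok <- all(vapply(chosen, function(c2)
        .node_dist(tree, tp, c2) >= min_separation, TRUE))
      if (ok) chosen <- c(chosen, tp)
    }
    if (length(chosen) < n_alleles)
      stop(sprintf(
        "could only place %d of %d alleles at min_separation %g; use fewer alleles, a larger tree, or a smaller separation",
        length(chosen), n_alleles, min_separation), call. = FALSE)

    records <- list()
    truth <- vector("list", n_alleles * length(primers))
    i <- 0L
    for (leaf in chosen) {
      for (pr in primers) {
        i <- i + 1L
        id <- sprintf("asv%05d", i)
        u <- sort(stats::runif(points_per_placement, 0, dispersion))
        pts <- lapply(u, function(d) .walk_up(tree, leaf, d))
        edge_num <- vapply(pts, `[[`, 0L, "edge_num")
        off <- vapply(pts, `[[`, 0.0, "offset")
        w <- stats::rexp(points_per_placement)
        w <- w / sum(w)
        ## collapse duplicate attachment points (dispersion 0 etc.)
        key <- paste(edge_num, signif(off, 12))
        if (anyDuplicated(key)) {
          w <- as.numeric(tapply(w, key, sum)[unique(key)])
          first <- !duplicated(key)
          edge_num <- edge_num[first]; off <- off[first]
        }
        rows <- data.frame(edge_num = edge_num,
                           likelihood = log(w) - 1000,
                           like_weight_ratio = w,
                           distal_length = off,
                           pendant_length = stats::runif(length(w),
                                                         0.001, 0.02))
        records[[id]] <- placement_record(id, rows)
        truth[[i]] <- data.frame(asv_id = id,
                                 allele = tree$tip_label[leaf],
                                 primer = pr)
      }
    }
    list(pset = placement_set(tree, records),
         truth = do.call(rbind, truth))
  })
}

## point at path distance d rootward of a leaf, clamped at the root
.walk_up <- function(tree, leaf, d) {
  v <- leaf
  repeat {
    L <- tree$brlen[v]
    if (d <= L || tree$parent[v] == 0L)
      return(tree_point(tree$edge_num[v], min(d, L)))
    d <- d - L
    v <- tree$parent[v]
  }
}

#' Simulate specimen-by-ASV counts
#'
#' Each specimen is "sequenced" with one primer (cycled through the truth
#' map's primers), with log-normal allele abundances and multinomial read
#' sampling at the target depth, reflecting typical per-platform read
#' depths (50,000 for MiSeq-like, 5,000 for 454-like runs). Row sums
#' equal `depth` exactly.
#'
#' @param truth Truth map from [simulate_placements()].
#' @param n_specimens Number of specimens.
#' @param depth Reads per specimen.
#' @param seed Integer RNG seed.
#' @param sigma Log-normal sd of allele abundances (default 2, a
#'   gut-like rank-abundance spread).
#' @return Specimen-by-ASV integer count matrix (one column per ASV in
#'   the truth map).
#' @export
simulate_counts <- function(truth, n_specimens, depth = 50000L, seed = 1L,
                            sigma = 2) {
  stopifnot(depth > 0, n_specimens >= 1L)
  alleles <- unique(truth$allele)
  primers <- unique(truth$primer)
  withr::with_seed(seed, {
    m <- matrix(0L, n_specimens, nrow(truth),
                dimnames = list(sprintf("sp%03d", seq_len(n_specimens)),
                                truth$asv_id))
    for (s in seq_len(n_specimens)) {
      pr <- primers[(s - 1L) %% length(primers) + 1L]
      ab <- stats::rlnorm(length(alleles), 0, sigma)
      reads <- stats::rmultinom(1L, depth, ab / sum(ab))[, 1L]
      cols <- truth$asv_id[match(paste(alleles, pr),
                                 paste(truth$allele, truth$primer))]
      m[s, cols] <- as.integer(reads)
    }
    m
  })
}

.as_assignment <- function(assignment) {
  if (inherits(assignment, "phylotype_model"))
    assignment <- assignment$asv_to_phylotype
  assignment
}

#' Mean source alleles per phylotype (lumping metric)
#'
#' For each phylotype, the number of distinct source alleles among its
#' member ASVs; the mean over phylotypes. A value of 1 means no lumping:
#' no phylotype mixes amplicons from different alleles.
#'
#' @param assignment Named character vector ASV -> phylotype (or a
#'   `phylotype_model`).
#' @param truth Truth map data.frame (`asv_id`, `allele`, `primer`).
#' @return A list: `mean` and `per_phylotype` (data.frame `phylotype`,
#'   `n_alleles`).
#' @export
alleles_per_phylotype <- function(assignment, truth) {
  assignment <- .as_assignment(assignment)
  miss <- setdiff(names(assignment), truth$asv_id)
  if (length(miss))
    .format_error("ASV '%s' missing from the truth map", miss[1L])
  allele <- truth$allele[match(names(assignment), truth$asv_id)]
  per <- tapply(allele, assignment, function(a) length(unique(a)))
  list(mean = mean(per),
       per_phylotype = data.frame(phylotype = names(per),
                                  n_alleles = as.integer(per),
                                  row.names = NULL))
}

#' Mean phylotypes per source allele (splitting metric)
#'
#' For each source allele, the number of distinct phylotypes containing
#' at least one of its ASVs; the mean over alleles. A value of 1 means no
#' splitting: all amplicons of an allele -- across every primer -- landed
#' in one phylotype.
#'
#' @inheritParams alleles_per_phylotype
#' @return A list: `mean` and `per_allele` (data.frame `allele`,
#'   `n_phylotypes`).
#' @export
phylotypes_per_allele <- function(assignment, truth) {
  assignment <- .as_assignment(assignment)
  miss <- setdiff(names(assignment), truth$asv_id)
  if (length(miss))
    .format_error("ASV '%s' missing from the truth map", miss[1L])
  allele <- truth$allele[match(names(assignment), truth$asv_id)]
  per <- tapply(assignment, allele, function(p) length(unique(p)))
  list(mean = mean(per),
       per_allele = data.frame(allele = names(per),
                               n_phylotypes = as.integer(per),
                               row.names = NULL))
}

#' Rarefaction curve of unique features
#'
#' Pools the table's reads and, for each depth, subsamples that many
#' reads without replacement `reps` times, counting features observed at
#' least once; the granularity measure used to compare feature sets
#' (raw ASVs versus phylotypes at several thresholds).
#'
#' @param counts Specimen-by-feature count matrix.
#' @param depths Integer vector of subsampling depths.
#' @param reps Subsampling replicates per depth (default 100).
#' @param seed Integer RNG seed.
#' @return A data.frame `depth`, `mean_features`.
#' @export
rarefaction_curve <- function(counts, depths, reps = 100L, seed = 1L) {
  stopifnot(all(depths > 0), reps >= 1L)
  totals <- colSums(counts)
  totals <- totals[totals > 0]
  N <- sum(totals)
  depths <- as.integer(depths)
  if (any(depths > N)) {
    warning(sprintf("depth(s) above the %d total reads capped", N))
    depths[depths > N] <- N
  }
  breaks <- cumsum(totals)
  withr::with_seed(seed, {
    means <- vapply(depths, function(d) {
      mean(vapply(seq_len(reps), function(r) {
        idx <- sample.int(N, d)
        length(unique(findInterval(idx - 1L, breaks) + 1L))
      }, 0L))
    }, 0.0)
    data.frame(depth = depths, mean_features = means)
  })
}
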