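# Identity-distance computation, UPGMA tree construction and tiered
# haplogroup partitioning.

#' Identity distance between two genotype columns
#'
#' The distance between two haplotypes is the number of mismatched calls
#' divided by the number of positions compared. Positions where either
#' sample is missing (`N` or `-`) are excluded from both counts. A pair
#' with no informative overlap gets the maximal distance 1 together with
#' a zero-overlap warning.
#'
#' @param a,b equal-length character vectors of genotype symbols.
#' @return list with `d` (distance in \[0,1\]) and `compared` (number of
#'   informative positions).
#' @export
pairwise_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop("genotype columns must have equal length", call. = FALSE)
  }
  keep <- !is_missing_symbol(a) & !is_missing_symbol(b)
  compared <- sum(keep)
  if (compared == 0L) {
    warning("zero informative overlap between columns; distance set to 1",
            call. = FALSE)
    return(list(d = 1.0, compared = 0L))
  }
  list(d = sum(a[keep] != b[keep]) / compared, compared = compared)
}

#' All-pairs identity distance matrix
#'
#' Computes [pairwise_distance()] for every pair of samples in `m`,
#' optionally restricted to a region first. Ambiguity codes are ordinary
#' symbols here: `R` vs `A` counts as a mismatch, `R` vs `R` as a match.
#'
#' @param m an [snp_matrix()] with at least two samples.
#' @param r optional [region()]; if given, `m` is sliced to it first.
#' @return object of class `dist_matrix`: list with `samples`, `d`
#'   (symmetric matrix in \[0,1\], zero diagonal) and `compared`
#'   (symmetric integer matrix of informative position counts; the
#'   diagonal counts each sample's non-missing cells).
#' @export
distance_matrix <- function(m, r = NULL) {
  stopifnot(inherits(m, "snp_matrix"))
  if (!is.null(r)) m <- slice_region(m, r)
  n <- length(m$samples)
  if (n < 2L) stop("distance_matrix needs at least 2 samples", call. = FALSE)
  present <- !is_missing_symbol(m$calls)
  dim(present) <- dim(m$calls)
  d <- matrix(0, n, n, dimnames = list(m$samples, m$samples))
  cmp <- matrix(0L, n, n, dimnames = list(m$samples, m$samples))
  diag(cmp) <- as.integer(colSums(present))
  zero_overlap <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      keep <- present[, i] & present[, j]
      nc <- sum(keep)
      cmp[i, j] <- cmp[j, i] <- as.integer(nc)
      if (nc == 0L) {
        d[i, j] <- d[j, i] <- 1.0
        zero_overlap <- c(zero_overlap,
                          paste(m$samples[i], m$samples[j], sep = "/"))
      } else {
        dij <- sum(m$calls[keep, i] != m$calls[keep, j]) / nc
        d[i, j] <- d[j, i] <- dij
      }
    }
  }
  if (length(zero_overlap) > 0L) {
    warning(sprintf("zero informative overlap for pair(s) %s; distance set to 1",
                    paste(zero_overlap, collapse = ", ")), call. = FALSE)
  }
  structure(list(samples = m$samples, d = d, compared = cmp,
                 zero_overlap_pairs = zero_overlap),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %d samples; distances in [%.4f, %.4f]\n",
              length(x$samples), min(x$d), max(x$d[upper.tri(x$d)])))
  invisible(x)
}

# ---- UPGMA ------------------------------------------------------------

# Tree nodes are nested lists. Leaf: list(leaf = name, height = 0).
# Internal: list(children = list(a, b), height = h). The root carries
# class "haplo_tree".

new_leaf <- function(name) list(leaf = name, height = 0)

tree_leaves <- function(node) {
  if (!is.null(node$leaf)) return(node$leaf)
  unlist(lapply(node$children, tree_leaves), use.names = FALSE)
}

#' Leaf names of a haplotype tree
#' @param t a `haplo_tree`.
#' @return character vector of leaf names in left-to-right display order.
#' @export
leaf_display_order <- function(t) {
  stopifnot(inherits(t, "haplo_tree"))
  tree_leaves(t)
}

#' UPGMA tree from an identity distance matrix
#'
#' Standard unweighted pair-group clustering with arithmetic mean:
#' repeatedly merge the two clusters with the smallest size-weighted
#' average inter-cluster distance; the merge node sits at half the merge
#' distance, so the tree is rooted and ultrametric.
#'
#' Two rules make the output deterministic. Among tied minimal-distance
#' pairs, the pair whose (smaller, larger) original-sample-index
#' signature is lexicographically least is merged (a cluster's signature
#' is the smallest input index among its members). Within a merge node
#' the child containing the lexicographically smallest leaf name comes
#' first, fixing the display and Newick order.
#'
#' @param dm a `dist_matrix` from [distance_matrix()], n >= 2.
#' @return object of class `haplo_tree`.
#' @export
upgma <- function(dm) {
  stopifnot(inherits(dm, "dist_matrix"))
  n <- length(dm$samples)
  if (n < 2L) stop("upgma needs at least 2 samples", call. = FALSE)
  if (any(is.na(dm$d))) stop("distance matrix contains NaN/NA", call. = FALSE)

  nodes <- lapply(dm$samples, new_leaf)
  sizes <- rep(1L, n)
  sig <- seq_len(n)            # smallest original sample index per cluster
  d <- dm$d
  active <- rep(TRUE, n)

  while (sum(active) > 1L) {
    idx <- which(active)
    best <- NULL
    for (ii in seq_along(idx)) {
      for (jj in seq_along(idx)) {
        if (jj <= ii) next
        i <- idx[ii]; j <- idx[jj]
        cand <- list(i = i, j = j, dist = d[i, j],
                     sig = sort(c(sig[i], sig[j])))
        if (is.null(best) ||
            cand$dist < best$dist - 1e-15 ||
            (abs(cand$dist - best$dist) <= 1e-15 &&
             (cand$sig[1] < best$sig[1] ||
              (cand$sig[1] == best$sig[1] && cand$sig[2] < best$sig[2])))) {
          best <- cand
        }
      }
    }
    i <- best$i; j <- best$j
    h <- best$dist / 2
    a <- nodes[[i]]; b <- nodes[[j]]
    # child with the lexicographically smallest leaf name first
    if (min(tree_leaves(b)) < min(tree_leaves(a))) { tmp <- a; a <- b; b <- tmp }
    merged <- list(children = list(a, b), height = h)
    # size-weighted average distance to every other active cluster
    for (k in which(active)) {
      if (k == i || k == j) next
      d[i, k] <- d[k, i] <-
        (sizes[i] * d[i, k] + sizes[j] * d[j, k]) / (sizes[i] + sizes[j])
    }
    nodes[[i]] <- merged
    sizes[i] <- sizes[i] + sizes[j]
    sig[i] <- min(sig[i], sig[j])
    active[j] <- FALSE
  }
  root <- nodes[[which(active)]]
  class(root) <- "haplo_tree"
  attr(root, "samples") <- dm$samples
  root
}

#' @export
print.haplo_tree <- function(x, ...) {
  cat(sprintf("<haplo_tree> %d leaves, root height %.6f\n",
              length(tree_leaves(x)), x$height))
  invisible(x)
}

#' Partition tree leaves into haplogroups at a branching tier
#'
#' Cuts the tree at depth `tier` (the root's children are at depth 1):
#' each maximal subtree rooted at that depth contributes its leaf set as
#' one group, and a leaf sitting shallower than `tier` forms its own
#' group. `tier = 1` therefore yields the two first-branching clades, the
#' classification into a reference-like group (the clade containing the
#' reference sample) and its complement.
#'
#' @param t a `haplo_tree`.
#' @param reference name of the reference sample; must be a leaf of `t`.
#' @param tier positive integer cut depth.
#' @return object of class `haplogroup_partition`: list with `tier`,
#'   `groups` (list of character vectors, in display order) and
#'   `reference_group_index`.
#' @export
partition_haplogroups <- function(t, reference, tier = 1L) {
  stopifnot(inherits(t, "haplo_tree"))
  tier <- as.integer(tier)
  if (is.na(tier) || tier < 1L) stop("tier must be a positive integer", call. = FALSE)
  leaves <- tree_leaves(t)
  if (!reference %in% leaves) {
    stop(sprintf("reference sample %s is not a leaf of the tree",
                 sQuote(reference)), call. = FALSE)
  }
  groups <- list()
  collect <- function(node, depth) {
    if (depth == tier || !is.null(node$leaf)) {
      groups[[length(groups) + 1L]] <<- tree_leaves(node)
    } else {
      for (ch in node$children) collect(ch, depth + 1L)
    }
  }
  collect(t, 0L)
  ref_idx <- which(vapply(groups, function(g) reference %in% g, logical(1)))
  structure(list(tier = tier, groups = groups,
                 reference_group_index = ref_idx),
            class = "haplogroup_partition")
}

#' @export
print.haplogroup_partition <- function(x, ...) {
  cat(sprintf("<haplogroup_partition> tier %d: %d group(s); reference in group %d\n",
              x$tier, length(x$groups), x$reference_group_index))
  for (i in seq_along(x$groups)) {
    cat(sprintf("  group %d (%d): %s\n", i, length(x$groups[[i]]),
                paste(x$groups[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' Per-sample haplogroup assignment table
#'
#' Flattens a [partition_haplogroups()] result into one row per sample
#' with its group index and whether that group contains the reference.
#'
#' @param p a `haplogroup_partition`.
#' @return data.frame with columns `sample`, `group`, `reference_like`.
#' @export
haplogroup_table <- function(p) {
  stopifnot(inherits(p, "haplogroup_partition"))
  data.frame(
    sample = unlist(p$groups, use.names = FALSE),
    group = rep(seq_along(p$groups), lengths(p$groups)),
    reference_like = rep(seq_along(p$groups) == p$reference_group_index,
                         lengths(p$groups)),
    stringsAsFactors = FALSE
  )
}
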