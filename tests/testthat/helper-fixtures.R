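# Shared builders and independent oracles for the test suite.

# Build an snp_matrix from per-sample genotype strings, e.g.
# mat_from_strings(REF = "ACGT", S1 = "ACTT").
mat_from_strings <- function(..., chromosome = "Gm06", start = 100L, step = 10L) {
  cols <- list(...)
  n <- nchar(cols[[1]])
  calls <- do.call(cbind, lapply(cols, function(s) strsplit(s, "")[[1]]))
  snp_matrix(chromosome, seq(start, by = step, length.out = n),
             names(cols), calls)
}

# Random symmetric zero-diagonal distance matrix in dist_matrix form.
random_dist <- function(n, seed) {
  set.seed(seed)
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2)
  d <- d + t(d)
  samples <- sprintf("L%02d", seq_len(n))
  dimnames(d) <- list(samples, samples)
  structure(list(samples = samples, d = d,
                 compared = matrix(1L, n, n),
                 zero_overlap_pairs = character(0)),
            class = "dist_matrix")
}

# ---- independent brute-force average-linkage oracle -------------------
# Clusters are kept as member index sets; every merge recomputes all
# inter-cluster averages from scratch over the ORIGINAL distance matrix
# (no Lance-Williams update), which is exactly the arithmetic-mean
# definition. Ties follow the same published rule (least (min,max)
# original-index signature) so that exact comparison is meaningful.
oracle_upgma <- function(dm) {
  d0 <- dm$d
  clusters <- lapply(seq_along(dm$samples), function(i) i)
  nodes <- lapply(dm$samples, function(s) list(leaf = s, height = 0))
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        avg <- mean(d0[clusters[[i]], clusters[[j]]])
        sig <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        if (is.null(best) || avg < best$avg - 1e-15 ||
            (abs(avg - best$avg) <= 1e-15 &&
             (sig[1] < best$sig[1] ||
              (sig[1] == best$sig[1] && sig[2] < best$sig[2])))) {
          best <- list(i = i, j = j, avg = avg, sig = sig)
        }
      }
    }
    a <- nodes[[best$i]]; b <- nodes[[best$j]]
    leaves_a <- oracle_leaves(a); leaves_b <- oracle_leaves(b)
    if (min(leaves_b) < min(leaves_a)) { tmp <- a; a <- b; b <- tmp }
    merged_node <- list(children = list(a, b), height = best$avg / 2)
    merged_members <- c(clusters[[best$i]], clusters[[best$j]])
    keep <- setdiff(seq_along(clusters), c(best$i, best$j))
    clusters <- c(clusters[keep], list(merged_members))
    nodes <- c(nodes[keep], list(merged_node))
  }
  nodes[[1]]
}

oracle_leaves <- function(node) {
  if (!is.null(node$leaf)) return(node$leaf)
  unlist(lapply(node$children, oracle_leaves))
}

# canonical printable signature of a tree: topology + rounded heights
tree_signature <- function(node, digits = 9) {
  if (!is.null(node$leaf)) return(node$leaf)
  kids <- vapply(node$children, tree_signature, character(1), digits = digits)
  sprintf("(%s)@%s", paste(kids, collapse = ","),
          format(round(node$height, digits), digits = 12))
}

# cophenetic matrix implied by an ultrametric tree (2 * MRCA height)
tree_cophenetic <- function(node, samples) {
  m <- matrix(0, length(samples), length(samples),
              dimnames = list(samples, samples))
  fill <- function(nd) {
    if (!is.null(nd$leaf)) return(nd$leaf)
    groups <- lapply(nd$children, fill)
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (j <= i) next
        m[groups[[i]], groups[[j]]] <<- 2 * nd$height
        m[groups[[j]], groups[[i]]] <<- 2 * nd$height
      }
    }
    unlist(groups)
  }
  fill(node)
  m
}

# root-to-leaf path lengths from branch lengths (for ultrametric checks)
newick_path_lengths <- function(nwk_path) {
  tr <- ape::read.tree(nwk_path)
  depths <- ape::node.depth.edgelength(tr)
  stats::setNames(depths[seq_along(tr$tip.label)], tr$tip.label)
}

# standard two-cluster fixture used across modules
planted_fixture <- function(seed, n_samples = 16L, n_sites = 200L,
                            divergence = 0.05, missing = 0.2, noise = 0) {
  r <- region("Gm06", 1e6, 2e6)
  assignment <- stats::setNames(rep(c(1L, 2L), length.out = n_samples - 1L),
                                sprintf("S%02d", seq_len(n_samples - 1L)))
  spec <- fixture_spec(n_samples, n_sites, r, founders = 2L,
                       divergence = divergence, noise = noise,
                       missing = missing, assignment = assignment,
                       seed = seed)
  generate_matrix(spec)
}
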