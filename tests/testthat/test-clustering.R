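test_that("pairwise identity distance excludes missing data", {
  expect_equal(pairwise_distance(c("A", "C", "G", "T"), c("A", "C", "T", "T")),
               list(d = 0.25, compared = 4L))
  # positions 2,3 dropped for missingness on either side; position 1 matches
  expect_equal(pairwise_distance(c("A", "N", "G"), c("A", "C", "-")),
               list(d = 0, compared = 1L))
  expect_equal(pairwise_distance(c("A", "R", "-"), c("A", "R", "C"))$d, 0)
  expect_warning(res <- pairwise_distance(c("N", "N"), c("A", "C")),
                 "zero informative overlap")
  expect_equal(res, list(d = 1, compared = 0L))
  expect_error(pairwise_distance("A", c("A", "C")), "equal length")
})

test_that("distance_matrix is symmetric, zero-diagonal, in [0,1]", {
  for (seed in 1:5) {
    fx <- planted_fixture(seed, n_samples = 10L, n_sites = 60L,
                          missing = 0.1, noise = 0.02)
    dm <- distance_matrix(fx$matrix)
    expect_equal(dm$d, t(dm$d))
    expect_equal(unname(diag(dm$d)), rep(0, 10))
    expect_true(all(dm$d >= 0 & dm$d <= 1))
    expect_equal(dm$compared, t(dm$compared))
    # the diagonal of `compared` counts each sample's non-missing cells
    non_missing <- matrix(!is_missing_symbol(fx$matrix$calls),
                          nrow = nrow(fx$matrix$calls))
    expect_equal(unname(diag(dm$compared)), as.integer(colSums(non_missing)))
  }
})

test_that("compared diagonal counts non-missing cells per sample", {
  m <- mat_from_strings(REF = "ACGT", S1 = "ANG-", S2 = "NNNN")
  expect_warning(dm <- distance_matrix(m), "zero informative overlap")
  expect_equal(unname(diag(dm$compared)), c(4L, 2L, 0L))
  expect_equal(dm$d["S2", "REF"], 1)
  expect_true("REF/S2" %in% dm$zero_overlap_pairs)
})

test_that("distance on a noiseless planted fixture equals the realized divergence", {
  fx <- planted_fixture(7, n_samples = 12L, n_sites = 200L,
                        divergence = 0.1, missing = 0, noise = 0)
  dm <- distance_matrix(fx$matrix)
  g1 <- names(fx$truth)[fx$truth == 1]
  g2 <- names(fx$truth)[fx$truth == 2]
  expect_true(all(dm$d[g1, g1] == 0))
  expect_true(all(dm$d[g2, g2] == 0))
  planted_fraction <- length(fx$founder_sites[[2]]) / 200
  expect_equal(unname(dm$d[g1, g2][1]), planted_fraction)
  expect_true(all(dm$d[g1, g2] == planted_fraction))
})

test_that("permuting sample order permutes the distance matrix consistently", {
  fx <- planted_fixture(3, n_samples = 8L, n_sites = 50L)
  m <- fx$matrix
  perm <- c(1L, sample(2:8))  # keep the reference first
  m2 <- snp_matrix(m$chromosome, m$positions, m$samples[perm],
                   m$calls[, perm, drop = FALSE])
  d1 <- distance_matrix(m)$d
  d2 <- distance_matrix(m2)$d
  expect_equal(d2, d1[m2$samples, m2$samples])
})

test_that("upgma hand example: closest pair merges first at half distance", {
  d <- matrix(c(0, 0.1, 0.4,
                0.1, 0, 0.4,
                0.4, 0.4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dm <- structure(list(samples = c("A", "B", "C"), d = d,
                       compared = matrix(1L, 3, 3),
                       zero_overlap_pairs = character(0)),
                  class = "dist_matrix")
  t <- upgma(dm)
  expect_equal(tree_signature(t), "((A,B)@0.05,C)@0.2")
  # two-leaf case: single merge at half the distance
  t2 <- upgma(structure(list(samples = c("A", "B"),
                             d = matrix(c(0, 0.2, 0.2, 0), 2, 2,
                                        dimnames = list(c("A", "B"), c("A", "B"))),
                             compared = matrix(1L, 2, 2),
                             zero_overlap_pairs = character(0)),
                        class = "dist_matrix"))
  expect_equal(t2$height, 0.1)
  expect_equal(leaf_display_order(t2), c("A", "B"))
})

test_that("upgma matches the brute-force average-linkage oracle", {
  # recompute-from-scratch oracle over random matrices, n <= 8
  for (seed in 1:60) {
    n <- 3L + (seed %% 6L)
    dm <- random_dist(n, seed)
    expect_equal(tree_signature(upgma(dm)), tree_signature(oracle_upgma(dm)),
                 info = sprintf("seed %d", seed))
  }
})

test_that("upgma cophenetic heights agree with hclust average linkage", {
  for (seed in c(11, 23, 37)) {
    dm <- random_dist(7, seed)
    mine <- tree_cophenetic(upgma(dm), dm$samples)
    hc <- stats::hclust(stats::as.dist(dm$d), method = "average")
    ref <- as.matrix(stats::cophenetic(hc))[dm$samples, dm$samples]
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("upgma trees are ultrametric with monotone merge heights", {
  check_heights <- function(node, parent_h) {
    expect_true(node$height <= parent_h + 1e-12)
    if (is.null(node$leaf)) for (ch in node$children) check_heights(ch, node$height)
  }
  for (seed in 1:10) {
    t <- upgma(random_dist(8, 100 + seed))
    check_heights(t, t$height)
    coph <- tree_cophenetic(t, leaf_display_order(t))
    # root-to-leaf depth equals root height for every leaf
    expect_true(all(abs(apply(coph, 1, max) / 2 - t$height) < 1e-9))
  }
})

test_that("haplogroup partition cuts the tree at the requested tier", {
  d <- matrix(c(0, 0.1, 0.4,
                0.1, 0, 0.4,
                0.4, 0.4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dm <- structure(list(samples = c("A", "B", "C"), d = d,
                       compared = matrix(1L, 3, 3),
                       zero_overlap_pairs = character(0)),
                  class = "dist_matrix")
  t <- upgma(dm)
  p1 <- partition_haplogroups(t, "A", 1)
  expect_equal(p1$groups, list(c("A", "B"), "C"))
  expect_equal(p1$reference_group_index, 1L)
  # a leaf shallower than the tier forms its own group
  p2 <- partition_haplogroups(t, "C", 2)
  expect_equal(p2$groups, list("A", "B", "C"))
  expect_equal(p2$reference_group_index, 3L)
  expect_error(partition_haplogroups(t, "Z", 1), "not a leaf")
})

test_that("tier k+1 refines tier k and groups partition the samples", {
  for (seed in 1:5) {
    t <- upgma(random_dist(8, 200 + seed))
    leaves <- leaf_display_order(t)
    prev <- NULL
    for (tier in 1:4) {
      p <- partition_haplogroups(t, leaves[1], tier)
      flat <- unlist(p$groups)
      expect_equal(sort(flat), sort(leaves))        # exhaustive
      expect_equal(anyDuplicated(flat), 0L)          # disjoint
      if (tier == 1) expect_lte(length(p$groups), 2L)
      if (!is.null(prev)) {
        for (g in p$groups) {
          expect_true(any(vapply(prev$groups, function(pg) all(g %in% pg),
                                 logical(1))))       # refinement
        }
      }
      prev <- p
    }
  }
})

test_that("tier-1 partition recovers planted haplogroups", {
  for (seed in 1:20) {
    fx <- planted_fixture(seed)
    dm <- distance_matrix(fx$matrix)
    t <- upgma(dm)
    p <- partition_haplogroups(t, "REF", 1)
    truth_ref <- names(fx$truth)[fx$truth == 1]
    expect_equal(sort(p$groups[[p$reference_group_index]]), sort(truth_ref),
                 info = sprintf("seed %d", seed))
  }
})
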