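# Seeded generator of SNP matrices with planted haplogroup structure,
# noise, missing data and deletion runs.

#' Specification for a synthetic SNP fixture
#'
#' Describes a planted-structure dataset: `founders` haplotypes, the
#' first of which is the reference genome; every other founder differs
#' from the reference at a fraction `divergence` of the sites; samples
#' copy their founder and are then perturbed by per-cell mutation
#' (`noise`), per-cell missingness (`missing`, written as `N`) and
#' contiguous all-missing deletion runs (written as `-`), in that
#' order. Everything is reproducible from `seed`: each stage (site
#' draw, reference bases, founder site sets, founder assignment, noise,
#' missingness) consumes its own seeded stream, so changing e.g.
#' `missing` does not perturb the founder draws.
#'
#' The defaults emulate the structure of reference-aligned resequencing
#' panels used for candidate-gene haplotype analysis: tens of samples,
#' a reference-like and a clearly divergent haplotype cluster, sparse
#' per-site noise and realistic missingness.
#'
#' @param n_samples total samples including the reference (>= 2).
#' @param n_sites number of variant positions.
#' @param region a [region()] the positions are drawn from.
#' @param founders number of founder haplotypes, k >= 1.
#' @param divergence fraction of sites at which each non-reference
#'   founder differs from the reference founder (default 0.1).
#' @param noise per-cell mutation probability (default 0).
#' @param missing per-cell missing probability (default 0).
#' @param deletion_runs list of `list(samples=, region=)` entries whose
#'   cells are blanked to `-`.
#' @param assignment optional named founder index per non-reference
#'   sample; by default founders are assigned uniformly at random.
#' @param seed integer seed.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_samples, n_sites, region,
                         founders = 2L, divergence = 0.1,
                         noise = 0, missing = 0,
                         deletion_runs = list(), assignment = NULL,
                         seed = 1L) {
  stopifnot(inherits(region, "region"))
  if (n_samples < 2L) stop("need at least 2 samples", call. = FALSE)
  if (founders < 1L || founders > n_samples) {
    stop("founders must be in [1, n_samples]", call. = FALSE)
  }
  for (p in c(divergence, noise, missing)) {
    if (p < 0 || p > 1) stop("rates must lie in [0, 1]", call. = FALSE)
  }
  if (n_sites > region$end - region$start + 1) {
    stop("region too small for n_sites distinct positions", call. = FALSE)
  }
  for (dr in deletion_runs) {
    stopifnot(inherits(dr$region, "region"))
    if (dr$region$start < region$start || dr$region$end > region$end) {
      stop("deletion run sub-region must lie within the fixture region",
           call. = FALSE)
    }
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_sites = as.integer(n_sites),
                 region = region, founders = as.integer(founders),
                 divergence = divergence, noise = noise, missing = missing,
                 deletion_runs = deletion_runs, assignment = assignment,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# stage-keyed child seed of the global fixture seed (kept below 2^31)
stage_seed <- function(seed, stage) {
  (as.numeric(seed) * 7919 + stage * 104729) %% 2147483647
}

BASES <- c("A", "C", "G", "T")

#' Generate a synthetic SNP matrix with planted haplogroups
#'
#' @param spec a [fixture_spec()].
#' @return list with `matrix` (an [snp_matrix()]), `truth` (named
#'   founder index per sample; the reference is founder 1) and
#'   `founder_sites` (per non-reference founder, the planted positions
#'   at which it differs from the reference).
#' @export
generate_matrix <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  r <- spec$region
  ns <- spec$n_sites

  set.seed(stage_seed(spec$seed, 1))   # positions
  width <- r$end - r$start + 1
  positions <- sort(sample.int(width, ns)) + r$start - 1

  set.seed(stage_seed(spec$seed, 2))   # reference bases
  ref <- sample(BASES, ns, replace = TRUE)

  set.seed(stage_seed(spec$seed, 3))   # founder divergence sets
  founders <- matrix(ref, nrow = ns, ncol = spec$founders)
  founder_sites <- vector("list", spec$founders)
  if (spec$founders > 1L) {
    n_div <- round(spec$divergence * ns)
    for (f in 2:spec$founders) {
      div <- sort(sample.int(ns, n_div))
      founder_sites[[f]] <- positions[div]
      for (i in div) {
        founders[i, f] <- sample(setdiff(BASES, ref[i]), 1L)
      }
    }
  }

  samples <- c("REF", sprintf("S%02d", seq_len(spec$n_samples - 1L)))
  set.seed(stage_seed(spec$seed, 4))   # founder assignment
  truth <- integer(spec$n_samples)
  truth[1] <- 1L
  if (!is.null(spec$assignment)) {
    truth[-1] <- spec$assignment[samples[-1]]
    if (anyNA(truth)) stop("assignment must name every non-reference sample",
                           call. = FALSE)
  } else {
    truth[-1] <- sample.int(spec$founders, spec$n_samples - 1L, replace = TRUE)
  }
  names(truth) <- samples

  calls <- founders[, truth, drop = FALSE]

  set.seed(stage_seed(spec$seed, 5))   # noise (non-reference samples only)
  if (spec$noise > 0) {
    for (s in 2:spec$n_samples) {
      hit <- which(stats::runif(ns) < spec$noise)
      for (i in hit) {
        calls[i, s] <- sample(setdiff(BASES, calls[i, s]), 1L)
      }
    }
  }

  set.seed(stage_seed(spec$seed, 6))   # missingness
  if (spec$missing > 0) {
    for (s in 2:spec$n_samples) {
      hit <- stats::runif(ns) < spec$missing
      calls[hit, s] <- "N"
    }
  }

  for (dr in spec$deletion_runs) {
    rows <- positions >= dr$region$start & positions <= dr$region$end
    calls[rows, match(dr$samples, samples)] <- "-"
  }

  list(matrix = snp_matrix(r$chromosome, positions, samples, calls),
       truth = truth,
       founder_sites = founder_sites)
}

#' Generate non-overlapping synthetic gene models
#'
#' Lays `n_genes` genes in disjoint equal slots of `region`, each with
#' 1–5 non-overlapping exons inside its span and a random strand;
#' reproducible from `seed`.
#'
#' @param region a [region()].
#' @param n_genes number of genes (>= 0).
#' @param seed integer seed.
#' @return list of [gene_model()] objects sorted by start.
#' @export
generate_annotation <- function(region, n_genes, seed = 1L) {
  stopifnot(inherits(region, "region"))
  if (n_genes == 0L) return(list())
  set.seed(stage_seed(seed, 7))
  width <- region$end - region$start + 1
  slot <- floor(width / n_genes)
  if (slot < 20L) stop("region too small for that many genes", call. = FALSE)
  models <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    slot_start <- region$start + (g - 1L) * slot
    gs <- slot_start + sample.int(max(1L, slot %/% 4L), 1L) - 1L
    ge <- min(slot_start + slot - 1L, gs + sample.int(slot %/% 2L, 1L) + 10L)
    n_ex <- sample.int(5L, 1L)
    # cut the span into 2*n_ex alternating blocks, exons on odd blocks
    block <- max(1L, floor((ge - gs + 1) / (2L * n_ex)))
    exons <- list()
    for (e in seq_len(n_ex)) {
      es <- gs + (2L * (e - 1L)) * block
      ee <- min(ge, es + block - 1L)
      if (es > ge) break
      exons[[length(exons) + 1L]] <- region(region$chromosome, es, ee)
    }
    models[[g]] <- gene_model(sprintf("g%02d", g),
                              sample(c("+", "-"), 1L),
                              region(region$chromosome, gs, ge), exons)
  }
  models
}

#' Plant a causative-SNP allele into a matrix
#'
#' Inserts the registered site (if absent) with the reference symbol in
#' every column, then sets each carrier to the variant symbol — giving
#' ground truth for [call_allele()] tests and simulations.
#'
#' @param m an [snp_matrix()] on the definition's chromosome.
#' @param def an [allele_def()].
#' @param carriers sample names to receive the variant symbol; must not
#'   include the reference sample (`m$samples[1]`).
#' @return a new [snp_matrix()].
#' @export
plant_allele <- function(m, def, carriers = character(0)) {
  validate_snp_matrix(m)
  stopifnot(inherits(def, "allele_def"))
  if (m$chromosome != def$chromosome) {
    stop("chromosome mismatch between matrix and allele definition",
         call. = FALSE)
  }
  if (m$samples[1] %in% carriers) {
    stop("carriers must not include the reference sample", call. = FALSE)
  }
  if (!all(carriers %in% m$samples)) {
    stop("unknown carrier sample(s)", call. = FALSE)
  }
  positions <- m$positions
  calls <- m$calls
  if (!def$position %in% positions) {
    at <- findInterval(def$position, positions)
    positions <- append(positions, def$position, after = at)
    calls <- rbind(calls[seq_len(at), , drop = FALSE],
                   rep(def$ref_symbol, ncol(calls)),
                   calls[setdiff(seq_len(nrow(calls)), seq_len(at)), ,
                         drop = FALSE])
  }
  row <- which(positions == def$position)
  calls[row, match(carriers, m$samples)] <- def$alt_symbol
  snp_matrix(m$chromosome, positions, m$samples, calls)
}
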