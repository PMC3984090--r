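# Haplotype-window construction, causative-SNP genotype calls,
# deletion-signature scanning and CDS codon arithmetic.

#' Causative-SNP allele definition
#'
#' Registers one biallelic causative SNP of a candidate gene: the
#' reference-genome symbol and the variant symbol, and the allele names
#' assigned to samples carrying each.
#'
#' @param gene gene/entry label (unique per registry entry).
#' @param chromosome,position the causative-SNP site (1-based).
#' @param ref_symbol,alt_symbol distinct non-missing single symbols.
#' @param ref_allele_name,alt_allele_name allele names reported for the
#'   reference and the variant state.
#' @return object of class `allele_def`.
#' @export
allele_def <- function(gene, chromosome, position,
                       ref_symbol, alt_symbol,
                       ref_allele_name, alt_allele_name) {
  ref_symbol <- normalize_symbol(ref_symbol)
  alt_symbol <- normalize_symbol(alt_symbol)
  if (ref_symbol == alt_symbol) {
    stop("ref and alt symbols must differ", call. = FALSE)
  }
  if (is_missing_symbol(ref_symbol) || is_missing_symbol(alt_symbol)) {
    stop("ref/alt symbols must not be missing-data symbols", call. = FALSE)
  }
  structure(list(gene = as.character(gene),
                 chromosome = trimws(as.character(chromosome)),
                 position = as.numeric(position),
                 ref_symbol = ref_symbol, alt_symbol = alt_symbol,
                 ref_allele_name = as.character(ref_allele_name),
                 alt_allele_name = as.character(alt_allele_name)),
            class = "allele_def")
}

#' Built-in registry of soybean maturity/growth-habit causative SNPs
#'
#' SNP alleles of the major soybean maturity genes and the stem-growth
#' gene, expressed against the Williams 82 reference genome: the E1
#' promoter-proximal missense SNP (Williams 82 carries the early
#' *e1-as* allele, C; the functional *E1* allele is G), the *e2*
#' nonsense SNP (reference *E2* = A, variant *e2* = T), and four *dt1*
#' missense SNPs (R62S, P113L, R130K, R166W). Structural alleles (gene
#' deletions, retrotransposon insertions, single-base frameshift
#' deletions) are not representable as biallelic SNP calls and are
#' handled, where possible, by [deletion_signature()].
#'
#' @return list of [allele_def()] entries.
#' @export
default_allele_registry <- function() {
  list(
    allele_def("E1", "Gm06", 20007173, "C", "G", "e1-as", "E1"),
    allele_def("E2", "Gm10", 44732850, "A", "T", "E2", "e2"),
    allele_def("Dt1_R62S",  "Gm19", 44981190, "C", "A", "Dt1", "dt1-R62S"),
    allele_def("Dt1_P113L", "Gm19", 44980245, "G", "A", "Dt1", "dt1-P113L"),
    allele_def("Dt1_R130K", "Gm19", 44980194, "C", "T", "Dt1", "dt1-R130K"),
    allele_def("Dt1_R166W", "Gm19", 44980087, "T", "A", "Dt1", "dt1-R166W")
  )
}

#' Read an allele registry from a tab-delimited config file
#'
#' One entry per non-comment line:
#' `gene <TAB> chromosome <TAB> position <TAB> ref <TAB> alt <TAB>
#' ref_allele_name <TAB> alt_allele_name`.
#'
#' @param path config file; lines starting with `#` are skipped.
#' @return list of [allele_def()] entries.
#' @export
read_allele_registry <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  entries <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) != 7L) {
      stop("registry lines need 7 tab-delimited fields", call. = FALSE)
    }
    allele_def(f[1], f[2], as.numeric(f[3]), f[4], f[5], f[6], f[7])
  })
  keys <- vapply(entries, function(e) paste(e$gene, e$chromosome, e$position),
                 character(1))
  if (anyDuplicated(keys)) stop("duplicate registry entries", call. = FALSE)
  entries
}

#' Haplotype analysis window around a gene
#'
#' Extends a gene interval by a symmetric flank (default 3,500 bp, the
#' window width used for candidate-gene haplotype analysis), clamping
#' the start at 1.
#'
#' @param gene_span a [region()].
#' @param flank flank size in bp on each side; must be >= 0.
#' @return a [region()] for the window.
#' @examples
#' haplotype_window(region("Gm06", 20006928, 20007814))
#' @export
haplotype_window <- function(gene_span, flank = 3500) {
  stopifnot(inherits(gene_span, "region"))
  if (flank < 0) stop("flank must be >= 0", call. = FALSE)
  region(gene_span$chromosome,
         max(1, gene_span$start - flank),
         gene_span$end + flank)
}

#' Call a causative-SNP allele for every sample
#'
#' Each sample's symbol at the registered site is mapped to an allele
#' call: the reference symbol gives the reference allele name, the
#' variant symbol the variant allele name, a missing symbol `"no_data"`,
#' the IUPAC code denoting exactly the {ref, alt} pair
#' `"heterozygous"`, and any other symbol `"unknown_variant"`.
#'
#' If the site is absent from the matrix entirely, every sample is
#' called with the reference allele name and the result carries
#' `attr(, "assumed_reference") = TRUE`: in a variant-only matrix,
#' absence of a position means no variant was reported there, which is
#' evidence of reference state but weaker than an observed base.
#'
#' @param m an [snp_matrix()] on the definition's chromosome.
#' @param def an [allele_def()].
#' @return data.frame with columns `sample`, `call`, `observed`; the
#'   `assumed_reference` attribute marks position-absent calls.
#' @export
call_allele <- function(m, def) {
  validate_snp_matrix(m)
  stopifnot(inherits(def, "allele_def"))
  if (m$chromosome != def$chromosome) {
    stop(sprintf("chromosome mismatch: matrix is %s, allele site is %s",
                 m$chromosome, def$chromosome), call. = FALSE)
  }
  row <- which(m$positions == def$position)
  if (length(row) == 0L) {
    out <- data.frame(sample = m$samples,
                      call = def$ref_allele_name,
                      observed = NA_character_,
                      stringsAsFactors = FALSE)
    attr(out, "assumed_reference") <- TRUE
    return(out)
  }
  sym <- m$calls[row, ]
  het_code <- names(Filter(function(x) setequal(x, c(def$ref_symbol,
                                                     def$alt_symbol)),
                           IUPAC_EXPANSION))
  call <- ifelse(is_missing_symbol(sym), "no_data",
          ifelse(sym == def$ref_symbol, def$ref_allele_name,
          ifelse(sym == def$alt_symbol, def$alt_allele_name,
          ifelse(sym %in% het_code, "heterozygous", "unknown_variant"))))
  out <- data.frame(sample = m$samples, call = unname(call),
                    observed = unname(sym), stringsAsFactors = FALSE)
  attr(out, "assumed_reference") <- FALSE
  out
}

#' Scan one sample for a deletion signature
#'
#' A genomic deletion leaves a contiguous run of missing SNP calls in
#' the affected sample. This scan counts, inside a candidate region, the
#' SNP positions at which the sample is missing and the longest
#' consecutive missing run, and flags the sample as a deletion
#' *candidate* when the missing fraction reaches `threshold` over at
#' least `min_sites` scanned sites. The flag is a heuristic consistent
#' with a deletion, not a definitive allele call (confirmation requires
#' an independent assay).
#'
#' @param m an [snp_matrix()].
#' @param sample sample name in `m`.
#' @param scan a [region()] on `m`'s chromosome.
#' @param threshold missing-fraction threshold for flagging, default 0.9.
#' @param min_sites minimum scanned sites required to flag, default 3.
#' @return object of class `deletion_signature`: list with `sample`,
#'   `region`, `n_sites`, `n_missing`, `longest_run`, `fraction`,
#'   `flagged`.
#' @export
deletion_signature <- function(m, sample, scan, threshold = 0.9,
                               min_sites = 3L) {
  validate_snp_matrix(m)
  stopifnot(inherits(scan, "region"))
  if (!sample %in% m$samples) {
    stop(sprintf("unknown sample %s", sQuote(sample)), call. = FALSE)
  }
  sub <- slice_region(m, scan)
  n_sites <- length(sub$positions)
  if (n_sites == 0L) {
    return(structure(list(sample = sample, region = scan, n_sites = 0L,
                          n_missing = 0L, longest_run = 0L,
                          fraction = NA_real_, flagged = FALSE),
                     class = "deletion_signature"))
  }
  miss <- is_missing_symbol(sub$calls[, sample])
  runs <- rle(miss)
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  frac <- sum(miss) / n_sites
  structure(list(sample = sample, region = scan,
                 n_sites = n_sites, n_missing = sum(miss),
                 longest_run = as.integer(longest),
                 fraction = frac,
                 flagged = frac >= threshold && n_sites >= min_sites),
            class = "deletion_signature")
}

#' @export
print.deletion_signature <- function(x, ...) {
  cat(sprintf("<deletion_signature> %s @ %s:%s-%s: %d/%d missing (%.2f), longest run %d%s\n",
              x$sample, x$region$chromosome,
              format(x$region$start, scientific = FALSE),
              format(x$region$end, scientific = FALSE),
              x$n_missing, x$n_sites,
              ifelse(is.na(x$fraction), 0, x$fraction), x$longest_run,
              if (x$flagged) " [FLAGGED candidate]" else ""))
  invisible(x)
}

#' Codon index affected by a CDS position
#'
#' @param cds_pos 1-based position(s) within the spliced coding sequence.
#' @return 1-based codon index, `ceiling(cds_pos / 3)`.
#' @examples
#' affected_codon(44)    # 15
#' affected_codon(1561)  # 521
#' @export
affected_codon <- function(cds_pos) {
  if (any(cds_pos < 1)) stop("CDS position must be >= 1", call. = FALSE)
  ceiling(cds_pos / 3)
}

#' Intact N-terminal residues before a frameshift
#'
#' A single-base deletion at CDS position `p` disrupts codon
#' `affected_codon(p)`; the residues before it are translated
#' unchanged.
#'
#' @param cds_del_pos 1-based CDS position of the deleted base.
#' @return count of unaffected N-terminal amino acids.
#' @examples
#' frameshift_intact_length(48)  # 15
#' @export
frameshift_intact_length <- function(cds_del_pos) {
  affected_codon(cds_del_pos) - 1
}

#' Interval length under the coordinate-difference convention
#'
#' Deletion lengths in the allele literature this registry mirrors are
#' reported as `end - start` (not `end - start + 1`); this helper fixes
#' that convention in one place.
#'
#' @param start,end 1-based bp coordinates, `end >= start`.
#' @return length in bp.
#' @examples
#' interval_length(47516697, 47519330)  # 2633
#' @export
interval_length <- function(start, end) {
  if (any(end < start)) stop("end must be >= start", call. = FALSE)
  end - start
}

#' Per-sample, per-gene genotype call table
#'
#' One row per non-reference sample, one column per registry entry with
#' that sample's allele call. When `e3_scan` is given, a
#' `e3_candidate` column reports whether [deletion_signature()] flags
#' the sample over that region, and `e3_missing_fraction` the measured
#' fraction. Registry entries whose site is absent from the matrix are
#' called assumed-reference and listed in the `assumed_reference`
#' column (identical for every row, since absence is a property of the
#' matrix).
#'
#' @param m an [snp_matrix()].
#' @param registry list of [allele_def()] (default: the built-in
#'   registry restricted to `m`'s chromosome).
#' @param e3_scan optional [region()] scanned for deletion candidates.
#' @param threshold missing-fraction threshold passed through to
#'   [deletion_signature()].
#' @return data.frame, one row per non-reference sample.
#' @export
genotype_table <- function(m, registry = NULL, e3_scan = NULL,
                           threshold = 0.9) {
  validate_snp_matrix(m)
  if (is.null(registry)) {
    registry <- Filter(function(d) d$chromosome == m$chromosome,
                       default_allele_registry())
  }
  if (length(registry) == 0L) stop("empty allele registry", call. = FALSE)
  samples <- m$samples[-1L]
  out <- data.frame(sample = samples, stringsAsFactors = FALSE)
  assumed <- character(0)
  for (def in registry) {
    calls <- call_allele(m, def)
    out[[def$gene]] <- calls$call[match(samples, calls$sample)]
    if (isTRUE(attr(calls, "assumed_reference"))) {
      assumed <- c(assumed, def$gene)
    }
  }
  if (!is.null(e3_scan)) {
    sigs <- lapply(samples, function(s) {
      deletion_signature(m, s, e3_scan, threshold = threshold)
    })
    out$e3_candidate <- vapply(sigs, function(s) s$flagged, logical(1))
    out$e3_missing_fraction <- vapply(sigs, function(s) {
      if (is.na(s$fraction)) 0 else s$fraction
    }, numeric(1))
  }
  out$assumed_reference <- paste(assumed, collapse = ",")
  out
}
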