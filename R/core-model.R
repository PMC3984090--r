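# Domain types and genotype-symbol normalization shared by every module.

#' The 16-symbol genotype alphabet
#'
#' All genotype calls are single IUPAC nucleotide symbols: the four bases,
#' the ten ambiguity codes, and the two missing-data markers `N` and `-`.
#'
#' @format Character vector of length 16.
#' @export
GENOTYPE_SYMBOLS <- c("A", "C", "G", "T",
                      "R", "Y", "S", "W", "K", "M",
                      "B", "D", "H", "V",
                      "N", "-")

MISSING_SYMBOLS <- c("N", "-")

AMBIGUITY_SYMBOLS <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

# base-set expansion of each ambiguity code, used for heterozygote calls
IUPAC_EXPANSION <- list(
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G")
)

# unordered base pair -> IUPAC code (keys are sorted two-base strings)
IUPAC_PAIR <- c(AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M")

#' Test whether symbols denote missing data
#'
#' @param x character vector of genotype symbols.
#' @return logical vector, `TRUE` where the symbol is `N` or `-`.
#' @export
is_missing_symbol <- function(x) x %in% MISSING_SYMBOLS

#' Test whether symbols are IUPAC ambiguity codes
#'
#' @param x character vector of genotype symbols.
#' @return logical vector, `TRUE` for the ten two/three-base codes.
#' @export
is_ambiguous_symbol <- function(x) x %in% AMBIGUITY_SYMBOLS

#' Normalize raw genotype tokens to single IUPAC symbols
#'
#' Input tables carry genotypes as one- or two-character tokens. Single
#' tokens must already be members of the 16-symbol alphabet (case is
#' folded). Double tokens are interpreted as an unordered base pair and
#' collapsed to the corresponding IUPAC code; an identical pair collapses
#' to the base itself (`"TT"` -> `"T"`, `"NN"` -> `"N"`).
#'
#' @param tokens character vector of raw tokens (whitespace is trimmed).
#' @return character vector of single-character symbols.
#' @examples
#' normalize_symbol(c("AG", "ga", "TT", "-"))  # "R" "R" "T" "-"
#' @export
normalize_symbol <- function(tokens) {
  out <- normalize_symbol_quietly(tokens)
  bad <- which(is.na(out) & !is.na(tokens))
  if (length(bad) > 0L) {
    stop(sprintf("invalid genotype token(s): %s",
                 paste(sQuote(unique(tokens[bad])), collapse = ", ")),
         call. = FALSE)
  }
  out
}

# Vectorized normalization returning NA for invalid tokens, so callers
# (the table reader) can report file line and column themselves.
normalize_symbol_quietly <- function(tokens) {
  toks <- toupper(trimws(tokens))
  uniq <- unique(toks)
  mapped <- vapply(uniq, normalize_one, character(1), USE.NAMES = FALSE)
  mapped[match(toks, uniq)]
}

normalize_one <- function(tok) {
  if (is.na(tok) || nchar(tok) == 0L || nchar(tok) > 2L) return(NA_character_)
  if (nchar(tok) == 1L) {
    if (tok %in% GENOTYPE_SYMBOLS) return(tok)
    return(NA_character_)
  }
  a <- substr(tok, 1L, 1L)
  b <- substr(tok, 2L, 2L)
  if (!(a %in% GENOTYPE_SYMBOLS) || !(b %in% GENOTYPE_SYMBOLS)) {
    return(NA_character_)
  }
  if (a == b) return(a)
  if (a %in% c("A", "C", "G", "T") && b %in% c("A", "C", "G", "T")) {
    key <- paste(sort(c(a, b)), collapse = "")
    return(unname(IUPAC_PAIR[key]))
  }
  NA_character_
}

#' Genomic region (1-based, both ends inclusive)
#'
#' @param chromosome chromosome label (compared as an exact trimmed string;
#'   `"Gm06"` and `"6"` are different chromosomes).
#' @param start,end 1-based bp coordinates, `start <= end`, both inclusive.
#' @return an object of class `region`.
#' @export
region <- function(chromosome, start, end) {
  stopifnot(length(chromosome) == 1L, length(start) == 1L, length(end) == 1L)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start != trunc(start) || end != trunc(end)) {
    stop("region bounds must be integers", call. = FALSE)
  }
  if (start < 1) stop("region start must be >= 1", call. = FALSE)
  if (start > end) stop("region start must not exceed end", call. = FALSE)
  structure(list(chromosome = trimws(as.character(chromosome)),
                 start = start, end = end),
            class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("<region> %s:%s-%s (%s bp)\n", x$chromosome,
              format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE),
              format(x$end - x$start + 1, scientific = FALSE)))
  invisible(x)
}

#' SNP matrix: variant positions by ordered samples
#'
#' One chromosome's variant positions (rows) by samples (columns), each
#' cell a single IUPAC genotype symbol. The first sample is the reference
#' genome all other calls are expressed against.
#'
#' @param chromosome chromosome label.
#' @param positions strictly increasing 1-based bp coordinates.
#' @param samples unique sample names; `samples[1]` is the reference.
#' @param calls character matrix `length(positions)` x `length(samples)`
#'   of symbols from [GENOTYPE_SYMBOLS].
#' @return an object of class `snp_matrix`.
#' @export
snp_matrix <- function(chromosome, positions, samples, calls) {
  positions <- as.numeric(positions)
  samples <- as.character(samples)
  calls <- as.matrix(calls)
  m <- structure(list(chromosome = trimws(as.character(chromosome)),
                      positions = positions,
                      samples = samples,
                      calls = calls),
                 class = "snp_matrix")
  validate_snp_matrix(m)
  dimnames(m$calls) <- list(format(positions, scientific = FALSE, trim = TRUE),
                            samples)
  m
}

validate_snp_matrix <- function(m) {
  stopifnot(inherits(m, "snp_matrix"))
  if (length(m$samples) == 0L) stop("snp_matrix needs at least one sample", call. = FALSE)
  if (anyDuplicated(m$samples)) stop("sample names must be unique", call. = FALSE)
  if (length(m$positions) > 1L && any(diff(m$positions) <= 0)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  if (nrow(m$calls) != length(m$positions) || ncol(m$calls) != length(m$samples)) {
    stop("calls matrix dimensions do not match positions x samples", call. = FALSE)
  }
  if (length(m$calls) > 0L && !all(m$calls %in% GENOTYPE_SYMBOLS)) {
    bad <- unique(m$calls[!(m$calls %in% GENOTYPE_SYMBOLS)])
    stop(sprintf("invalid genotype symbol(s) in matrix: %s",
                 paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  }
  invisible(m)
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("<snp_matrix> %s: %d positions x %d samples (reference: %s)\n",
              x$chromosome, length(x$positions), length(x$samples),
              x$samples[1]))
  invisible(x)
}

#' Restrict a SNP matrix to a genomic region
#'
#' Keeps positions `p` with `r$start <= p <= r$end`; samples are unchanged.
#' A region beyond all positions yields a valid zero-position matrix.
#'
#' @param m an [snp_matrix()].
#' @param r a [region()] on the same chromosome.
#' @return an `snp_matrix` restricted to `r`.
#' @export
slice_region <- function(m, r) {
  stopifnot(inherits(m, "snp_matrix"), inherits(r, "region"))
  if (m$chromosome != r$chromosome) {
    stop(sprintf("chromosome mismatch: matrix is %s, region is %s",
                 m$chromosome, r$chromosome), call. = FALSE)
  }
  keep <- m$positions >= r$start & m$positions <= r$end
  snp_matrix(m$chromosome, m$positions[keep], m$samples,
             m$calls[keep, , drop = FALSE])
}

#' Gene model for the annotation track
#'
#' @param name gene identifier.
#' @param strand `"+"` or `"-"`.
#' @param span a [region()] covering the gene.
#' @param exons list of [region()] objects, each within `span`; stored
#'   sorted by start and must be pairwise non-overlapping.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(name, strand, span, exons = list()) {
  stopifnot(inherits(span, "region"))
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  if (length(exons) > 0L) {
    starts <- vapply(exons, function(e) e$start, numeric(1))
    exons <- exons[order(starts)]
    for (e in exons) {
      stopifnot(inherits(e, "region"))
      if (e$chromosome != span$chromosome ||
          e$start < span$start || e$end > span$end) {
        stop(sprintf("exon %s:%d-%d lies outside the gene span",
                     e$chromosome, e$start, e$end), call. = FALSE)
      }
    }
    ends <- vapply(exons, function(e) e$end, numeric(1))
    starts <- vapply(exons, function(e) e$start, numeric(1))
    if (length(exons) > 1L && any(starts[-1] <= ends[-length(ends)])) {
      stop("exons must be pairwise non-overlapping", call. = FALSE)
    }
  }
  structure(list(name = as.character(name), strand = strand,
                 span = span, exons = exons),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%s-%s, %d exon(s)\n", x$name, x$strand,
              x$span$chromosome,
              format(x$span$start, scientific = FALSE),
              format(x$span$end, scientific = FALSE),
              length(x$exons)))
  invisible(x)
}
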