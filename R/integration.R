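# Merge multiple reference-aligned datasets into one SNP matrix.

#' Merge reference-aligned SNP datasets
#'
#' Positions become the sorted union across datasets. A dataset that
#' lacks a union position is assumed to match the reference genome
#' there, so all its samples (and the merged reference column) receive
#' the reference symbol observed by a dataset that does carry the
#' position. This reference fill-in biases absent positions toward
#' reference-likeness and therefore shrinks distances for sparsely
#' ascertained datasets; it is the documented merge semantic, not an
#' imputation.
#'
#' The merged sample order is bundle order with each bundle's internal
#' order preserved. The reference column is emitted once, from the first
#' bundle; a later bundle's reference column is dropped when it carries
#' the same name (with a log message) and otherwise kept as an ordinary
#' sample. Sample-name collisions across bundles are resolved by
#' suffixing `@<dataset>` with a warning. Reference symbols at shared
#' positions must agree across bundles; a conflict is an error naming
#' the position and bundles unless `on_conflict = "prefer_first"`, which
#' keeps the earliest bundle's symbol and warns.
#'
#' @param bundles list of [dataset_bundle()] objects on one chromosome.
#' @param on_conflict `"error"` (default) or `"prefer_first"`.
#' @return the merged [snp_matrix()].
#' @export
merge_datasets <- function(bundles, on_conflict = c("error", "prefer_first")) {
  on_conflict <- match.arg(on_conflict)
  if (length(bundles) < 1L) stop("no datasets to merge", call. = FALSE)
  for (b in bundles) stopifnot(inherits(b, "dataset_bundle"))
  if (length(bundles) == 1L) return(bundles[[1]]$matrix)
  if (length(bundles) > 3L) {
    warning(sprintf("merging %d datasets; more than 3 exceeds the tool's documented design limit",
                    length(bundles)), call. = FALSE)
  }
  chroms <- vapply(bundles, function(b) b$matrix$chromosome, character(1))
  if (length(unique(chroms)) > 1L) {
    stop(sprintf("chromosome mismatch across datasets: %s",
                 paste(unique(chroms), collapse = " vs ")), call. = FALSE)
  }

  union_pos <- sort(unique(unlist(lapply(bundles,
                                         function(b) b$matrix$positions))))
  np <- length(union_pos)

  # merged reference symbol per union position, checking agreement
  ref_sym <- rep(NA_character_, np)
  ref_from <- rep(NA_character_, np)
  for (b in bundles) {
    idx <- match(b$matrix$positions, union_pos)
    sym <- b$matrix$calls[, 1]
    fresh <- is.na(ref_sym[idx])
    ref_sym[idx[fresh]] <- sym[fresh]
    ref_from[idx[fresh]] <- b$name
    clash <- !fresh & ref_sym[idx] != sym
    if (any(clash)) {
      where <- idx[clash][1]
      msg <- sprintf("reference symbols disagree at position %s (%s in %s vs %s in %s)",
                     format(union_pos[where], scientific = FALSE),
                     ref_sym[where], ref_from[where],
                     sym[clash][1], b$name)
      if (on_conflict == "error") stop(msg, call. = FALSE)
      warning(paste(msg, "- keeping the earlier dataset's symbol"),
              call. = FALSE)
    }
  }

  ref_name <- bundles[[1]]$matrix$samples[1]
  cols <- list()
  col_names <- character(0)
  for (bi in seq_along(bundles)) {
    b <- bundles[[bi]]
    m <- b$matrix
    idx <- match(m$positions, union_pos)
    take <- seq_along(m$samples)
    if (bi > 1L && m$samples[1] == ref_name) {
      message(sprintf("dropping duplicate reference column %s from dataset %s",
                      sQuote(ref_name), b$name))
      take <- take[-1L]
    }
    for (si in take) {
      col <- ref_sym                       # fill-in: reference symbol
      col[idx] <- m$calls[, si]
      nm <- m$samples[si]
      if (nm %in% col_names) {
        new_nm <- paste0(nm, "@", b$name)
        warning(sprintf("sample name collision: %s renamed to %s",
                        sQuote(nm), sQuote(new_nm)), call. = FALSE)
        nm <- new_nm
      }
      col_names <- c(col_names, nm)
      cols[[length(cols) + 1L]] <- col
    }
  }
  calls <- do.call(cbind, cols)
  snp_matrix(chroms[1], union_pos, col_names, calls)
}
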