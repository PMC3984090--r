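# Readers for the SNP-table, sample-header and annotation dialects;
# writers for the text and tree outputs.

#' Bundle a named dataset with its SNP matrix
#'
#' @param name dataset label (non-empty).
#' @param matrix an [snp_matrix()].
#' @param source_path provenance string (file the matrix was read from).
#' @return object of class `dataset_bundle`.
#' @export
dataset_bundle <- function(name, matrix, source_path = NA_character_) {
  if (!nzchar(name)) stop("dataset name must be non-empty", call. = FALSE)
  validate_snp_matrix(matrix)
  structure(list(name = as.character(name), matrix = matrix,
                 source_path = as.character(source_path)),
            class = "dataset_bundle")
}

#' Read a tab-delimited SNP table
#'
#' The dialect has no header line: every line is data, with the
#' chromosome label in column 1, the 1-based position in column 2, and
#' one genotype token per sample from column 3 on. The first sample
#' column is the reference genome. One file holds one chromosome.
#' Tokens are normalized with [normalize_symbol()] (so two-letter
#' heterozygote calls become IUPAC codes). Rows are sorted by position;
#' duplicate positions, ragged rows, non-integer positions and mixed
#' chromosome labels are errors with the offending line number.
#'
#' @param path file path (plain or gzip; Windows line endings and
#'   trailing blank lines are tolerated).
#' @param sample_names ordered sample names, one per genotype column;
#'   the first names the reference.
#' @return an [snp_matrix()].
#' @export
read_snp_table <- function(path, sample_names) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  sample_names <- as.character(sample_names)
  if (anyDuplicated(sample_names)) {
    stop("sample names must be unique", call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop(sprintf("empty SNP table: %s", path), call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  want <- 2L + length(sample_names)
  nf <- lengths(fields)
  if (any(nf != want)) {
    bad <- which(nf != want)[1]
    stop(sprintf("%s line %d: expected %d tab-delimited columns, found %d",
                 path, line_no[bad], want, nf[bad]), call. = FALSE)
  }
  tab <- matrix(unlist(fields, use.names = FALSE), ncol = want, byrow = TRUE)
  chrom <- trimws(tab[, 1])
  if (length(unique(chrom)) > 1L) {
    bad <- which(chrom != chrom[1])[1]
    stop(sprintf("%s line %d: one chromosome per file (found %s after %s)",
                 path, line_no[bad], sQuote(chrom[bad]), sQuote(chrom[1])),
         call. = FALSE)
  }
  pos_txt <- trimws(tab[, 2])
  ok_pos <- grepl("^[0-9]+$", pos_txt)
  if (!all(ok_pos)) {
    bad <- which(!ok_pos)[1]
    stop(sprintf("%s line %d: position %s is not an integer",
                 path, line_no[bad], sQuote(pos_txt[bad])), call. = FALSE)
  }
  pos <- as.numeric(pos_txt)
  if (anyDuplicated(pos)) {
    bad <- which(duplicated(pos))[1]
    stop(sprintf("%s line %d: duplicate position %s",
                 path, line_no[bad], format(pos[bad], scientific = FALSE)),
         call. = FALSE)
  }
  raw <- tab[, -(1:2), drop = FALSE]
  syms <- normalize_symbol_quietly(raw)
  dim(syms) <- dim(raw)
  if (anyNA(syms)) {
    bad <- which(is.na(syms), arr.ind = TRUE)[1, ]
    stop(sprintf("%s line %d, column %d (sample %s): invalid genotype token %s",
                 path, line_no[bad[1]], bad[2] + 2L,
                 sQuote(sample_names[bad[2]]),
                 sQuote(raw[bad[1], bad[2]])), call. = FALSE)
  }
  o <- order(pos)
  snp_matrix(chrom[1], pos[o], sample_names, syms[o, , drop = FALSE])
}

#' Write a SNP matrix in the input table dialect
#'
#' Emits the same headerless tab-delimited format [read_snp_table()]
#' consumes, so merged or simulated matrices can feed back into the
#' pipeline.
#'
#' @param m an [snp_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_snp_table <- function(m, path) {
  validate_snp_matrix(m)
  rows <- apply(cbind(m$chromosome,
                      format(m$positions, scientific = FALSE, trim = TRUE),
                      m$calls),
                1L, paste, collapse = "\t")
  writeLines(as.character(rows), path)
  invisible(path)
}

#' Read an ordered sample-name list from a header file
#'
#' Two dialects are accepted. The XML dialect is a root `<dataset>`
#' element (a `name` attribute is optional) containing one `<sample>`
#' element per sample, in order; the sample name is the element text.
#' Any file not starting with `<` is read as the plain-text fallback:
#' one name per line, blanks skipped. In both dialects the first name
#' denotes the reference genome.
#'
#' @param path file path.
#' @return character vector of sample names in document order.
#' @export
read_sample_header <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  first <- trimws(readLines(path, n = 1L, warn = FALSE))
  if (length(first) == 1L && startsWith(first, "<")) {
    doc <- tryCatch(xml2::read_xml(path), error = function(e) {
      stop(sprintf("malformed XML header %s: %s", path, conditionMessage(e)),
           call. = FALSE)
    })
    names <- trimws(xml2::xml_text(xml2::xml_find_all(doc, ".//sample")))
  } else {
    names <- trimws(readLines(path, warn = FALSE))
    names <- names[nzchar(names)]
  }
  if (length(names) == 0L) {
    stop(sprintf("no sample names found in %s", path), call. = FALSE)
  }
  if (anyDuplicated(names)) {
    stop(sprintf("duplicate sample name(s) in %s: %s", path,
                 paste(sQuote(unique(names[duplicated(names)])), collapse = ", ")),
         call. = FALSE)
  }
  names
}

#' Write the XML sample-header dialect
#'
#' @param sample_names ordered sample names (first = reference).
#' @param path output file.
#' @param dataset_name value of the root element's `name` attribute.
#' @return `path`, invisibly.
#' @export
write_sample_header <- function(sample_names, path, dataset_name = "dataset") {
  doc <- xml2::xml_new_root("dataset", name = dataset_name)
  for (nm in sample_names) {
    xml2::xml_add_child(doc, "sample", nm)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read gene models from a GFF3/GFF2/GTF annotation file
#'
#' Features are grouped by the value of `id_attribute` (the chosen
#' identification feature, e.g. `ID`, `Name`, `locus_id`, `gene_id`). The gene span comes from `gene` or `mRNA`
#' records (falling back to the range of the grouped features), exons
#' from `exon` records or, when a group has none, from `CDS` records.
#'
#' @param path annotation file (any dialect `rtracklayer` imports).
#' @param id_attribute attribute key used to group features; default `"ID"`.
#' @param r optional [region()]: only models overlapping it are returned
#'   (an empty overlap yields an empty list, not an error).
#' @return list of [gene_model()] objects sorted by span start.
#' @export
read_annotation <- function(path, id_attribute = "ID", r = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  gr <- rtracklayer::import(path)
  meta <- as.data.frame(gr)
  if (!id_attribute %in% names(meta) || all(is.na(meta[[id_attribute]]))) {
    keys <- setdiff(names(meta),
                    c("seqnames", "start", "end", "width", "strand",
                      "source", "type", "score", "phase"))
    stop(sprintf("attribute %s not present in %s; available keys: %s",
                 sQuote(id_attribute), path, paste(keys, collapse = ", ")),
         call. = FALSE)
  }
  ids <- as.character(meta[[id_attribute]])
  type <- tolower(as.character(meta$type))
  models <- list()
  for (id in unique(ids[!is.na(ids)])) {
    rows <- which(ids == id)
    chrom <- as.character(meta$seqnames[rows[1]])
    strand <- as.character(meta$strand[rows[1]])
    if (!strand %in% c("+", "-")) strand <- "+"
    span_rows <- rows[type[rows] %in% c("gene", "mrna", "transcript")]
    span_start <- if (length(span_rows)) min(meta$start[span_rows]) else min(meta$start[rows])
    span_end <- if (length(span_rows)) max(meta$end[span_rows]) else max(meta$end[rows])
    exon_rows <- rows[type[rows] == "exon"]
    if (length(exon_rows) == 0L) exon_rows <- rows[type[rows] == "cds"]
    exons <- lapply(exon_rows, function(i) {
      region(chrom, meta$start[i], meta$end[i])
    })
    models[[length(models) + 1L]] <-
      gene_model(id, strand, region(chrom, span_start, span_end), exons)
  }
  starts <- vapply(models, function(g) g$span$start, numeric(1))
  models <- models[order(starts)]
  if (!is.null(r)) {
    models <- Filter(function(g) {
      g$span$chromosome == r$chromosome &&
        g$span$start <= r$end && g$span$end >= r$start
    }, models)
  }
  models
}

#' Write GFF3 for a list of gene models
#'
#' Emits one `gene` record plus its `exon` records per model, with `ID`
#' attributes readable back through [read_annotation()].
#'
#' @param models list of [gene_model()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (g in models) {
    lines <- c(lines, paste(
      g$span$chromosome, "haploviz", "gene",
      format(g$span$start, scientific = FALSE),
      format(g$span$end, scientific = FALSE),
      ".", g$strand, ".", sprintf("ID=%s", g$name), sep = "\t"))
    for (i in seq_along(g$exons)) {
      e <- g$exons[[i]]
      lines <- c(lines, paste(
        e$chromosome, "haploviz", "exon",
        format(e$start, scientific = FALSE),
        format(e$end, scientific = FALSE),
        ".", g$strand, ".",
        sprintf("ID=%s;Parent=%s", g$name, g$name), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# gene/exon annotation strings for a vector of positions
annotate_positions <- function(positions, models) {
  gene_col <- character(length(positions))
  exon_col <- character(length(positions))
  for (g in models) {
    hit <- positions >= g$span$start & positions <= g$span$end
    gene_col[hit] <- ifelse(nzchar(gene_col[hit]),
                            paste(gene_col[hit], g$name, sep = ","), g$name)
    for (i in seq_along(g$exons)) {
      e <- g$exons[[i]]
      ehit <- positions >= e$start & positions <= e$end
      lbl <- sprintf("%s:exon%d", g$name, i)
      exon_col[ehit] <- ifelse(nzchar(exon_col[ehit]),
                               paste(exon_col[ehit], lbl, sep = ","), lbl)
    }
  }
  list(gene = gene_col, exon = exon_col)
}

#' Write the per-position SNP text report
#'
#' A human-facing tab-delimited report (one row per SNP position with
#' chromosome, position and per-sample symbols, plus gene/exon columns
#' when models are supplied). Unlike the input dialect, the report has a
#' header row.
#'
#' @param m an [snp_matrix()].
#' @param r optional [region()] to restrict to.
#' @param models optional list of [gene_model()] for annotation columns.
#' @param path output file.
#' @param display_order optional permutation of sample names fixing the
#'   column order (e.g. [leaf_display_order()] of the tree).
#' @return `path`, invisibly.
#' @export
write_region_report <- function(m, r = NULL, models = NULL, path,
                                display_order = NULL) {
  validate_snp_matrix(m)
  if (!is.null(r)) m <- slice_region(m, r)
  samples <- m$samples
  if (!is.null(display_order)) {
    if (!setequal(display_order, samples)) {
      stop("display_order must be a permutation of the sample names",
           call. = FALSE)
    }
    samples <- display_order
  }
  calls <- m$calls[, samples, drop = FALSE]
  header <- c("chromosome", "position", samples)
  if (!is.null(models)) header <- c(header, "gene", "exon")
  rows <- character(0)
  if (length(m$positions) > 0L) {
    body <- cbind(m$chromosome,
                  format(m$positions, scientific = FALSE, trim = TRUE),
                  calls)
    if (!is.null(models)) {
      ann <- annotate_positions(m$positions, models)
      body <- cbind(body, ann$gene, ann$exon)
    }
    rows <- apply(body, 1L, paste, collapse = "\t")
  }
  writeLines(c(paste(header, collapse = "\t"), as.character(rows)), path)
  invisible(path)
}

#' Write a distance matrix as tab-delimited text
#'
#' Square matrix with row and column sample labels; distances rendered
#' with six decimal places.
#'
#' @param dm a `dist_matrix` from [distance_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "dist_matrix"))
  vals <- matrix(sprintf("%.6f", dm$d), nrow = nrow(dm$d))
  rows <- vapply(seq_along(dm$samples), function(i) {
    paste(c(dm$samples[i], vals[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(paste(c("", dm$samples), collapse = "\t"), rows), path)
  invisible(path)
}

#' Read back a distance matrix written by [write_distance_matrix()]
#'
#' @param path file path.
#' @return a `dist_matrix` (the `compared` counts are not stored in the
#'   text format and come back as `NA`).
#' @export
read_distance_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  d <- as.matrix(tab)
  structure(list(samples = rownames(d), d = d,
                 compared = matrix(NA_integer_, nrow(d), ncol(d)),
                 zero_overlap_pairs = character(0)),
            class = "dist_matrix")
}

# ---- Newick export ----------------------------------------------------

newick_node <- function(node, parent_height) {
  bl <- parent_height - node$height
  if (!is.null(node$leaf)) {
    return(sprintf("%s:%s", node$leaf, format(bl, digits = 10)))
  }
  sprintf("(%s):%s",
          paste(vapply(node$children, newick_node, character(1),
                       parent_height = node$height),
                collapse = ","),
          format(bl, digits = 10))
}

#' Newick string for a haplotype tree
#'
#' Branch lengths are parent height minus child height, so root-to-leaf
#' path lengths all equal the root height (the tree is ultrametric).
#'
#' @param t a `haplo_tree`.
#' @return Newick string terminated by `";"`.
#' @export
newick_string <- function(t) {
  stopifnot(inherits(t, "haplo_tree"))
  if (!is.null(t$leaf)) return(sprintf("%s;", t$leaf))
  inner <- paste(vapply(t$children, newick_node, character(1),
                        parent_height = t$height),
                 collapse = ",")
  sprintf("(%s);", inner)
}

#' Write a haplotype tree as Newick
#'
#' @param t a `haplo_tree`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(t, path) {
  writeLines(newick_string(t), path)
  invisible(path)
}
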