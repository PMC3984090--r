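# Deterministic pictorial output: SNP grid colored against the
# reference, dendrogram panel, gene-annotation sidebar.
#
# All drawing happens in a numeric RGB raster written with png/jpeg, and
# all text uses the embedded 5x7 bitmap font below, so identical inputs
# give byte-identical PNG files (no system fonts, no graphics device).

# ---- color tables -----------------------------------------------------

# base colors of the multi-color mode plus a fixed 10-entry auxiliary
# palette for the ambiguity codes (one distinct color per code)
MULTI_COLOR_MAP <- c(
  A = "red", G = "blue", C = "green", T = "yellow",
  R = "orange", Y = "purple", S = "cyan", W = "magenta",
  K = "brown", M = "pink", B = "olive", D = "teal",
  H = "navy", V = "maroon",
  N = "gray", `-` = "gray"
)

COLOR_RGB <- list(
  white   = c(1, 1, 1),
  black   = c(0, 0, 0),
  gray    = c(0.62, 0.62, 0.62),
  red     = c(0.90, 0.10, 0.10),
  blue    = c(0.15, 0.25, 0.90),
  green   = c(0.10, 0.65, 0.15),
  yellow  = c(0.95, 0.85, 0.10),
  orange  = c(1.00, 0.55, 0.00),
  purple  = c(0.55, 0.00, 0.55),
  cyan    = c(0.00, 0.75, 0.80),
  magenta = c(0.90, 0.10, 0.75),
  brown   = c(0.55, 0.27, 0.07),
  pink    = c(1.00, 0.60, 0.75),
  olive   = c(0.50, 0.50, 0.00),
  teal    = c(0.00, 0.50, 0.50),
  navy    = c(0.05, 0.05, 0.45),
  maroon  = c(0.50, 0.05, 0.05),
  genebody = c(0.80, 0.90, 0.80),
  exon     = c(0.20, 0.55, 0.25)
)

#' Cell color for one genotype symbol
#'
#' Three-color mode classifies each call against the reference symbol
#' at the same position: identical calls are white, different calls
#' black, missing data gray. Multi-color mode colors by nucleotide
#' (A red, G blue, C green, T yellow), gray for missing, and a fixed
#' auxiliary palette for the ten ambiguity codes.
#'
#' @param symbol,ref single genotype symbols.
#' @param mode `"three_color"` or `"multi_color"`.
#' @return a color name (key of the package's RGB table).
#' @export
cell_color <- function(symbol, ref, mode = c("three_color", "multi_color")) {
  mode <- match.arg(mode)
  if (mode == "three_color") {
    if (is_missing_symbol(symbol)) return("gray")
    if (symbol == ref) return("white")
    return("black")
  }
  unname(MULTI_COLOR_MAP[symbol])
}

#' Rendering options
#'
#' @param mode `"three_color"` (default) or `"multi_color"`.
#' @param show_letters overlay the nucleotide on each cell.
#' @param show_space insert a one-cell gap between sample columns.
#' @param include_annotation draw the gene/exon sidebar when models are
#'   supplied.
#' @param cell_size cell edge in pixels (>= 1; >= 9 recommended when
#'   letters are shown).
#' @param tree_height dendrogram panel height in pixels.
#' @param max_pixels refuse renders larger than this pixel area; very
#'   large regions belong in the text report, which has no cap.
#' @return list of class `render_options`.
#' @export
render_options <- function(mode = c("three_color", "multi_color"),
                           show_letters = FALSE, show_space = FALSE,
                           include_annotation = TRUE,
                           cell_size = 12L, tree_height = 60L,
                           max_pixels = 4e7) {
  mode <- match.arg(mode)
  if (cell_size < 1L) stop("cell_size must be >= 1 pixel", call. = FALSE)
  structure(list(mode = mode, show_letters = isTRUE(show_letters),
                 show_space = isTRUE(show_space),
                 include_annotation = isTRUE(include_annotation),
                 cell_size = as.integer(cell_size),
                 tree_height = as.integer(tree_height),
                 max_pixels = max_pixels),
            class = "render_options")
}

# ---- 5x7 bitmap font --------------------------------------------------

FONT_5x7 <- local({
  raw <- list(
    "0" = c(".###.", "#...#", "#..##", "#.#.#", "##..#", "#...#", ".###."),
    "1" = c("..#..", ".##..", "..#..", "..#..", "..#..", "..#..", ".###."),
    "2" = c(".###.", "#...#", "....#", "...#.", "..#..", ".#...", "#####"),
    "3" = c(".###.", "#...#", "....#", "..##.", "....#", "#...#", ".###."),
    "4" = c("...#.", "..##.", ".#.#.", "#..#.", "#####", "...#.", "...#."),
    "5" = c("#####", "#....", "####.", "....#", "....#", "#...#", ".###."),
    "6" = c("..##.", ".#...", "#....", "####.", "#...#", "#...#", ".###."),
    "7" = c("#####", "....#", "...#.", "..#..", ".#...", ".#...", ".#..."),
    "8" = c(".###.", "#...#", "#...#", ".###.", "#...#", "#...#", ".###."),
    "9" = c(".###.", "#...#", "#...#", ".####", "....#", "...#.", ".##.."),
    A = c(".###.", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
    B = c("####.", "#...#", "#...#", "####.", "#...#", "#...#", "####."),
    C = c(".###.", "#...#", "#....", "#....", "#....", "#...#", ".###."),
    D = c("####.", "#...#", "#...#", "#...#", "#...#", "#...#", "####."),
    G = c(".###.", "#...#", "#....", "#.###", "#...#", "#...#", ".###."),
    H = c("#...#", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
    K = c("#...#", "#..#.", "#.#..", "##...", "#.#..", "#..#.", "#...#"),
    M = c("#...#", "##.##", "#.#.#", "#.#.#", "#...#", "#...#", "#...#"),
    N = c("#...#", "##..#", "#.#.#", "#..##", "#...#", "#...#", "#...#"),
    R = c("####.", "#...#", "#...#", "####.", "#.#..", "#..#.", "#...#"),
    S = c(".###.", "#...#", "#....", ".###.", "....#", "#...#", ".###."),
    T = c("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "..#.."),
    V = c("#...#", "#...#", "#...#", "#...#", "#...#", ".#.#.", "..#.."),
    W = c("#...#", "#...#", "#...#", "#.#.#", "#.#.#", "##.##", "#...#"),
    Y = c("#...#", "#...#", ".#.#.", "..#..", "..#..", "..#..", "..#.."),
    "-" = c(".....", ".....", ".....", "#####", ".....", ".....", "....."),
    "+" = c(".....", "..#..", "..#..", "#####", "..#..", "..#..", "....."),
    " " = c(".....", ".....", ".....", ".....", ".....", ".....", ".....")
  )
  lapply(raw, function(rows) {
    do.call(rbind, lapply(strsplit(rows, ""), function(r) r == "#"))
  })
})

# paint one glyph with top-left corner (x, y); out-of-raster pixels clip
draw_glyph <- function(img, x, y, ch, rgb) {
  g <- FONT_5x7[[ch]]
  if (is.null(g)) return(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  for (r in 1:7) {
    for (cc in 1:5) {
      if (g[r, cc]) {
        yy <- y + r - 1L; xx <- x + cc - 1L
        if (yy >= 1L && yy <= h && xx >= 1L && xx <= w) {
          img[yy, xx, ] <- rgb
        }
      }
    }
  }
  img
}

draw_text <- function(img, x, y, text, rgb) {
  chars <- strsplit(toupper(text), "")[[1]]
  for (i in seq_along(chars)) {
    img <- draw_glyph(img, x + (i - 1L) * 6L, y, chars[i], rgb)
  }
  img
}

fill_rect <- function(img, x0, y0, x1, y1, rgb) {
  h <- dim(img)[1]; w <- dim(img)[2]
  ys <- max(1L, y0):min(h, y1); xs <- max(1L, x0):min(w, x1)
  for (ch in 1:3) img[ys, xs, ch] <- rgb[ch]
  img
}

draw_hline <- function(img, y, x0, x1, rgb) fill_rect(img, min(x0, x1), y, max(x0, x1), y, rgb)
draw_vline <- function(img, x, y0, y1, rgb) fill_rect(img, x, min(y0, y1), x, max(y0, y1), rgb)

# ---- geometry ---------------------------------------------------------

#' Pixel dimensions of a pictorial render
#'
#' The layout is affine in the inputs: width is the position-label
#' gutter plus `n_samples` cells (doubled pitch when spacing is on)
#' plus the annotation sidebar; height is the tree panel plus one cell
#' row per SNP position.
#'
#' @param n_positions,n_samples matrix dimensions.
#' @param opts a [render_options()].
#' @param label_chars characters in the widest row label.
#' @param n_models number of annotation gene models drawn.
#' @return named numeric `c(height =, width =)`.
#' @export
pictorial_dimensions <- function(n_positions, n_samples, opts,
                                 label_chars = 10L, n_models = 0L) {
  cell <- opts$cell_size
  pitch <- if (opts$show_space) 2L * cell else cell
  label_w <- label_chars * 6L + 6L
  ann_w <- if (n_models > 0L && opts$include_annotation) {
    n_models * (cell + 2L) + 6L
  } else 0L
  width <- label_w + (n_samples - 1L) * pitch + cell + ann_w + 2L
  height <- opts$tree_height + 4L + n_positions * cell + 2L
  c(height = height, width = width)
}

# x pixel center of sample column j (1-based, display order)
column_center <- function(j, label_w, cell, pitch) {
  label_w + (j - 1L) * pitch + cell %/% 2L
}

# recursive dendrogram painter; returns list(img, x) where x is the
# node's horizontal center
draw_tree <- function(img, node, leaf_x, y_of, rgb) {
  if (!is.null(node$leaf)) {
    return(list(img = img, x = leaf_x[[node$leaf]]))
  }
  y <- y_of(node$height)
  xs <- numeric(0)
  for (ch in node$children) {
    res <- draw_tree(img, ch, leaf_x, y_of, rgb)
    img <- res$img
    img <- draw_vline(img, res$x, y_of(ch$height), y, rgb)
    xs <- c(xs, res$x)
  }
  img <- draw_hline(img, y, min(xs), max(xs), rgb)
  list(img = img, x = round(mean(range(xs))))
}

# ---- renderer ---------------------------------------------------------

#' Render the clustering pictorial
#'
#' Draws the SNP matrix as a grid — rows are SNP positions in ascending
#' coordinate order with the position and the reference nucleotide
#' printed on the left; columns are samples in the tree's left-to-right
#' leaf order — under the UPGMA dendrogram, with an optional gene/exon
#' sidebar (one column per gene model: light fill over the gene body,
#' dark fill over exons, strand sign on top). Cell colors follow
#' [cell_color()]; letters can be overlaid. Output format is chosen by
#' the file extension (`.png`, or `.jpg`/`.jpeg` when the jpeg package
#' is installed); PNG output is byte-deterministic.
#'
#' @param m an [snp_matrix()].
#' @param t a `haplo_tree` whose leaves are exactly `m`'s samples.
#' @param models optional list of [gene_model()] for the sidebar.
#' @param opts a [render_options()].
#' @param path output image path.
#' @return `path`, invisibly.
#' @export
render_pictorial <- function(m, t, models = NULL, opts = render_options(),
                             path) {
  validate_snp_matrix(m)
  stopifnot(inherits(t, "haplo_tree"), inherits(opts, "render_options"))
  order <- leaf_display_order(t)
  if (!setequal(order, m$samples)) {
    stop("tree leaves and matrix samples differ", call. = FALSE)
  }
  ext <- tolower(sub(".*\\.", "", path))
  if (!ext %in% c("png", "jpg", "jpeg")) {
    stop(sprintf("unknown image extension %s (use .png, .jpg or .jpeg)",
                 sQuote(ext)), call. = FALSE)
  }
  if (ext %in% c("jpg", "jpeg") && !requireNamespace("jpeg", quietly = TRUE)) {
    stop("JPEG output needs the jpeg package; use .png", call. = FALSE)
  }

  cell <- opts$cell_size
  pitch <- if (opts$show_space) 2L * cell else cell
  n_pos <- length(m$positions)
  n_smp <- length(m$samples)
  pos_lab <- format(m$positions, scientific = FALSE, trim = TRUE)
  row_lab <- paste(pos_lab, m$calls[, 1])
  label_chars <- if (n_pos > 0L) max(nchar(row_lab)) else 1L
  n_models <- if (!is.null(models) && opts$include_annotation) length(models) else 0L
  dims <- pictorial_dimensions(n_pos, n_smp, opts, label_chars, n_models)
  if (prod(dims) > opts$max_pixels) {
    stop(sprintf("render of %d x %d pixels exceeds the %g-pixel cap; use the text report for very large regions",
                 dims["height"], dims["width"], opts$max_pixels),
         call. = FALSE)
  }
  label_w <- label_chars * 6L + 6L
  grid_top <- opts$tree_height + 4L

  img <- array(1, c(dims[["height"]], dims[["width"]], 3L))

  # dendrogram panel
  leaf_x <- as.list(stats::setNames(
    vapply(seq_len(n_smp), column_center, numeric(1),
           label_w = label_w, cell = cell, pitch = pitch),
    order))
  root_h <- max(t$height, .Machine$double.eps)
  y_of <- function(h) 2L + round((1 - h / root_h) * (opts$tree_height - 3L))
  res <- draw_tree(img, t, leaf_x, y_of, COLOR_RGB$black)
  img <- res$img

  # SNP grid
  ref_sym <- m$calls[, 1]
  for (i in seq_len(n_pos)) {
    y0 <- grid_top + (i - 1L) * cell
    img <- draw_text(img, 3L, y0 + max(0L, (cell - 7L) %/% 2L),
                     row_lab[i], COLOR_RGB$black)
    for (j in seq_len(n_smp)) {
      sym <- m$calls[i, order[j]]
      col <- cell_color(sym, ref_sym[i], opts$mode)
      rgb <- COLOR_RGB[[col]]
      x0 <- label_w + (j - 1L) * pitch
      img <- fill_rect(img, x0, y0, x0 + cell - 1L, y0 + cell - 1L, rgb)
      if (opts$show_letters && cell >= 7L) {
        lum <- sum(rgb * c(0.299, 0.587, 0.114))
        fg <- if (lum > 0.5) COLOR_RGB$black else COLOR_RGB$white
        img <- draw_glyph(img, x0 + (cell - 5L) %/% 2L,
                          y0 + (cell - 7L) %/% 2L, sym, fg)
      }
    }
  }

  # annotation sidebar
  if (n_models > 0L) {
    ann_x0 <- dims[["width"]] - (n_models * (cell + 2L) + 6L) + 4L
    for (k in seq_len(n_models)) {
      g <- models[[k]]
      x0 <- ann_x0 + (k - 1L) * (cell + 2L)
      img <- draw_glyph(img, x0 + max(0L, (cell - 5L) %/% 2L),
                        grid_top - 10L, g$strand, COLOR_RGB$black)
      for (i in seq_len(n_pos)) {
        p <- m$positions[i]
        if (p >= g$span$start && p <= g$span$end) {
          in_exon <- any(vapply(g$exons, function(e) {
            p >= e$start && p <= e$end
          }, logical(1)))
          rgb <- if (in_exon) COLOR_RGB$exon else COLOR_RGB$genebody
          y0 <- grid_top + (i - 1L) * cell
          img <- fill_rect(img, x0, y0, x0 + cell - 1L, y0 + cell - 1L, rgb)
        }
      }
    }
  }

  if (ext == "png") {
    png::writePNG(img, path)
  } else {
    jpeg::writeJPEG(img, path, quality = 0.95)
  }
  invisible(path)
}
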