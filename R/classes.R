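#' Construct a slide image
#'
#' A `slide_image` wraps an 8-bit RGB raster of one IHC-stained serial section
#' together with its marker name, position in the section stack and resolution
#' scale (1 = original scanner resolution).
#'
#' @param pixels numeric H x W x 3 array with values in \[0, 255\].
#' @param marker marker (antibody) name, e.g. `"POSTN"` or `"CD163"`.
#' @param section_index integer position of the section in the serial stack.
#' @param scale resolution relative to the original image (1 = full).
#' @return An object of class `slide_image`.
#' @export
slide_image <- function(pixels, marker = "unknown", section_index = 1L, scale = 1) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3, dim(pixels)[3] == 3,
            all(dim(pixels)[1:2] > 0), scale > 0)
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 255) stop("pixel values must lie in [0, 255]", call. = FALSE)
  structure(list(pixels = pixels, marker = marker,
                 section_index = as.integer(section_index), scale = scale),
            class = "slide_image")
}

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<slide_image> %d x %d RGB, marker %s, section %d, scale %.4g\n",
              d[1], d[2], x$marker, x$section_index, x$scale))
  invisible(x)
}

#' @export
dim.slide_image <- function(x) dim(x$pixels)[1:2]

#' Construct a deformation field
#'
#' A dense pull-back displacement field: `disp[r, c, ]` is the `(d_row,
#' d_col)` displacement, in pixels at the field's own resolution, added to a
#' reference-frame coordinate to find the corresponding moving-frame
#' coordinate. Coordinates are 0-based `(row, col)`.
#'
#' @param disp numeric H x W x 2 array of displacements (finite).
#' @param scale resolution of the field relative to the original image.
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(disp, scale = 1) {
  stopifnot(is.array(disp), length(dim(disp)) == 3, dim(disp)[3] == 2, scale > 0)
  if (!all(is.finite(disp))) stop("displacements must be finite", call. = FALSE)
  structure(list(disp = disp, scale = scale), class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  d <- dim(x$disp)
  mag <- sqrt(x$disp[, , 1]^2 + x$disp[, , 2]^2)
  cat(sprintf("<deformation_field> %d x %d at scale %.4g, |d| mean %.3f max %.3f px\n",
              d[1], d[2], x$scale, mean(mag), max(mag)))
  invisible(x)
}

#' @export
dim.deformation_field <- function(x) dim(x$disp)[1:2]

# Zero field matching an image grid.
zero_field <- function(height, width, scale = 1) {
  deformation_field(array(0, c(height, width, 2)), scale = scale)
}

#' Construct an expression matrix
#'
#' Container for a nonnegative cell-by-gene expression matrix (RPKM-like
#' values) with per-cell annotation columns (sample, group/origin, cluster).
#'
#' @param values numeric cells x genes matrix, nonnegative; rownames are cell
#'   ids and colnames gene names (generated when missing).
#' @param cell_data `data.frame` with one row per cell (may be zero-column).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, cell_data = NULL) {
  if (inherits(values, "Matrix")) values <- as.matrix(values)
  stopifnot(is.matrix(values), is.numeric(values))
  if (any(values < 0)) stop("expression values must be nonnegative", call. = FALSE)
  if (is.null(rownames(values)) && nrow(values) > 0)
    rownames(values) <- sprintf("cell%d", seq_len(nrow(values)))
  if (is.null(colnames(values)) && ncol(values) > 0)
    colnames(values) <- sprintf("gene%d", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values))) stop("cell ids must be unique", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("gene names must be unique", call. = FALSE)
  if (is.null(cell_data)) cell_data <- data.frame(row.names = rownames(values))
  stopifnot(nrow(cell_data) == nrow(values))
  structure(list(values = values, cell_data = cell_data), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d cells x %d genes; cell annotations: %s\n",
              nrow(x$values), ncol(x$values),
              if (ncol(x$cell_data)) paste(names(x$cell_data), collapse = ", ") else "none"))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

# Generic two-group test result container used across the statistics module.
test_result <- function(method, statistic, p, n, gate = NULL) {
  stopifnot(p > 0, p <= 1)
  structure(list(method = method, statistic = unname(statistic), p = p,
                 n = n, gate = gate), class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.4g, p = %.4g (n = %s)\n",
              x$method, x$statistic, x$p, paste(x$n, collapse = "/")))
  if (!is.null(x$gate)) cat("  normality gate:", x$gate$outcome, "\n")
  invisible(x)
}
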