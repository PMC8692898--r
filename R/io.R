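#' Write a slide image to PNG or TIFF
#'
#' @param image a [slide_image()].
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return Invisibly, `path`.
#' @export
write_slide <- function(image, path) {
  stopifnot(inherits(image, "slide_image"))
  arr <- image$pixels / 255
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(arr, path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(arr, path, bits.per.sample = 8)
  } else stop("path must end in .png, .tif or .tiff", call. = FALSE)
  invisible(path)
}

#' Read a slide image from PNG or TIFF
#'
#' @param path input path.
#' @param marker,section_index,scale metadata attached to the slide.
#' @return A [slide_image()].
#' @export
read_slide <- function(path, marker = "unknown", section_index = 1L, scale = 1) {
  arr <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
  else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) tiff::readTIFF(path)
  else stop("path must end in .png, .tif or .tiff", call. = FALSE)
  if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), c(dim(arr), 3))
  if (dim(arr)[3] > 3) arr <- arr[, , 1:3]
  slide_image(round(arr * 255), marker = marker,
              section_index = section_index, scale = scale)
}

#' Write compartment annotations as a GeoJSON FeatureCollection
#'
#' One polygon feature per compartment polygon, property `label`; ring
#' coordinates are written `[col, row]` (x, y) 0-based, holes as additional
#' rings.
#'
#' @param layout a `tissue_layout`.
#' @param path output `.geojson` path.
#' @return Invisibly, `path`.
#' @export
write_annotation_geojson <- function(layout, path) {
  stopifnot(inherits(layout, "tissue_layout"))
  ring_coords <- function(ring) {
    m <- cbind(ring[, 2], ring[, 1])
    m <- rbind(m, m[1, ])                  # closed ring
    lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
  }
  feats <- list()
  for (lab in names(layout$compartments)) {
    for (poly in layout$compartments[[lab]]) {
      rings <- c(list(ring_coords(poly$outer)), lapply(poly$holes, ring_coords))
      feats[[length(feats) + 1]] <- list(
        type = "Feature",
        properties = list(label = lab),
        geometry = list(type = "Polygon", coordinates = rings))
    }
  }
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read compartment polygons from GeoJSON
#'
#' @param path a `.geojson` FeatureCollection written by
#'   [write_annotation_geojson()] (or compatible: polygon features with a
#'   `label` property, `[x, y]` coordinates).
#' @return Named list of polygon lists (`list(outer=, holes=)`, 0-based
#'   `(row, col)` rings), keyed by label.
#' @export
read_annotation_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  out <- list()
  for (f in fc$features) {
    lab <- f$properties$label
    rings <- lapply(f$geometry$coordinates, function(ring) {
      m <- do.call(rbind, lapply(ring, function(p) c(p[[2]], p[[1]])))
      m[-nrow(m), , drop = FALSE]          # drop closing vertex
    })
    poly <- list(outer = rings[[1]],
                 holes = if (length(rings) > 1) rings[-1] else list())
    out[[lab]] <- c(out[[lab]], list(poly))
  }
  out
}

#' Write / read landmark pairs as CSV
#'
#' @param landmarks data frame with columns `row_fixed`, `col_fixed`,
#'   `row_moving`, `col_moving`.
#' @param path CSV path.
#' @return Invisibly `path` (write); the data frame (read).
#' @export
write_landmarks_csv <- function(landmarks, path) {
  stopifnot(all(c("row_fixed", "col_fixed", "row_moving", "col_moving") %in%
                  names(landmarks)))
  write.csv(landmarks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks_csv
#' @export
read_landmarks_csv <- function(path) read.csv(path)

#' Write a deformation field with a JSON sidecar
#'
#' The two displacement bands are stored as a long CSV (`row`, `col`,
#' `d_row`, `d_col`, 0-based grid coordinates); the sidecar records the
#' scale and the pull-back `(row, col)` convention.
#'
#' @param field a [deformation_field()].
#' @param prefix output path prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`.
#' @return Invisibly, the two paths.
#' @export
write_field <- function(field, prefix) {
  stopifnot(inherits(field, "deformation_field"))
  d <- dim(field$disp)
  idx <- which(matrix(TRUE, d[1], d[2]))
  df <- data.frame(row = (idx - 1) %% d[1], col = (idx - 1) %/% d[1],
                   d_row = as.numeric(field$disp[, , 1]),
                   d_col = as.numeric(field$disp[, , 2]))
  csv <- paste0(prefix, ".csv"); js <- paste0(prefix, ".json")
  write.csv(df, csv, row.names = FALSE)
  jsonlite::write_json(list(scale = field$scale, n_rows = d[1], n_cols = d[2],
                            convention = "pullback_row_col_0based"),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = js))
}

#' @rdname write_field
#' @param prefix path prefix used by `write_field`.
#' @export
read_field <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"))
  df <- read.csv(paste0(prefix, ".csv"))
  disp <- array(0, c(meta$n_rows, meta$n_cols, 2))
  disp[, , 1] <- df$d_row
  disp[, , 2] <- df$d_col
  deformation_field(disp, scale = meta$scale)
}

#' Write / read an expression matrix as MatrixMarket + TSVs
#'
#' Writes `<prefix>.mtx` (genes stored column-wise, cells x genes sparse),
#' `<prefix>.genes.tsv`, `<prefix>.cells.tsv` (cell id plus any annotation
#' columns).
#'
#' @param matrix an [expression_matrix()].
#' @param prefix output path prefix.
#' @return Invisibly the paths (write); an [expression_matrix()] (read).
#' @export
write_expression_mtx <- function(matrix, prefix) {
  stopifnot(inherits(matrix, "expression_matrix"))
  m <- Matrix::Matrix(matrix$values, sparse = TRUE)
  Matrix::writeMM(m, paste0(prefix, ".mtx"))
  writeLines(colnames(matrix$values), paste0(prefix, ".genes.tsv"))
  cells <- data.frame(cell = rownames(matrix$values), matrix$cell_data,
                      check.names = FALSE)
  write.table(cells, paste0(prefix, ".cells.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(paste0(prefix, c(".mtx", ".genes.tsv", ".cells.tsv")))
}

#' @rdname write_expression_mtx
#' @export
read_expression_mtx <- function(prefix) {
  m <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  genes <- readLines(paste0(prefix, ".genes.tsv"))
  cells <- read.delim(paste0(prefix, ".cells.tsv"), check.names = FALSE)
  colnames(m) <- genes
  rownames(m) <- cells$cell
  expression_matrix(m, cells[, setdiff(names(cells), "cell"), drop = FALSE])
}

#' Read a gene-signature list (one gene per line)
#'
#' @param path text file path.
#' @return Character vector of gene names (blank lines dropped).
#' @export
read_signature <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}
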