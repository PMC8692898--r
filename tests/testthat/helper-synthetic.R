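# Shared small fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures)
}

fix_layout <- function() memo("layout", function() {
  make_tissue_layout(360, 360, n_glands = 1, seed = 11)
})

fix_points <- function() memo("points", function() {
  plant_marker_points(fix_layout(),
                      list(POSTN = c(T = 1e-4, IF = 6e-4, S = 1.5e-3)),
                      seed = 12)$POSTN
})

fix_slide <- function() memo("slide", function() {
  render_ihc_image(fix_layout(), fix_points(), blob_radius = 4, dab_od = 0.8,
                   seed = 13)
})

# stain_channels with a given DAB matrix and flat hematoxylin (for tests that
# exercise detection/tiling logic directly)
make_channels <- function(dab, hema = NULL) {
  if (is.null(hema)) hema <- matrix(0, nrow(dab), ncol(dab))
  structure(list(hema_od = hema, dab_od = dab,
                 stain_vectors = hdab_stain_vectors()),
            class = "stain_channels")
}

# positive_detection built directly from a mask (optionally with objects)
make_detection <- function(mask, objects = NULL, min_area = 1) {
  if (is.null(objects)) {
    ch <- make_channels(mask * 1)
    return(detect_positive(ch, threshold = 0.5, min_area = min_area))
  }
  structure(list(mask = mask, objects = objects, threshold = 0.5,
                 min_area = min_area),
            class = "positive_detection")
}

# density_map on a synthetic grid from a plain matrix of values (all valid)
make_map <- function(values, tile_size = 10, marker = "m") {
  nr <- nrow(values); nc <- ncol(values)
  grid <- structure(list(origin = c(0, 0), tile_size = as.integer(tile_size),
                         n_rows = nr, n_cols = nc,
                         tissue_px = matrix(tile_size^2, nr, nc),
                         valid = matrix(TRUE, nr, nc),
                         region_mask = matrix(TRUE, nr * tile_size, nc * tile_size)),
                    class = "tile_grid")
  structure(list(marker = marker, grid = grid, values = values,
                 mode = "object_count"),
            class = "density_map")
}

# independent average-rank oracle for signature scores: rank of gene g within
# cell x via the closed form #{less} + (#{equal} + 1) / 2
oracle_score <- function(values, signature) {
  sig <- match(signature, colnames(values))
  apply(values, 1, function(x) {
    r <- vapply(sig, function(g) sum(x < x[g]) + (sum(x == x[g]) + 1) / 2,
                numeric(1))
    mean(r) / length(x)
  })
}

# draw disk blobs (value 1) at 0-based centers on an h x w zero matrix
draw_blobs <- function(h, w, centers, radius) {
  m <- matrix(0, h, w)
  for (i in seq_len(nrow(centers))) {
    rr <- pmax(0, round(centers[i, 1]) - radius):pmin(h - 1, round(centers[i, 1]) + radius)
    cc <- pmax(0, round(centers[i, 2]) - radius):pmin(w - 1, round(centers[i, 2]) + radius)
    d2 <- outer((rr - centers[i, 1])^2, (cc - centers[i, 2])^2, `+`)
    sub <- m[rr + 1, cc + 1]
    sub[d2 <= radius^2] <- 1
    m[rr + 1, cc + 1] <- sub
  }
  m
}
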