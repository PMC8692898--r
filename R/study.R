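#' Simulate a complete serial-section IHC study with ground truth
#'
#' Convenience generator tying the synthetic pieces together: one tissue
#' layout, one marker point process per section, a rendered slide per
#' section, and — for every non-reference section — a known smooth
#' deformation (with landmark pairs) distorting it, emulating how serial
#' sections of one block are individually stretched on glass. The middle
#' section is left undistorted and acts as the registration reference.
#'
#' The default marker panel and per-compartment rates emulate the study
#' design this package targets: an endothelial/iCAF-type marker enriched in
#' tumor glands (CD34), an eCAF marker densest in distal stroma (POSTN), and
#' an M2-macrophage marker (CD163) tracking the stroma with partial overlap.
#'
#' @param width,height slide size in pixels.
#' @param n_glands tumor glands in the layout.
#' @param rates named list of per-compartment intensities per marker (one
#'   section per marker); `NULL` gives the default three-marker panel.
#' @param max_disp maximum random displacement in pixels at full resolution.
#' @param smoothness smoothing length of the random deformation, pixels.
#' @param blob_radius DAB blob radius per positive cell, pixels.
#' @param coloc_rho latent-field correlation between the markers.
#' @param seed integer seed driving every random choice.
#' @return List with `layout`, `points`, `images` (one [slide_image()] per
#'   marker/section), `ground_truth` (per-section list with `field` and
#'   `landmarks`, `NULL` for the reference) and `reference` (index).
#' @export
simulate_serial_study <- function(width = 2000, height = 2000, n_glands = 3,
                                  rates = NULL, max_disp = 60, smoothness = 300,
                                  blob_radius = 6, coloc_rho = 0, seed = 1) {
  if (is.null(rates)) {
    rates <- list(CD34  = c(T = 3e-4, IF = 2e-4, S = 1e-4, LN = 2e-4),
                  POSTN = c(T = 5e-5, IF = 3e-4, S = 6e-4, LN = 1e-4),
                  CD163 = c(T = 1e-4, IF = 3e-4, S = 4e-4, LN = 4e-4))
  }
  base <- as.integer(seed) %% 100000L * 1000L
  layout <- make_tissue_layout(width, height, n_glands = n_glands, seed = base + 1)
  # drop rate entries for compartments the layout could not place (e.g. LN)
  rates <- lapply(rates, function(r) r[names(r) %in% names(layout$compartments)])
  points <- plant_marker_points(layout, rates, coloc_rho = coloc_rho,
                                seed = base + 2)
  n <- length(rates)
  ref <- floor((n + 1) / 2)
  images <- vector("list", n)
  ground_truth <- vector("list", n)
  for (i in seq_len(n)) {
    img <- render_ihc_image(layout, points[[i]], blob_radius = blob_radius,
                            seed = base + 10 + i)
    img$section_index <- i
    if (i == ref) {
      images[[i]] <- img
    } else {
      d <- apply_deformation(img, max_disp = max_disp, smoothness = smoothness,
                             rigid_part = list(angle = 1.5 * (i - ref),
                                               shift = c(10 * (i - ref),
                                                         -8 * (i - ref))),
                             seed = base + 20 + i)
      images[[i]] <- d$image
      ground_truth[[i]] <- d[c("field", "landmarks")]
    }
  }
  list(layout = layout, points = points, images = images,
       ground_truth = ground_truth, reference = ref)
}
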