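#' Tissue pre-segmentation of the structure channel
#'
#' Reproduces the pre-segmentation step that excludes scar debris and suture
#' material outside the heart: global threshold (Otsu by default), a
#' one-voxel morphological opening, retention of the largest 26-connected
#' component, and filling of internal cavities smaller than a configurable
#' fraction of the component (the LV chamber itself stays open). The result
#' is a single connected foreground component.
#'
#' @param image a [volume_image()] with tissue brighter than background.
#' @param threshold fixed threshold; `NULL` (default) uses Otsu's method.
#' @param opening_voxels radius of the single-voxel opening (iterations of the
#'   6-neighbour cross); 0 disables.
#' @param max_hole_frac fill internal background cavities smaller than this
#'   fraction of the tissue component (the chamber, being larger, survives).
#' @param min_component_voxels error out if the largest component is smaller
#'   than this (guards against pure-noise inputs).
#' @param min_component_frac error out unless the largest component holds at
#'   least this fraction of the post-opening foreground — scattered noise
#'   foreground has no such dominant component.
#' @return a [volume_mask()] (`kind = "tissue"`).
#' @export
tissue_mask <- function(image, threshold = NULL, opening_voxels = 1L,
                        max_hole_frac = 0.1, min_component_voxels = 50L,
                        min_component_frac = 0.5) {
  data <- vol_data(image)
  sp <- vol_spacing(image)
  thr <- if (is.null(threshold)) otsu_threshold(as.vector(data)) else threshold
  fg <- array(data > thr, dim(data))
  if (opening_voxels > 0) fg <- open_voxel(fg, as.integer(opening_voxels))
  if (!any(fg)) stop("empty foreground after threshold and opening")
  comp <- largest_component(fg, connectivity = 26)
  n_comp <- sum(comp)
  if (n_comp < min_component_voxels || n_comp < min_component_frac * sum(fg))
    stop("no dominant tissue component (largest has ", n_comp, " of ",
         sum(fg), " foreground voxels)")
  # fill small enclosed cavities: background components (6-connectivity) that
  # do not touch the grid boundary and are below the size cutoff
  bg_lab <- label_components(!comp, connectivity = 6)
  border_labels <- unique(c(bg_lab[1, , ], bg_lab[dim(bg_lab)[1], , ],
                            bg_lab[, 1, ], bg_lab[, dim(bg_lab)[2], ],
                            bg_lab[, , 1], bg_lab[, , dim(bg_lab)[3]]))
  border_labels <- setdiff(border_labels, 0L)
  sizes <- tabulate(bg_lab)
  fill <- setdiff(which(sizes < max_hole_frac * n_comp), border_labels)
  if (length(fill)) comp[bg_lab %in% fill] <- TRUE
  volume_mask(comp, sp, kind = "tissue",
              provenance = sprintf("otsu=%s threshold=%.6g", is.null(threshold),
                                   thr))
}

#' Segment the LV chamber as the enclosed cavity of the tissue mask
#'
#' Classical chamber segmenter fulfilling the same mask contract as a learned
#' model (externally produced chamber masks can be passed straight to the
#' downstream morphometry). The basal valve-plane opening is capped by
#' morphological closing of the tissue mask with a Euclidean ball larger than
#' the aperture (default 1 mm diameter); the chamber is then the largest
#' enclosed cavity: a 6-connected background component of the capped tissue
#' not touching the grid boundary. Tissue connectivity is 26, cavity
#' connectivity 6; ties in "largest" break deterministically by scan order.
#'
#' @param tissue a [volume_mask()] from [tissue_mask()] (or supplied).
#' @param closing_radius_um radius of the capping ball in µm (default 500,
#'   i.e. a 1 mm element).
#' @return a [volume_mask()] (`kind = "chamber"`), disjoint from `tissue`.
#' @export
segment_chamber <- function(tissue, closing_radius_um = 500) {
  td <- mask_data(tissue)
  sp <- vol_spacing(tissue)
  capped <- if (closing_radius_um > 0) close_ball(td, closing_radius_um, sp)
            else td
  bg_lab <- label_components(!capped, connectivity = 6)
  border_labels <- unique(c(bg_lab[1, , ], bg_lab[dim(bg_lab)[1], , ],
                            bg_lab[, 1, ], bg_lab[, dim(bg_lab)[2], ],
                            bg_lab[, , 1], bg_lab[, , dim(bg_lab)[3]]))
  border_labels <- setdiff(border_labels, 0L)
  sizes <- tabulate(bg_lab)
  if (length(sizes)) sizes[border_labels] <- 0L
  if (!length(sizes) || max(sizes) == 0L)
    stop("no enclosed cavity found; is the basal opening larger than the ",
         "closing element?")
  cavity <- bg_lab == which.max(sizes)
  # the closing also fills narrow cavity recesses (the sharp apex of a
  # conical chamber); reconstruct the full cavity over the original
  # complement, excluding everything connected to the outside of the capped
  # volume, so the chamber keeps its apex but stays sealed at the base
  outside <- array(bg_lab %in% border_labels, dim(td))
  region <- !td & !outside
  reg_lab <- label_components(region, connectivity = 6)
  keep <- setdiff(unique(reg_lab[cavity]), 0L)
  chamber <- array(reg_lab %in% keep, dim(td))
  volume_mask(chamber, sp, kind = "chamber",
              provenance = sprintf("cavity of closed tissue (r=%g um)",
                                   closing_radius_um))
}

#' Diastole quality control of a segmented chamber
#'
#' Hearts not fixed in full diastole are excluded by thresholding the chamber
#' volume (strictly above 10 mm^3) and the long-axis length (strictly above
#' 4 mm, measured as the chamber extent along its first principal axis).
#' Both thresholds are configurable; the inequalities are strict.
#'
#' @param chamber a [volume_mask()] of the LV chamber.
#' @param min_volume_mm3 volume threshold (mm^3).
#' @param min_long_axis_mm long-axis threshold (mm).
#' @return a one-row [tibble::tibble()] with `volume_mm3`, `long_axis_mm`,
#'   `pass`, and a `reasons` list-column naming any failed criteria.
#' @export
diastole_qc <- function(chamber, min_volume_mm3 = 10, min_long_axis_mm = 4) {
  if (!any(mask_data(chamber))) stop("empty chamber mask")
  vol <- mask_volume_mm3(chamber)
  frame <- principal_axes(chamber)
  coords <- mask_coords_um(chamber)
  proj <- as.vector((coords %*% frame$axes[1, ]) -
                      sum(frame$centroid_um * frame$axes[1, ]))
  long_axis_mm <- (max(proj) - min(proj)) / 1000
  reasons <- character()
  if (!(vol > min_volume_mm3))
    reasons <- c(reasons, sprintf("volume %.2f mm3 not above %g mm3", vol,
                                  min_volume_mm3))
  if (!(long_axis_mm > min_long_axis_mm))
    reasons <- c(reasons, sprintf("long axis %.2f mm not above %g mm",
                                  long_axis_mm, min_long_axis_mm))
  tibble::tibble(volume_mm3 = vol, long_axis_mm = long_axis_mm,
                 pass = length(reasons) == 0L, reasons = list(reasons))
}
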