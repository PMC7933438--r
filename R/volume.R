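#' 3D volume containers
#'
#' `volume_image()` wraps a 3D numeric array with its per-axis voxel spacing
#' in micrometres; `volume_mask()` does the same for binary masks. The axis
#' order is fixed as (z, y, x): array dimension 1 is the optical z-axis,
#' dimensions 2 and 3 the in-plane axes. Physical coordinates follow the
#' voxel-centre convention, `coord = (index - 1) * spacing`, with all internal
#' units in µm (volumes are converted to mm^3 only at the reporting boundary).
#'
#' @param data 3D numeric (or logical, for masks) array, axis order (z, y, x).
#' @param spacing_um numeric length-3 voxel spacing in µm, all > 0. A scalar
#'   is recycled to an isotropic spacing.
#' @param channel channel name, e.g. `"structure"` or `"lectin"`.
#' @param kind mask kind label, e.g. `"tissue"`, `"chamber"`, `"vessels"`.
#' @param provenance free-text note on how the mask was produced.
#' @return A `volume_image` or `volume_mask` object (list with elements
#'   `data`, `spacing_um` and metadata).
#' @examples
#' img <- volume_image(array(rnorm(8 * 8 * 8), c(8, 8, 8)), spacing_um = 5)
#' voxel_volume_um3(img)
#' @export
volume_image <- function(data, spacing_um, channel = "structure") {
  spacing_um <- check_spacing(spacing_um)
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!is.numeric(data)) storage.mode(data) <- "double"
  if (any(!is.finite(data))) stop("volume data must be finite")
  structure(list(data = data, spacing_um = spacing_um, channel = channel),
            class = "volume_image")
}

#' @rdname volume_image
#' @export
volume_mask <- function(data, spacing_um, kind = "mask", provenance = "") {
  spacing_um <- check_spacing(spacing_um)
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!is.logical(data)) {
    data <- array(data != 0, dim(data))
  }
  structure(list(data = data, spacing_um = spacing_um, kind = kind,
                 provenance = provenance),
            class = "volume_mask")
}

check_spacing <- function(spacing_um) {
  if (length(spacing_um) == 1L) spacing_um <- rep(spacing_um, 3L)
  stopifnot(length(spacing_um) == 3L, all(is.finite(spacing_um)),
            all(spacing_um > 0))
  as.numeric(spacing_um)
}

#' @rdname volume_image
#' @export
voxel_volume_um3 <- function(x) prod(vol_spacing(x))

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_image> %s  %d x %d x %d voxels (z,y,x), spacing %s um\n",
              x$channel, d[1], d[2], d[3],
              paste(signif(x$spacing_um, 4), collapse = " x ")))
  invisible(x)
}

#' @export
print.volume_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<volume_mask> %s  %d x %d x %d voxels (z,y,x), spacing %s um, %d foreground\n",
    x$kind, d[1], d[2], d[3], paste(signif(x$spacing_um, 4), collapse = " x "),
    sum(x$data)))
  invisible(x)
}

#' @export
as.array.volume_image <- function(x, ...) x$data

#' @export
as.array.volume_mask <- function(x, ...) x$data

# internal accessors tolerating bare arrays (spacing then mandatory)
vol_data <- function(x) {
  if (inherits(x, "volume_image") || inherits(x, "volume_mask")) x$data else x
}
vol_spacing <- function(x, spacing_um = NULL) {
  if (inherits(x, "volume_image") || inherits(x, "volume_mask"))
    return(x$spacing_um)
  if (is.null(spacing_um)) stop("spacing_um required for bare arrays")
  check_spacing(spacing_um)
}
mask_data <- function(x) {
  d <- vol_data(x)
  if (!is.logical(d)) array(d != 0, dim(d)) else d
}

#' Mask volume in mm^3
#'
#' Foreground voxel count times the physical voxel volume, reported in mm^3
#' (1 mm^3 = 1e9 µm^3).
#' @param mask a `volume_mask` (or logical array with `spacing_um` supplied).
#' @param spacing_um spacing override for bare arrays.
#' @return volume in mm^3.
#' @export
mask_volume_mm3 <- function(mask, spacing_um = NULL) {
  sp <- vol_spacing(mask, spacing_um)
  sum(mask_data(mask)) * prod(sp) / 1e9
}

# physical (z,y,x) coordinates of foreground voxels, µm; n x 3 matrix
mask_coords_um <- function(mask, spacing_um = NULL) {
  sp <- vol_spacing(mask, spacing_um)
  d <- mask_data(mask)
  idx <- which(d)
  ai <- arrayInd(idx, dim(d))
  sweep(ai - 1, 2, sp, `*`)
}

#' Euclidean distance to a voxel set
#'
#' Exact anisotropic Euclidean distance transform: for every voxel, the
#' distance in µm to the nearest foreground voxel centre of `set`.
#' Distances honour per-axis spacing directly (no resampling).
#' @param set logical array or `volume_mask`.
#' @param spacing_um spacing override for bare arrays.
#' @return numeric array of distances (µm); `Inf` if `set` is empty.
#' @export
dist_to_set <- function(set, spacing_um = NULL) {
  sp <- vol_spacing(set, spacing_um)
  d <- mask_data(set)
  dist_to_set_cpp(d, dim(d), sp)
}

#' Connected component labelling
#'
#' Labels foreground components with 6- or 26-connectivity. Labels are
#' assigned in voxel scan order, so ties in component size are broken
#' deterministically by lowest linear voxel index.
#' @param mask logical array or `volume_mask`.
#' @param connectivity 6 or 26.
#' @return integer array of labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(connectivity %in% c(6L, 26L))
  d <- mask_data(mask)
  label_components_cpp(d, dim(d), as.integer(connectivity))
}

# keep the largest component; ties broken by lowest label (= scan order)
largest_component <- function(mask, connectivity = 26) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(array(FALSE, dim(lab)))
  sizes <- tabulate(lab)
  lab == which.max(sizes)
}

# morphological closing with a Euclidean ball of physical radius (µm),
# computed through two distance transforms (exact for anisotropic grids)
close_ball <- function(mask, radius_um, spacing_um = NULL) {
  sp <- vol_spacing(mask, spacing_um)
  d <- mask_data(mask)
  dil <- dist_to_set_cpp(d, dim(d), sp) <= radius_um
  er <- dist_to_set_cpp(!dil, dim(d), sp) > radius_um
  array(er, dim(d))
}

# single-voxel opening with the 6-neighbour cross element
open_voxel <- function(mask, iterations = 1L) {
  d <- mask_data(mask)
  dims <- dim(d)
  for (t in seq_len(iterations)) d <- morph_step_cpp(d, dims, FALSE)
  for (t in seq_len(iterations)) d <- morph_step_cpp(d, dims, TRUE)
  array(d, dims)
}

# Otsu threshold from a 256-bin histogram of x
otsu_threshold <- function(x, levels = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = levels)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  breaks[which.max(sb) + 1L]
}
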