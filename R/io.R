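#' Read a 3D volume from TIFF or NIfTI
#'
#' Accepts a multi-page TIFF stack, a directory of single-page TIFFs
#' (stacked in lexicographic filename order along z), or a NIfTI-1 file.
#' TIFF files carry no reliable 3D spacing tags, so spacing is taken from the
#' JSON sidecar written by [write_volume()] (`<path>.meta.json`) when present,
#' else from `spacing_override`; an error is raised if neither is available.
#' NIfTI pixdim values are interpreted as millimetres (the NIfTI default) and
#' converted to µm. The first array axis is treated as z.
#'
#' @param path file or directory path.
#' @param spacing_override numeric length-3 (z, y, x) spacing in µm, used when
#'   the file carries no spacing metadata.
#' @param channel channel name attached to the result.
#' @return a [volume_image()].
#' @export
read_volume <- function(path, spacing_override = NULL, channel = "structure") {
  if (!file.exists(path)) stop("cannot read volume: ", path)
  is_nifti <- grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)
  if (is_nifti) {
    img <- RNifti::readNifti(path)
    sp_mm <- RNifti::pixdim(img)[1:3]
    data <- array(as.numeric(img), dim(img)[1:3])
    spacing <- if (all(is.finite(sp_mm)) && all(sp_mm > 0)) sp_mm * 1000
               else spacing_override
    if (is.null(spacing)) stop("no spacing in NIfTI header and no override given")
    return(volume_image(data, spacing, channel))
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (length(files) == 0L) stop("no TIFF slices found in ", path)
    slices <- lapply(files, function(f) as_gray(tiff::readTIFF(f)))
    shp <- vapply(slices, dim, integer(2))
    if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
      stop("inconsistent slice shapes in ", path)
    data <- simplify2array(slices)        # (y, x, z)
    meta_path <- file.path(path, "volume.meta.json")
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, as_gray)
    data <- simplify2array(pages)         # (y, x, z)
    meta_path <- paste0(path, ".meta.json")
  }
  data <- aperm(data, c(3, 1, 2))          # -> (z, y, x)
  spacing <- spacing_override
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$spacing_um)) spacing <- meta$spacing_um
    if (!is.null(meta$channel) && missing(channel)) channel <- meta$channel
    if (!is.null(meta$value_scale))
      data <- data * meta$value_scale + meta$value_offset
  }
  if (is.null(spacing)) stop("no spacing metadata for ", path,
                             " and no spacing_override given")
  volume_image(data, spacing, channel)
}

as_gray <- function(m) {
  if (length(dim(m)) == 3L) m <- m[, , 1L]  # first sample of multi-channel pages
  m
}

#' Write a 3D volume as multi-page TIFF with a spacing sidecar
#'
#' Scalar volumes are written as 32-bit pages. TIFF samples are stored as
#' normalized integers, so the value range is rescaled to \[0, 1\] on write
#' and the affine transform recorded in the `<path>.meta.json` sidecar
#' together with voxel spacing and channel name; [read_volume()] restores
#' physical values (e.g. thickness maps in µm) to the stored 32-bit
#' precision.
#'
#' @param vol a [volume_image()] (or numeric array plus `spacing_um`).
#' @param path output `.tif` path.
#' @param spacing_um spacing for bare arrays.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, spacing_um = NULL) {
  sp <- vol_spacing(vol, spacing_um)
  data <- vol_data(vol)
  channel <- if (inherits(vol, "volume_image")) vol$channel else "structure"
  offset <- min(data)
  scale <- max(data) - offset
  if (scale <= 0) scale <- 1
  scaled <- (data - offset) / scale
  pages <- lapply(seq_len(dim(data)[1]),
                  function(i) matrix(scaled[i, , ], dim(data)[2],
                                     dim(data)[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(spacing_um = sp, channel = channel,
                            value_offset = offset, value_scale = scale),
                       paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read binary and labelled masks as 8-bit TIFF
#'
#' Binary masks are stored as 0/255 8-bit pages; zone partitions as labels
#' 0 (background), 1 (infarct), 2 (border), 3 (remote). Spacing goes to the
#' same JSON sidecar as [write_volume()].
#' @param mask a [volume_mask()] or logical array; for `write_zones` an
#'   integer array of labels 0-3 (or a `zone_partition` object).
#' @param path output `.tif` path.
#' @param spacing_um spacing for bare arrays.
#' @rdname mask_io
#' @export
write_mask <- function(mask, path, spacing_um = NULL) {
  sp <- vol_spacing(mask, spacing_um)
  d <- mask_data(mask)
  pages <- lapply(seq_len(dim(d)[1]),
                  function(i) matrix(as.numeric(d[i, , ]), dim(d)[2], dim(d)[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, reduce = FALSE)
  jsonlite::write_json(list(spacing_um = sp, kind = "mask"),
                       paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname mask_io
#' @export
read_mask <- function(path, spacing_override = NULL, kind = "mask") {
  vol <- read_volume(path, spacing_override = spacing_override)
  volume_mask(vol$data > 0.5, vol$spacing_um, kind = kind,
              provenance = paste0("read from ", path))
}

#' @rdname mask_io
#' @export
write_zones <- function(mask, path, spacing_um = NULL) {
  if (inherits(mask, "zone_partition")) {
    spacing_um <- mask$spacing_um
    mask <- mask$labels
  }
  sp <- check_spacing(spacing_um)
  d <- vol_data(mask)
  stopifnot(all(d %in% 0:3))
  pages <- lapply(seq_len(dim(d)[1]),
                  function(i) matrix(d[i, , ] / 255, dim(d)[2], dim(d)[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, reduce = FALSE)
  jsonlite::write_json(list(spacing_um = sp, kind = "zones"),
                       paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname mask_io
#' @export
read_zones <- function(path, spacing_override = NULL) {
  vol <- read_volume(path, spacing_override = spacing_override)
  labels <- array(as.integer(round(vol$data * 255)), dim(vol$data))
  stopifnot(all(labels %in% 0:3))
  structure(list(labels = labels, spacing_um = vol$spacing_um,
                 cutoffs_um = NULL),
            class = "zone_partition")
}

#' Write a triangle mesh as PLY
#'
#' Binary little-endian PLY with double-precision vertex coordinates (so
#' geometry and any per-vertex scalar round-trip exactly) and an optional
#' per-vertex `quality` property carrying e.g. mean curvature. Loadable by
#' standard mesh viewers (Meshlab, trimesh).
#'
#' @param mesh a `surface_mesh` (see [chamber_mesh()]).
#' @param path output `.ply` path.
#' @param scalar optional per-vertex numeric attribute (length = n vertices).
#' @param ascii write ASCII PLY instead of binary.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, scalar = NULL, ascii = FALSE) {
  V <- mesh$vertices
  F <- mesh$faces
  if (is.null(F) || nrow(F) == 0L) stop("refusing to write an empty mesh")
  nV <- nrow(V)
  if (!is.null(scalar)) stopifnot(length(scalar) == nV)
  fmt <- if (ascii) "ascii" else "binary_little_endian"
  hdr <- c("ply", sprintf("format %s 1.0", fmt),
           "comment lvmorph surface mesh (coordinates in um)",
           sprintf("element vertex %d", nV),
           "property double x", "property double y", "property double z",
           if (!is.null(scalar)) "property double quality",
           sprintf("element face %d", nrow(F)),
           "property list uchar int vertex_indices",
           "end_header")
  # PLY x,y,z = physical x,y,z -> our columns are (z, y, x)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  vert <- cbind(V[, 3], V[, 2], V[, 1])
  if (!is.null(scalar)) vert <- cbind(vert, scalar)
  if (ascii) {
    writeLines(apply(vert, 1, function(r)
      paste(format(r, digits = 17, scientific = FALSE, trim = TRUE),
            collapse = " ")), con)
    writeLines(apply(F, 1, function(f)
      paste(c(3L, f - 1L), collapse = " ")), con)
  } else {
    writeBin(as.vector(t(vert)), con, size = 8, endian = "little")
    for (i in seq_len(nrow(F))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(F[i, ] - 1L), con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1L)
    hdr <- c(hdr, line)
    if (identical(line, "end_header")) break
    if (length(hdr) > 100L) stop("not a PLY file: ", path)
  }
  fmt <- sub("^format\\s+(\\S+).*", "\\1", grep("^format", hdr, value = TRUE))
  nV <- as.integer(sub("^element vertex\\s+", "",
                       grep("^element vertex", hdr, value = TRUE)))
  nF <- as.integer(sub("^element face\\s+", "",
                       grep("^element face", hdr, value = TRUE)))
  vstart <- which(grepl("^element vertex", hdr))
  vend <- which(grepl("^element face", hdr))
  props <- sub("^property \\S+ ", "", grep("^property (double|float)",
                                           hdr[vstart:vend], value = TRUE))
  np <- length(props)
  if (identical(fmt, "ascii")) {
    rest <- readLines(con)
    vrows <- do.call(rbind, lapply(rest[seq_len(nV)],
                                   function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
    frows <- do.call(rbind, lapply(rest[nV + seq_len(nF)],
                                   function(s) as.integer(strsplit(trimws(s), "\\s+")[[1]])))
    faces <- frows[, 2:4, drop = FALSE] + 1L
  } else {
    vrows <- matrix(readBin(con, "double", n = nV * np, size = 8,
                            endian = "little"), nV, np, byrow = TRUE)
    faces <- matrix(0L, nF, 3)
    for (i in seq_len(nF)) {
      cnt <- as.integer(readBin(con, "raw", n = 1L))
      idx <- readBin(con, "integer", n = cnt, size = 4, endian = "little")
      faces[i, ] <- idx[1:3] + 1L
    }
  }
  vertices <- cbind(vrows[, 3], vrows[, 2], vrows[, 1]) # x,y,z -> (z,y,x)
  colnames(vertices) <- c("z", "y", "x")
  scalar <- if ("quality" %in% props) vrows[, which(props == "quality")] else NULL
  out <- structure(list(vertices = vertices, faces = faces, spacing_um = NULL),
                   class = "surface_mesh")
  attr(out, "quality") <- scalar
  out
}
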