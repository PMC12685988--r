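#' Maximum-intensity projection of a CT slab
#'
#' Projects a 3-D HU volume along one axis, restricted to a slab given in
#' mm along that axis (voxels whose centres fall inside the bounds). The
#' slab is meant to cover all valvular calcification in one image; a
#' thickness outside 15-20 mm draws a warning but is allowed.
#'
#' @param volume 3-D numeric array of HU values.
#' @param spacing_mm Length-3 voxel spacing, mm.
#' @param axis Projection axis (1, 2 or 3).
#' @param slab_mm Length-2 slab bounds along `axis`, mm; `NULL` uses the
#'   full extent.
#' @return A list of class `mip_image` with `pixels` (matrix over the two
#'   remaining axes, in order), `spacing_mm` (of those axes),
#'   `thickness_mm` and `axis`.
#' @export
make_mip <- function(volume, spacing_mm = c(1, 1, 1), axis = 3L,
                     slab_mm = NULL) {
  stopifnot(is.array(volume), length(dim(volume)) == 3,
            length(spacing_mm) == 3, axis %in% 1:3)
  n_ax <- dim(volume)[axis]
  centres <- ((seq_len(n_ax)) - 0.5) * spacing_mm[axis]
  if (is.null(slab_mm)) slab_mm <- c(0, n_ax * spacing_mm[axis])
  keep <- which(centres >= slab_mm[1] & centres <= slab_mm[2])
  if (!length(keep)) {
    abort("make_mip: slab contains no voxel centres",
          class = "crushcurve_input_error")
  }
  thickness <- slab_mm[2] - slab_mm[1]
  if (thickness < 15 || thickness > 20) {
    warn(sprintf("make_mip: slab thickness %.1f mm outside the usual 15-20 mm",
                 thickness))
  }
  idx <- list(seq_len(dim(volume)[1]), seq_len(dim(volume)[2]),
              seq_len(dim(volume)[3]))
  idx[[axis]] <- keep
  sub <- volume[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  plane <- setdiff(1:3, axis)
  px <- apply(sub, plane, max)
  structure(list(pixels = px, spacing_mm = spacing_mm[plane],
                 thickness_mm = thickness, axis = axis),
            class = "mip_image")
}

# Even-odd (ray-casting) point-in-polygon test, vectorised over points.
# Points exactly on an edge follow the half-open crossing convention.
.point_in_polygon <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((poly_y[i] > py) != (poly_y[j] > py)) &
      (px < (poly_x[j] - poly_x[i]) * (py - poly_y[i]) /
         (poly_y[j] - poly_y[i]) + poly_x[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Mean CT number of high-density pixels inside an ROI
#'
#' Selects MIP pixels whose centres fall inside the polygon (even-odd
#' rule, 0-based pixel indices, pixel centre at its integer index) and
#' whose value is at or above the threshold (default 600 HU, the
#' calcification cut-off; the threshold is inclusive), then averages
#' them. With no qualifying pixel the measurement is flagged missing
#' rather than zero.
#'
#' @param mip A `mip_image` from [make_mip()].
#' @param roi Polygon vertices: a data frame/matrix with columns `x`, `y`
#'   in 0-based pixel units (first plane axis = x, second = y).
#' @param threshold_hu Inclusion threshold, HU.
#' @return A one-row tibble: `n_pixels` (count at/above threshold inside
#'   the ROI), `mean_hu` (`NA` when `n_pixels` is 0), `threshold_hu`.
#' @export
mean_ct_number <- function(mip, roi, threshold_hu = 600) {
  stopifnot(inherits(mip, "mip_image"))
  roi <- as.data.frame(roi)
  if (nrow(roi) < 3) {
    abort("mean_ct_number: ROI polygon needs at least 3 vertices",
          class = "crushcurve_input_error")
  }
  dims <- dim(mip$pixels)
  xs <- rep(seq_len(dims[1]) - 1L, times = dims[2])
  ys <- rep(seq_len(dims[2]) - 1L, each = dims[1])
  inside <- .point_in_polygon(xs, ys, roi$x, roi$y)
  vals <- as.vector(mip$pixels)[inside]
  qual <- vals[vals >= threshold_hu]
  if (!length(qual)) {
    warn("mean_ct_number: no pixel at/above threshold inside the ROI; mean flagged missing")
    return(tibble(n_pixels = 0L, mean_hu = NA_real_,
                  threshold_hu = threshold_hu))
  }
  tibble(n_pixels = length(qual), mean_hu = mean(qual),
         threshold_hu = threshold_hu)
}

#' Read a CT volume from NIfTI
#'
#' Thin wrapper over `RNifti` returning the array and voxel spacing in
#' the form [make_mip()] expects.
#'
#' @param path NIfTI file path.
#' @return A list with `volume` (3-D array) and `spacing_mm`.
#' @export
read_ct_volume <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("read_ct_volume requires the 'RNifti' package",
          class = "crushcurve_io_error")
  }
  img <- RNifti::readNifti(path)
  list(volume = unclass(as.array(img)),
       spacing_mm = RNifti::pixdim(img)[1:3])
}

#' Read an ROI polygon from JSON
#'
#' Expects a JSON object with arrays `x` and `y` (0-based pixel units) or
#' an array of `[x, y]` pairs.
#'
#' @param path JSON file path.
#' @return A tibble with columns `x`, `y`.
#' @export
read_roi <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (is.list(obj) && all(c("x", "y") %in% names(obj))) {
    return(tibble(x = as.numeric(obj$x), y = as.numeric(obj$y)))
  }
  m <- as.matrix(obj)
  if (ncol(m) != 2) {
    abort("read_roi: expected {x:[], y:[]} or an Nx2 array",
          class = "crushcurve_io_error")
  }
  tibble(x = as.numeric(m[, 1]), y = as.numeric(m[, 2]))
}
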