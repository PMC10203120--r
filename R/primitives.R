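# Thin R wrappers around the compiled morphological primitives. All of
# them accept a matrix (y, x) or a 3D array (y, x, z) and preserve dims.

.dims3 <- function(x) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop("expected a matrix or a 3D array")
  d
}

#' Euclidean distance transform
#'
#' Distance from every foreground (nonzero) element to the nearest
#' background (zero) element. `spacing` gives the physical step per axis
#' in `(y, x, z)` order, so anisotropic stacks can be transformed in
#' physical units.
#'
#' @param x Binary matrix or 3D array.
#' @param spacing Numeric vector of per-axis grid steps, recycled to the
#'   number of axes. Default 1 (isotropic, pixel units).
#' @return Numeric array of distances, same dims as `x`.
#' @examples
#' m <- matrix(0L, 5, 5); m[2:4, 2:4] <- 1L
#' distanceTransform(m)[3, 3]
#' @export
distanceTransform <- function(x, spacing = 1) {
  d <- .dims3(x)
  sp <- rep_len(as.numeric(spacing), length(d))
  out <- .edt_cpp(as.integer(x != 0), as.integer(d), sp)
  dim(out) <- d
  out
}

#' Gaussian smoothing of a 2D or 3D array
#'
#' Separable Gaussian filter (kernel truncated at four standard
#' deviations, edges replicated). For a 3D array, `inplane = TRUE`
#' smooths each slice independently.
#'
#' @param x Numeric matrix or 3D array.
#' @param sigma Standard deviation in pixels; 0 returns `x` unchanged.
#' @param inplane Smooth along y and x only (default `TRUE` for 3D input
#'   used slice-wise; ignored for matrices).
#' @return Smoothed array, same dims.
#' @export
gaussianSmooth <- function(x, sigma, inplane = TRUE) {
  d <- .dims3(x)
  out <- .gauss_cpp(as.numeric(x), as.integer(d), as.numeric(sigma),
                    isTRUE(inplane))
  dim(out) <- d
  out
}

#' Grayscale reconstruction by dilation
#'
#' Morphological reconstruction of `marker` under `mask` (marker is
#' iteratively dilated but never allowed to exceed mask). The workhorse
#' behind [hMaxima()].
#'
#' @param marker,mask Numeric arrays of identical dims with
#'   `marker <= mask` everywhere.
#' @param connectivity 4/8 (2D) or 6/18/26 (3D).
#' @return Reconstructed array.
#' @export
grayReconstruct <- function(marker, mask, connectivity = 4L) {
  d <- .dims3(marker)
  if (!identical(d, dim(mask))) stop("marker and mask dims differ")
  if (any(marker > mask + 1e-12)) stop("marker must not exceed mask")
  out <- .reconstruct_cpp(as.numeric(marker), as.numeric(mask),
                          as.integer(d), as.integer(connectivity))
  dim(out) <- d
  out
}

#' h-maxima seed mask
#'
#' Suppresses regional maxima whose depth relative to their surroundings
#' is smaller than `h`, returning a binary mask of the surviving maxima
#' plateaus. Used to obtain one watershed seed per cell from a (blurred)
#' distance map.
#'
#' @param x Numeric matrix or 3D array (e.g. a distance map).
#' @param h Depth threshold, in the units of `x`; must be > 0.
#' @param connectivity Neighbourhood code as in [grayReconstruct()].
#' @return Logical array marking seed plateaus.
#' @export
hMaxima <- function(x, h, connectivity = 4L) {
  if (h <= 0) stop("h must be > 0")
  rec <- grayReconstruct(x - h, x, connectivity)
  out <- (x - rec) >= h - 1e-9
  dim(out) <- dim(x)
  out
}

#' Connected-component labelling
#'
#' Labels connected regions of a binary array with consecutive positive
#' integers, numbered in the order of each component's first element in
#' column-major scan order (deterministic).
#'
#' @param x Binary matrix or 3D array.
#' @param connectivity 4/8 (2D) or 6/18/26 (3D).
#' @return Integer array of component labels.
#' @export
labelComponents <- function(x, connectivity = 4L) {
  d <- .dims3(x)
  out <- .label_cpp(as.integer(x != 0), as.integer(d),
                    as.integer(connectivity))
  dim(out) <- d
  out
}

#' Marker-controlled watershed
#'
#' Floods the elevation map from the labelled seeds, restricted to
#' `mask`; every masked element receives the label of the flood that
#' reaches it first (ties broken by insertion order, so results are
#' reproducible).
#'
#' @param elevation Numeric matrix or 3D array.
#' @param seeds Integer array of seed labels (0 elsewhere), same dims.
#' @param mask Binary array restricting the flood (default: everywhere).
#' @param connectivity Neighbourhood code.
#' @return Integer label array partitioning `mask`.
#' @export
seededWatershed <- function(elevation, seeds, mask = NULL,
                            connectivity = 4L) {
  d <- .dims3(elevation)
  if (!identical(d, dim(seeds))) stop("elevation and seeds dims differ")
  if (is.null(mask)) mask <- array(1L, d)
  if (!identical(d, dim(mask))) stop("elevation and mask dims differ")
  out <- .watershed_cpp(as.numeric(elevation), as.integer(seeds),
                        as.integer(mask != 0), as.integer(d),
                        as.integer(connectivity))
  dim(out) <- d
  out
}

# Per-label voxel counts and tight bounding boxes (internal).
.labelStats <- function(labels) {
  d <- .dims3(labels)
  .label_stats_cpp(as.integer(labels), as.integer(d))
}

# Row-major (y-then-x) scan position of matrix linear indices, used to
# give user-facing label orderings a reading-order convention.
.rowMajorPos <- function(idx, dimyx) {
  y <- (idx - 1L) %% dimyx[1L]
  x <- (idx - 1L) %/% dimyx[1L]
  y * dimyx[2L] + x  # row-major rank
}

# Relabel components so they are numbered by the row-major position of
# each component's first pixel.
.orderLabelsRowMajor <- function(lab) {
  d <- dim(lab)
  n <- max(lab)
  if (n == 0L) return(lab)
  idx <- which(lab > 0L)
  pos <- .rowMajorPos(idx, d)
  first <- vapply(split(pos, lab[idx]), min, numeric(1))
  ord <- order(first)                      # names are old labels in 1..n
  lut <- integer(n)
  lut[as.integer(names(first))[ord]] <- seq_len(n)
  out <- lab
  out[idx] <- lut[lab[idx]]
  out
}
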