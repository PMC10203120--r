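# Synthetic phantoms with known ground truth, emulating the failure
# modes the linking workflow targets: touching convex-ish cells, strong
# z anisotropy, stochastic boundary dropout, and per-slice misalignment.

#' Specification of a synthetic cell phantom
#'
#' @param dims Stack shape as `(Z, Y, X)` slices x rows x columns.
#' @param nCells Number of cells to place.
#' @param radiusRange Cell radius range in xy pixels (physical units).
#' @param zAnisotropy Ratio of z step to xy pixel size (default 5,
#'   typical of serial-section EM where z steps are several-fold coarser
#'   than the in-plane resolution).
#' @param boundaryDropout Probability that an inter-cell boundary pixel
#'   of the prediction is flipped back to foreground (missing-boundary
#'   failure mode). Default 0.
#' @param displacement Maximum per-slice rigid shift, in pixels, applied
#'   jointly to predictions and ground truth (misalignment failure
#'   mode). Default 0.
#' @param seed RNG seed; fixed seeds reproduce phantoms bit-for-bit.
#' @return A `PhantomSpec` object.
#' @examples
#' PhantomSpec(dims = c(16, 64, 64), nCells = 6)
#' @export
PhantomSpec <- function(dims = c(64L, 256L, 256L), nCells = 50L,
                        radiusRange = c(30, 45), zAnisotropy = 5,
                        boundaryDropout = 0, displacement = 0, seed = 1L) {
  new("PhantomSpec", dims = as.integer(dims), nCells = as.integer(nCells),
      radiusRange = as.numeric(radiusRange),
      zAnisotropy = as.numeric(zAnisotropy),
      boundaryDropout = as.numeric(boundaryDropout),
      displacement = as.numeric(displacement), seed = as.integer(seed))
}

#' @rdname PhantomSpec-class
#' @name PhantomSpec-class
#' @aliases PhantomSpec
#' @exportClass PhantomSpec
setClass("PhantomSpec", representation(
  dims = "integer", nCells = "integer", radiusRange = "numeric",
  zAnisotropy = "numeric", boundaryDropout = "numeric",
  displacement = "numeric", seed = "integer"
), validity = function(object) {
  if (length(object@dims) != 3L || any(object@dims < 1L))
    return("dims must be three positive integers (Z, Y, X)")
  if (object@nCells < 1L) return("nCells must be >= 1")
  if (length(object@radiusRange) != 2L || any(object@radiusRange < 1) ||
      diff(object@radiusRange) < 0)
    return("radiusRange must be an increasing pair of radii >= 1")
  if (object@zAnisotropy < 1) return("zAnisotropy must be >= 1")
  if (object@boundaryDropout < 0 || object@boundaryDropout > 1)
    return("boundaryDropout must be in [0, 1]")
  if (object@displacement < 0) return("displacement must be >= 0")
  TRUE
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %dx%dx%d (Z,Y,X), %d cells, r=[%g,%g] px, zAniso=%g\n",
    object@dims[1], object@dims[2], object@dims[3], object@nCells,
    object@radiusRange[1], object@radiusRange[2], object@zAnisotropy))
  cat(sprintf("  boundaryDropout=%g, displacement=%g, seed=%d\n",
              object@boundaryDropout, object@displacement, object@seed))
})

# run `expr` under a private RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# dart-throw cell nuclei. Two seeds may be close in xy only when they are
# far apart along (anisotropy-scaled) z and vice versa: laterally close
# pairs form in-plane boundaries that per-slice predictions can carry,
# while the constraint keeps distinct cells from meeting across a single
# z step, where a per-slice prediction has no boundary signal at all.
.placeSeeds <- function(spec) {
  Z <- spec@dims[1L]; Y <- spec@dims[2L]; X <- spec@dims[3L]
  za <- spec@zAnisotropy
  ys <- xs <- zs <- rs <- numeric(0)
  tries <- 0L
  maxTries <- 400L * spec@nCells
  while (length(rs) < spec@nCells && tries < maxTries) {
    tries <- tries + 1L
    r <- runif(1, spec@radiusRange[1L], spec@radiusRange[2L])
    y <- runif(1, 1, Y); x <- runif(1, 1, X); z <- runif(1, 1, Z)
    ok <- TRUE
    for (j in seq_along(rs)) {
      sumr <- r + rs[j]
      dxy <- sqrt((y - ys[j])^2 + (x - xs[j])^2)
      dz <- abs(z - zs[j]) * za
      if (dxy < 0.8 * sumr && dz < sumr) { ok <- FALSE; break }
    }
    if (ok) {
      ys <- c(ys, y); xs <- c(xs, x); zs <- c(zs, z); rs <- c(rs, r)
    }
  }
  if (length(rs) < spec@nCells)
    stop(sprintf("could not place %d cells in a %dx%dx%d stack",
                 spec@nCells, Z, Y, X))
  data.frame(y = ys, x = xs, z = zs, r = rs)
}

#' Generate a synthetic phantom with ground truth
#'
#' Grows `nCells` convex-ish cells from dart-thrown nuclei: a voxel
#' belongs to the nucleus nearest in the anisotropy-scaled metric,
#' restricted to that nucleus's radius, with one-z-step polar caps
#' trimmed so distinct cells never share a boundary parallel to the
#' cutting plane (a boundary a per-slice prediction cannot carry).
#' Predictions are derived from the ground truth: foreground with
#' one-pixel in-plane inter-cell boundaries set to background, boundary
#' pixels stochastically flipped back to foreground at rate
#' `boundaryDropout`, and finally a random per-slice rigid shift of
#' magnitude up to `displacement` applied jointly to predictions and
#' ground truth. Deterministic under a fixed seed.
#'
#' @param spec A [PhantomSpec].
#' @return List with `groundTruth` (integer label array `(y, x, z)`),
#'   `predictions` (binary array of the same shape) and `spec`.
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  .withSeed(spec@seed, {
    Z <- spec@dims[1L]; Y <- spec@dims[2L]; X <- spec@dims[3L]
    za <- spec@zAnisotropy
    seeds <- .placeSeeds(spec)

    gt <- array(0L, c(Y, X, Z))
    best <- array(Inf, c(Y, X, Z))
    for (i in seq_len(nrow(seeds))) {
      r <- seeds$r[i]
      zlo <- max(1L, ceiling(seeds$z[i] - (r - za) / za))
      zhi <- min(Z, floor(seeds$z[i] + (r - za) / za))
      if (zlo > zhi) next                 # cell thinner than one z step
      ylo <- max(1L, ceiling(seeds$y[i] - r))
      yhi <- min(Y, floor(seeds$y[i] + r))
      xlo <- max(1L, ceiling(seeds$x[i] - r))
      xhi <- min(X, floor(seeds$x[i] + r))
      dy2 <- ((ylo:yhi) - seeds$y[i])^2
      dx2 <- ((xlo:xhi) - seeds$x[i])^2
      lat2 <- outer(dy2, dx2, "+")
      for (z in zlo:zhi) {
        dz2 <- ((z - seeds$z[i]) * za)^2
        d2 <- lat2 + dz2
        hit <- lat2 <= r^2 - dz2 & d2 < best[ylo:yhi, xlo:xhi, z]
        if (any(hit)) {
          sl <- gt[ylo:yhi, xlo:xhi, z]
          bb <- best[ylo:yhi, xlo:xhi, z]
          sl[hit] <- i
          bb[hit] <- d2[hit]
          gt[ylo:yhi, xlo:xhi, z] <- sl
          best[ylo:yhi, xlo:xhi, z] <- bb
        }
      }
    }

    pred <- array(0L, dim(gt))
    pred[gt > 0L] <- 1L
    bidx <- .boundaryPixels(gt)
    pred[bidx] <- 0L
    if (spec@boundaryDropout > 0 && length(bidx)) {
      flip <- runif(length(bidx)) < spec@boundaryDropout
      pred[bidx[flip]] <- 1L
    }

    if (spec@displacement > 0) {
      dmax <- round(spec@displacement)
      for (z in seq_len(Z)) {
        dy <- sample(-dmax:dmax, 1L)
        dx <- sample(-dmax:dmax, 1L)
        pred[, , z] <- .shift2d(pred[, , z], dy, dx)
        gt[, , z] <- .shift2d(gt[, , z], dy, dx)
      }
    }
    list(groundTruth = gt, predictions = pred, spec = spec)
  })
}

# linear indices of the 1-px in-plane boundaries of a label volume: a
# foreground pixel is a boundary pixel when its +y or +x neighbour in
# the same slice carries a different nonzero label (one side marked,
# giving one-pixel-wide separations).
.boundaryPixels <- function(gt) {
  d <- dim(gt)
  idx <- integer()
  a <- gt[-d[1L], , , drop = FALSE]
  b <- gt[-1L, , , drop = FALSE]
  w <- which(a > 0L & b > 0L & a != b)
  if (length(w)) {
    w0 <- w - 1L
    y <- w0 %% (d[1L] - 1L)
    rest <- w0 %/% (d[1L] - 1L)
    idx <- c(idx, y + rest * d[1L] + 1L)
  }
  a <- gt[, -d[2L], , drop = FALSE]
  b <- gt[, -1L, , drop = FALSE]
  w <- which(a > 0L & b > 0L & a != b)
  if (length(w)) {
    w0 <- w - 1L
    y <- w0 %% d[1L]
    x <- (w0 %/% d[1L]) %% (d[2L] - 1L)
    z <- w0 %/% (d[1L] * (d[2L] - 1L))
    idx <- c(idx, y + x * d[1L] + z * d[1L] * d[2L] + 1L)
  }
  sort(unique(as.integer(idx)))
}

.shift2d <- function(m, dy, dx) {
  out <- array(0L, dim(m))
  d <- dim(m)
  ys <- max(1, 1 + dy):min(d[1], d[1] + dy)
  xs <- max(1, 1 + dx):min(d[2], d[2] + dx)
  if (!length(ys) || !length(xs)) return(out)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

#' Score a segmentation against ground truth
#'
#' Detection-style error rates over ground-truth cells. A GT cell is
#' *undersegmented* when its best-matching segmented cell (maximal voxel
#' overlap) is also the best match of another GT cell -- i.e. several
#' true cells share one label -- or when no segmented cell overlaps it at
#' all. It is *oversegmented* when more than one segmented cell claims at
#' least `minFraction` of its voxels. Both are reported as fractions of
#' all GT cells; scores are invariant to relabelling of the
#' segmentation.
#'
#' @param seg,gt Integer label arrays of identical shape.
#' @param minFraction Fraction of a GT cell's voxels a segmented cell
#'   must hold to count towards oversegmentation (default 0.1).
#' @return List with `undersegmented` and `oversegmented` fractions and
#'   `nCells` (number of GT cells).
#' @export
scoreSegmentation <- function(seg, gt, minFraction = 0.1) {
  if (!identical(dim(seg), dim(gt))) stop("seg and gt shapes differ")
  sel <- gt > 0L
  dt <- data.table::data.table(g = as.integer(gt[sel]),
                               s = as.integer(seg[sel]))
  ct <- dt[, list(n = .N), by = c("g", "s")]
  gvol <- ct[, list(vol = sum(n)), by = "g"]
  nCells <- nrow(gvol)
  if (nCells == 0L)
    return(list(undersegmented = NA_real_, oversegmented = NA_real_,
                nCells = 0L))

  nz <- ct[ct$s > 0L, ]
  # best seg match per GT cell (ties: smaller seg label)
  best <- nz[order(nz$g, -nz$n, nz$s), ]
  best <- best[!duplicated(best$g), ]
  shared <- best$s[duplicated(best$s) | duplicated(best$s, fromLast = TRUE)]
  underIds <- unique(c(best$g[best$s %in% shared],
                       setdiff(gvol$g, best$g)))   # unmatched cells too

  claims <- merge(nz, gvol, by = "g")
  claims <- claims[claims$n >= minFraction * claims$vol, ]
  overTab <- claims[, list(k = .N), by = "g"]
  overIds <- overTab$g[overTab$k > 1L]

  list(undersegmented = length(underIds) / nCells,
       oversegmented = length(overIds) / nCells,
       nCells = nCells)
}
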