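# The slice-wise label model: resolving (base labels + label lists) into
# final cell IDs, and maintenance of the LinkedStack store.

# lookup table base label -> final ID for one SliceSeg; deleted IDs map
# to 0. Element k+1 of the result corresponds to base label k.
.sliceLut <- function(ss) {
  m <- max(ss@baseLabels, 0L)
  lut <- integer(m + 1L)
  for (k in seq_along(ss@ids)) {
    mem <- ss@members[[k]]
    mem <- mem[mem <= m]
    id <- ss@ids[k]
    lut[mem + 1L] <- if (id %in% ss@deleted) 0L else id
  }
  lut
}

.resolveSliceSeg <- function(ss) {
  lut <- .sliceLut(ss)
  out <- lut[ss@baseLabels + 1L]
  dim(out) <- dim(ss@baseLabels)
  out
}

#' Resolve one slice to final cell IDs
#'
#' Computes the displayable segmentation of slice `z`: each pixel takes
#' the final ID of the group containing its base label, or 0 if it is
#' background or its ID has been deleted. This is the pure resolution
#' function of the slice-wise store -- edits never touch the base label
#' grid, they only update the label lists that this function applies.
#'
#' @param x A [LinkedStack].
#' @param z Slice index, `1 <= z <= nSlices(x)`.
#' @return Integer matrix of final cell IDs.
#' @export
resolveSlice <- function(x, z) {
  stopifnot(is(x, "LinkedStack"))
  z <- as.integer(z)
  if (length(z) != 1 || is.na(z) || z < 1L || z > length(x@slices))
    stop("slice index out of range")
  .resolveSliceSeg(x@slices[[z]])
}

#' @describeIn resolveVolume Stack all resolved slices into a `(y, x, z)`
#'   integer array; errors on an empty stack.
#' @export
setMethod("resolveVolume", "LinkedStack", function(x) {
  nz <- length(x@slices)
  if (nz == 0L) stop("empty stack: no slices to resolve")
  d <- dim(x@slices[[1L]]@baseLabels)
  out <- array(0L, c(d, nz))
  for (z in seq_len(nz)) out[, , z] <- .resolveSliceSeg(x@slices[[z]])
  out
})

#' Render the display window around a slice
#'
#' Resolves only the slices within the display window
#' `[zCenter - w, zCenter + w]` (w = `displayWindow`, default 100),
#' clipped to the stack bounds -- the economy that keeps interactive
#' display cheap when a stack has thousands of slices.
#'
#' @param x A [LinkedStack].
#' @param zCenter Centre slice index.
#' @return Integer array `(y, x, z)` covering the clipped window, with
#'   attribute `zRange` giving the slice indices rendered.
#' @export
renderWindow <- function(x, zCenter) {
  stopifnot(is(x, "LinkedStack"))
  zCenter <- as.integer(zCenter)
  nz <- length(x@slices)
  if (length(zCenter) != 1 || is.na(zCenter) || zCenter < 1L || zCenter > nz)
    stop("slice index out of range")
  w <- x@displayWindow
  zr <- max(1L, zCenter - w):min(nz, zCenter + w)
  d <- dim(x@slices[[1L]]@baseLabels)
  out <- array(0L, c(d, length(zr)))
  for (i in seq_along(zr)) out[, , i] <- .resolveSliceSeg(x@slices[[zr[i]]])
  attr(out, "zRange") <- range(zr)
  out
}

#' Append a slice without linking
#'
#' Adds a freshly segmented slice to the stack, giving every base label
#' its own fresh final cell ID (ascending with base label). Used for the
#' first slice of a stack; subsequent slices normally go through
#' [linkSlice()] instead.
#'
#' @param x A [LinkedStack].
#' @param base Integer label matrix from [segmentSlice()].
#' @return The extended stack.
#' @export
appendSlice <- function(x, base) {
  stopifnot(is(x, "LinkedStack"))
  storage.mode(base) <- "integer"
  if (length(x@slices) &&
      !identical(dim(base), dim(x@slices[[1L]]@baseLabels)))
    stop("slice shape does not match the stack")
  labs <- sort(unique(base[base > 0L]))
  ids <- if (length(labs)) x@nextId + seq_along(labs) - 1L else integer()
  ss <- SliceSeg(base, ids = ids, members = as.list(labs))
  nid <- if (length(ids)) max(ids) + 1L else x@nextId
  .pushDelta(x, op = "append",
             before = list(), after = list(),
             appendedSlice = ss,
             nextIdBefore = x@nextId, nextIdAfter = nid,
             wsBefore = x@workingSlice,
             wsAfter = length(x@slices) + 1L)
}

# ---------------------------------------------------------------------------
# Delta plumbing for LinkedStack. Deltas are symmetric snapshots of the
# affected slices (before/after), the ID counter and the working slice;
# slice snapshots share the base grid by reference so they stay small.

.pushDelta <- function(x, op, before, after, nextIdBefore, nextIdAfter,
                       wsBefore, wsAfter, appendedSlice = NULL) {
  # apply the "after" side
  for (znm in names(after)) x@slices[[as.integer(znm)]] <- after[[znm]]
  if (!is.null(appendedSlice))
    x@slices[[length(x@slices) + 1L]] <- appendedSlice
  x@nextId <- as.integer(nextIdAfter)
  x@workingSlice <- as.integer(wsAfter)
  delta <- list(op = op, before = before, after = after,
                appendedSlice = appendedSlice,
                nextIdBefore = as.integer(nextIdBefore),
                nextIdAfter = as.integer(nextIdAfter),
                wsBefore = as.integer(wsBefore),
                wsAfter = as.integer(wsAfter))
  x@history <- c(x@history, list(delta))
  if (length(x@history) > x@historyCapacity)
    x@history <- x@history[-1L]           # oldest step becomes unrecoverable
  x@redoStack <- list()                   # any new edit clears redo
  validObject(x)
  x
}

#' @describeIn undo Revert the last edit of a slice-wise store.
#' @export
setMethod("undo", "LinkedStack", function(x) {
  if (length(x@history) == 0L) {
    warning("nothing to undo")
    return(x)
  }
  d <- x@history[[length(x@history)]]
  x@history <- x@history[-length(x@history)]
  if (!is.null(d$appendedSlice)) x@slices <- x@slices[-length(x@slices)]
  for (znm in names(d$before)) x@slices[[as.integer(znm)]] <- d$before[[znm]]
  x@nextId <- d$nextIdBefore
  x@workingSlice <- d$wsBefore
  x@redoStack <- c(x@redoStack, list(d))
  x
})

#' @describeIn undo Re-apply the most recently undone edit.
#' @export
setMethod("redo", "LinkedStack", function(x) {
  if (length(x@redoStack) == 0L) {
    warning("nothing to redo")
    return(x)
  }
  d <- x@redoStack[[length(x@redoStack)]]
  x@redoStack <- x@redoStack[-length(x@redoStack)]
  for (znm in names(d$after)) x@slices[[as.integer(znm)]] <- d$after[[znm]]
  if (!is.null(d$appendedSlice))
    x@slices[[length(x@slices) + 1L]] <- d$appendedSlice
  x@nextId <- d$nextIdAfter
  x@workingSlice <- d$wsAfter
  x@history <- c(x@history, list(d))
  if (length(x@history) > x@historyCapacity) x@history <- x@history[-1L]
  x
})

# ---------------------------------------------------------------------------
# Accessors

#' @describeIn nSlices Slice count of a slice-wise store.
#' @export
setMethod("nSlices", "LinkedStack", function(x) length(x@slices))

#' @describeIn cellIds IDs present in at least one slice's label list and
#'   not deleted there.
#' @export
setMethod("cellIds", "LinkedStack", function(x) {
  ids <- integer()
  for (ss in x@slices) ids <- c(ids, setdiff(ss@ids, ss@deleted))
  sort(unique(ids))
})

#' Working slice of a slice-wise store
#'
#' The slice currently being segmented/corrected. Division in the
#' slice-wise store is only permitted here; merge and delete may target
#' any completed slice.
#'
#' @param x A [LinkedStack].
#' @return Integer slice index (0 for an empty stack).
#' @export
workingSlice <- function(x) {
  stopifnot(is(x, "LinkedStack"))
  x@workingSlice
}

setMethod("show", "LinkedStack", function(object) {
  cat(sprintf(
    "LinkedStack: %d slice(s), %d active cell(s), nextId=%d\n",
    length(object@slices), length(cellIds(object)), object@nextId))
  cat(sprintf("  history: %d/%d step(s), redo: %d; working slice: %d\n",
              length(object@history), object@historyCapacity,
              length(object@redoStack), object@workingSlice))
})

setMethod("show", "SliceSeg", function(object) {
  cat(sprintf("SliceSeg %dx%d: %d group(s), %d deleted ID(s)\n",
              nrow(object@baseLabels), ncol(object@baseLabels),
              length(object@ids), length(object@deleted)))
})

setMethod("show", "Seg2DParams", function(object) {
  cat(sprintf(
    "Seg2DParams: sigma=%g px, h=%g, connectivity=%d, maskThreshold=%g\n",
    object@gaussianSigma, object@hMaxima, object@connectivity,
    object@maskThreshold))
})

setMethod("show", "LinkParams", function(object) {
  cat(sprintf("LinkParams: overlapThreshold=%g\n", object@overlapThreshold))
})
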