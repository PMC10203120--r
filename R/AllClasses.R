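#' @import methods
#' @importFrom stats runif
NULL

# ---------------------------------------------------------------------------
# Parameter classes

#' Parameters for slice-wise watershed segmentation
#'
#' Bundles the tunable parameters of [segmentSlice()] and
#' [watershed3D()]: the Gaussian blur applied to the distance map, the
#' h-maxima depth used to suppress spurious seeds, the pixel connectivity,
#' and the ROI-mask retention threshold used by [applyMask()].
#'
#' @param gaussianSigma Standard deviation (pixels) of the Gaussian blur
#'   applied to the distance map before seed detection. Default 2.
#' @param hMaxima Depth `h` (in distance-map units) of the h-maxima
#'   transform: local maxima shallower than `h` relative to their
#'   surroundings are suppressed, so one seed survives per convex cell.
#'   Default 2.
#' @param connectivity Pixel neighbourhood for components, seeds and the
#'   watershed flood: 4 or 8 in 2D. Default 4, so that one-pixel-wide
#'   drawn boundaries separate regions during division.
#' @param maskThreshold Minimum in-ROI proportion for a cell to be kept by
#'   [applyMask()]; cells with a proportion strictly below it are removed.
#'   Default 0.8.
#' @return A `Seg2DParams` object.
#' @examples
#' Seg2DParams(gaussianSigma = 1.5, hMaxima = 3)
#' @export
Seg2DParams <- function(gaussianSigma = 2, hMaxima = 2, connectivity = 4L,
                        maskThreshold = 0.8) {
  new("Seg2DParams", gaussianSigma = as.numeric(gaussianSigma),
      hMaxima = as.numeric(hMaxima), connectivity = as.integer(connectivity),
      maskThreshold = as.numeric(maskThreshold))
}

#' @rdname Seg2DParams-class
#' @name Seg2DParams-class
#' @aliases Seg2DParams
#' @exportClass Seg2DParams
setClass("Seg2DParams", representation(
  gaussianSigma = "numeric", hMaxima = "numeric",
  connectivity = "integer", maskThreshold = "numeric"
), validity = function(object) {
  if (length(object@gaussianSigma) != 1 || object@gaussianSigma < 0)
    return("gaussianSigma must be a single value >= 0")
  if (length(object@hMaxima) != 1 || object@hMaxima < 0)
    return("hMaxima must be a single value >= 0")
  if (!(object@connectivity %in% c(4L, 8L)))
    return("connectivity must be 4 or 8")
  if (length(object@maskThreshold) != 1 || object@maskThreshold < 0 ||
      object@maskThreshold > 1)
    return("maskThreshold must be in [0, 1]")
  TRUE
})

#' Parameters for cross-slice overlap linking
#'
#' @param overlapThreshold Two regions in adjacent slices are linked when
#'   their overlap coefficient strictly exceeds this value. Default 0.5.
#' @return A `LinkParams` object.
#' @examples
#' LinkParams(overlapThreshold = 0.6)
#' @export
LinkParams <- function(overlapThreshold = 0.5) {
  new("LinkParams", overlapThreshold = as.numeric(overlapThreshold))
}

#' @rdname LinkParams-class
#' @name LinkParams-class
#' @aliases LinkParams
#' @exportClass LinkParams
setClass("LinkParams", representation(overlapThreshold = "numeric"),
  validity = function(object) {
    if (length(object@overlapThreshold) != 1 ||
        object@overlapThreshold < 0 || object@overlapThreshold > 1)
      return("overlapThreshold must be in [0, 1]")
    TRUE
  })

# ---------------------------------------------------------------------------
# SliceSeg: one slice's immutable base labels + mutable label list

#' One slice of the linked segmentation store
#'
#' A `SliceSeg` couples the immutable 2D label image produced by the
#' watershed (`baseLabels`) with a mutable label list: disjoint groups of
#' base labels, each carrying one final cell ID, plus a set of final IDs
#' tombstoned as deleted. Link, merge and delete edits touch only the
#' label list, never the pixel grid, which is what makes those edits (and
#' their caching to disk) cheap. The displayable segmentation of the slice
#' is a pure function of the three parts; see [resolveSlice()].
#'
#' @param baseLabels Integer matrix of non-negative base labels
#'   (0 = background).
#' @param ids Integer vector of final cell IDs, one per group.
#' @param members List of integer vectors, parallel to `ids`: the base
#'   labels belonging to each group. Every nonzero base label present in
#'   `baseLabels` must appear in exactly one group.
#' @param deleted Integer vector of final cell IDs marked removed.
#' @return A `SliceSeg` object.
#' @examples
#' base <- matrix(c(0L, 1L, 1L, 2L), 2, 2)
#' SliceSeg(base, ids = c(5L, 9L), members = list(1L, 2L))
#' @export
SliceSeg <- function(baseLabels, ids = integer(), members = list(),
                     deleted = integer()) {
  storage.mode(baseLabels) <- "integer"
  new("SliceSeg", baseLabels = baseLabels, ids = as.integer(ids),
      members = lapply(members, as.integer), deleted = as.integer(deleted))
}

#' @rdname SliceSeg-class
#' @name SliceSeg-class
#' @aliases SliceSeg
#' @exportClass SliceSeg
setClass("SliceSeg", representation(
  baseLabels = "matrix", ids = "integer", members = "list",
  deleted = "integer"
), validity = function(object) {
  b <- object@baseLabels
  if (!is.integer(b)) return("baseLabels must be an integer matrix")
  if (any(b < 0L, na.rm = TRUE) || anyNA(b))
    return("baseLabels must be non-negative and non-missing")
  if (length(object@ids) != length(object@members))
    return("ids and members must be parallel")
  mem <- unlist(object@members, use.names = FALSE)
  if (any(mem <= 0L)) return("groups must not contain base label 0")
  if (anyDuplicated(mem)) return("a base label appears in more than one group")
  if (anyDuplicated(object@ids)) return("final cell IDs must be unique")
  if (length(object@ids) && any(object@ids <= 0L))
    return("final cell IDs must be positive")
  present <- sort(unique(b[b > 0L]))
  if (!all(present %in% mem))
    return("every nonzero base label must appear in exactly one group")
  TRUE
})

# ---------------------------------------------------------------------------
# LinkedStack: the Module-1 store

#' @rdname LinkedStack
#' @name LinkedStack-class
#' @aliases LinkedStack
#' @exportClass LinkedStack
setClass("LinkedStack", representation(
  slices = "list", nextId = "integer", history = "list",
  redoStack = "list", historyCapacity = "integer",
  displayWindow = "integer", workingSlice = "integer"
), validity = function(object) {
  if (length(object@nextId) != 1 || object@nextId < 1L)
    return("nextId must be a single positive integer")
  if (object@historyCapacity < 0L) return("historyCapacity must be >= 0")
  if (length(object@history) > object@historyCapacity)
    return("history exceeds its capacity")
  if (object@displayWindow < 0L) return("displayWindow must be >= 0")
  TRUE
})

#' Create the slice-wise linked segmentation store
#'
#' A `LinkedStack` holds a z-ordered sequence of [SliceSeg] objects, the
#' smallest unused final cell ID, and bounded undo/redo history. It is the
#' store behind the slice-by-slice segment-and-link workflow: slices are
#' added with [appendSlice()] (first slice) and [linkSlice()] (subsequent
#' slices), edited with [mergeCells()], [deleteCells()], [divideCell()]
#' and [divideRelink()], and resolved to label images with
#' [resolveSlice()], [resolveVolume()] or [renderWindow()].
#'
#' @param base Optional integer label matrix for the first slice; each of
#'   its labels receives a fresh final cell ID.
#' @param historyCapacity Maximum number of undo steps retained
#'   (default 10).
#' @param displayWindow Half-width, in slices, of the window rendered by
#'   [renderWindow()] (default 100).
#' @return A `LinkedStack`.
#' @examples
#' st <- LinkedStack(matrix(c(1L, 1L, 0L, 2L), 2, 2))
#' nSlices(st)
#' @export
LinkedStack <- function(base = NULL, historyCapacity = 10L,
                        displayWindow = 100L) {
  st <- new("LinkedStack", slices = list(), nextId = 1L, history = list(),
            redoStack = list(), historyCapacity = as.integer(historyCapacity),
            displayWindow = as.integer(displayWindow), workingSlice = 0L)
  if (!is.null(base)) st <- appendSlice(st, base)
  st
}

# ---------------------------------------------------------------------------
# LabelVolume: the Module-2 store

#' @rdname buildVolume
#' @name LabelVolume-class
#' @aliases LabelVolume
#' @exportClass LabelVolume
setClass("LabelVolume", representation(
  labels = "array", ids = "integer", bbox = "matrix", volumes = "numeric",
  nextId = "integer", history = "list", redoStack = "list",
  historyCapacity = "integer"
), validity = function(object) {
  if (length(dim(object@labels)) != 3L)
    return("labels must be a 3D array")
  if (length(object@ids) != nrow(object@bbox) ||
      length(object@ids) != length(object@volumes))
    return("ids, bbox and volumes must be parallel")
  if (length(object@nextId) != 1 || object@nextId < 1L)
    return("nextId must be a single positive integer")
  if (length(object@history) > object@historyCapacity)
    return("history exceeds its capacity")
  TRUE
})
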