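# The volumetric correction store: a dense 3D label grid plus cached
# per-cell bounding boxes and voxel counts, with sub-region diff deltas
# for undo/redo. The bbox cache is what makes localization and editing
# depend on cell size rather than image size.

.bboxCols <- c("y0", "y1", "x0", "x1", "z0", "z1")

#' Build the volumetric label store
#'
#' Wraps a dense 3D integer label grid into a [LabelVolume], computing in
#' one pass the tight bounding box and voxel count of every cell. All
#' volumetric corrections keep these caches coherent incrementally, and
#' record sub-region voxel diffs for bounded undo/redo.
#'
#' @param labels 3D array `(y, x, z)` of non-negative integer labels
#'   (0 = background), e.g. `resolveVolume()` output or an imported
#'   segmentation.
#' @param historyCapacity Maximum undo depth (default 5; volumetric
#'   deltas are larger than label-list snapshots, so the default is
#'   smaller than the slice-wise store's).
#' @return A `LabelVolume`.
#' @examples
#' v <- array(0L, c(8, 8, 4)); v[2:4, 2:4, 1:2] <- 1L
#' vol <- buildVolume(v)
#' cellVolumes(vol)
#' @export
buildVolume <- function(labels, historyCapacity = 5L) {
  if (length(dim(labels)) == 2L) dim(labels) <- c(dim(labels), 1L)
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  if (anyNA(labels) || any(labels < 0))
    stop("labels must be non-negative integers")
  storage.mode(labels) <- "integer"
  st <- .labelStats(labels)
  bbox <- st$bbox
  colnames(bbox) <- .bboxCols
  new("LabelVolume", labels = labels, ids = st$ids, bbox = bbox,
      volumes = st$volumes,
      nextId = if (length(st$ids)) max(st$ids) + 1L else 1L,
      history = list(), redoStack = list(),
      historyCapacity = as.integer(historyCapacity))
}

# ---------------------------------------------------------------------------
# Accessors

#' @describeIn buildVolume Dense grid of a volumetric store.
#' @param x A `LabelVolume`.
#' @export
setMethod("resolveVolume", "LabelVolume", function(x) x@labels)

#' @describeIn nSlices z extent of a volumetric store.
#' @export
setMethod("nSlices", "LabelVolume", function(x) dim(x@labels)[3L])

#' @describeIn cellIds IDs with at least one voxel.
#' @export
setMethod("cellIds", "LabelVolume", function(x) sort(x@ids))

#' Cached per-cell voxel counts and bounding boxes
#'
#' @param x A [LabelVolume].
#' @return `cellVolumes`: named numeric vector of voxel counts.
#'   `cellBoxes`: integer matrix (one row per cell, rownames = IDs) with
#'   1-based inclusive bounds `y0,y1,x0,x1,z0,z1`.
#' @export
cellVolumes <- function(x) {
  stopifnot(is(x, "LabelVolume"))
  stats::setNames(x@volumes, x@ids)
}

#' @rdname cellVolumes
#' @export
cellBoxes <- function(x) {
  stopifnot(is(x, "LabelVolume"))
  b <- x@bbox
  rownames(b) <- x@ids
  b
}

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LabelVolume %dx%dx%d (y,x,z): %d cell(s), nextId=%d\n",
              d[1], d[2], d[3], length(object@ids), object@nextId))
  cat(sprintf("  history: %d/%d step(s), redo: %d\n",
              length(object@history), object@historyCapacity,
              length(object@redoStack)))
})

# ---------------------------------------------------------------------------
# internal helpers

.volRow <- function(x, id) {
  at <- match(id, x@ids)
  if (is.na(at)) stop(sprintf("unknown cell ID: %d", id))
  at
}

# linear indices of a cell's voxels, searched only inside its cached
# bounding box (the localization shortcut).
.cellIndices <- function(x, id) {
  at <- .volRow(x, id)
  b <- x@bbox[at, ]
  d <- dim(x@labels)
  sub <- x@labels[b[1]:b[2], b[3]:b[4], b[5]:b[6], drop = FALSE]
  w <- which(sub == id)
  .subToFull(w, b, dim(sub), d)
}

.subToFull <- function(w, b, sd, d) {
  if (!length(w)) return(integer())
  w0 <- w - 1L
  y <- w0 %% sd[1]
  x <- (w0 %/% sd[1]) %% sd[2]
  z <- w0 %/% (sd[1] * sd[2])
  as.integer((b[1] - 1L + y) + (b[3] - 1L + x) * d[1] +
             (b[5] - 1L + z) * d[1] * d[2] + 1L)
}

.unionBox <- function(boxes) {
  boxes <- matrix(boxes, ncol = 6L)
  c(min(boxes[, 1]), max(boxes[, 2]), min(boxes[, 3]), max(boxes[, 4]),
    min(boxes[, 5]), max(boxes[, 6]))
}

# record + apply one volumetric delta: voxel diff (idx/old/new) plus full
# before/after snapshots of the (small) stats tables and the ID counter.
.pushVolDelta <- function(x, op, idx, new, statsAfter, nextIdAfter) {
  old <- x@labels[idx]
  delta <- list(op = op, idx = idx, old = old, new = new,
                statsBefore = list(ids = x@ids, bbox = x@bbox,
                                   volumes = x@volumes),
                statsAfter = statsAfter,
                nextIdBefore = x@nextId,
                nextIdAfter = as.integer(nextIdAfter))
  x@labels[idx] <- new
  x@ids <- statsAfter$ids
  x@bbox <- statsAfter$bbox
  x@volumes <- statsAfter$volumes
  x@nextId <- as.integer(nextIdAfter)
  x@history <- c(x@history, list(delta))
  if (length(x@history) > x@historyCapacity) x@history <- x@history[-1L]
  x@redoStack <- list()
  x
}

# recompute stats rows for `ids` by scanning only `region` (a bbox known
# to contain all their voxels), leaving other rows untouched.
.recomputeStats <- function(x, ids, region) {
  keep <- !(x@ids %in% ids)
  outIds <- x@ids[keep]
  outBox <- x@bbox[keep, , drop = FALSE]
  outVol <- x@volumes[keep]
  sub <- x@labels[region[1]:region[2], region[3]:region[4],
                  region[5]:region[6], drop = FALSE]
  st <- .labelStats(sub)
  sel <- st$ids %in% ids
  if (any(sel)) {
    b <- st$bbox[sel, , drop = FALSE]
    b[, 1:2] <- b[, 1:2] + region[1] - 1L
    b[, 3:4] <- b[, 3:4] + region[3] - 1L
    b[, 5:6] <- b[, 5:6] + region[5] - 1L
    outIds <- c(outIds, st$ids[sel])
    outBox <- rbind(outBox, b)
    outVol <- c(outVol, st$volumes[sel])
  }
  ord <- order(outIds)
  colnames(outBox) <- .bboxCols
  list(ids = outIds[ord], bbox = outBox[ord, , drop = FALSE],
       volumes = outVol[ord])
}

# ---------------------------------------------------------------------------
# Inspection operations

#' Locate a cell and jump to its central slice
#'
#' Returns the central slice and the tight bounding box of a cell,
#' looked up from the cached bounding boxes rather than by scanning the
#' full grid -- the search cost depends on cell size, not image size.
#'
#' @param x A [LabelVolume].
#' @param id Cell ID.
#' @return List with `middleZ` (floor of the bbox z midpoint) and `bbox`
#'   (named integer vector `y0,y1,x0,x1,z0,z1`).
#' @export
locateCell <- function(x, id) {
  stopifnot(is(x, "LabelVolume"))
  at <- .volRow(x, as.integer(id))
  b <- x@bbox[at, ]
  list(middleZ = as.integer(floor((b["z0"] + b["z1"]) / 2)), bbox = b)
}

#' Relabel cells by descending volume
#'
#' Bijectively renames cell IDs so that ID 1 is the largest cell, ties
#' broken by ascending old ID; the voxel partition is unchanged and the
#' caches are remapped. Useful for inspecting cells from largest to
#' smallest.
#'
#' @param x A [LabelVolume] with at least one cell.
#' @return The relabelled `LabelVolume`.
#' @export
sortByVolume <- function(x) {
  stopifnot(is(x, "LabelVolume"))
  if (!length(x@ids)) stop("no cells to sort")
  ord <- order(-x@volumes, x@ids)
  lut <- integer(max(x@ids))
  lut[x@ids[ord]] <- seq_along(ord)
  lab <- x@labels
  nz <- which(lab > 0L)
  newv <- lut[lab[nz]]
  changed <- newv != lab[nz]
  idx <- nz[changed]
  statsAfter <- list(ids = seq_along(ord),
                     bbox = x@bbox[ord, , drop = FALSE],
                     volumes = x@volumes[ord])
  colnames(statsAfter$bbox) <- .bboxCols
  .pushVolDelta(x, "sort", idx, newv[changed], statsAfter,
                length(ord) + 1L)
}

#' Remove cells smaller than a voxel threshold
#'
#' Deletes every cell whose voxel count is strictly less than
#' `minVoxels`; all other cells are untouched.
#'
#' @param x A [LabelVolume].
#' @param minVoxels Threshold (>= 0).
#' @return List with `state` (the edited `LabelVolume`) and `removed`
#'   (IDs removed, possibly empty).
#' @export
removeSmall <- function(x, minVoxels) {
  stopifnot(is(x, "LabelVolume"), minVoxels >= 0)
  small <- x@ids[x@volumes < minVoxels]
  idx <- integer()
  for (id in small) idx <- c(idx, .cellIndices(x, id))
  keep <- !(x@ids %in% small)
  statsAfter <- list(ids = x@ids[keep], bbox = x@bbox[keep, , drop = FALSE],
                     volumes = x@volumes[keep])
  st <- .pushVolDelta(x, "remove_small", idx, rep(0L, length(idx)),
                      statsAfter, x@nextId)
  list(state = st, removed = small)
}

# ---------------------------------------------------------------------------
# Correction operations

#' @describeIn mergeCells Merge on the volumetric store: voxels of the
#'   other IDs are relabelled to the smallest ID inside their bounding
#'   boxes; the target's cached bbox becomes the union.
#' @export
setMethod("mergeCells", "LabelVolume", function(x, ids) {
  ids <- unique(as.integer(ids))
  for (id in ids) .volRow(x, id)
  if (length(ids) < 2L) stop("merge needs at least two distinct cell IDs")
  target <- min(ids)
  old <- setdiff(ids, target)
  idx <- integer()
  for (id in old) idx <- c(idx, .cellIndices(x, id))
  rows <- match(c(target, old), x@ids)
  keep <- !(x@ids %in% old)
  bbox <- x@bbox
  bbox[rows[1L], ] <- .unionBox(x@bbox[rows, , drop = FALSE])
  vols <- x@volumes
  vols[rows[1L]] <- sum(x@volumes[rows])
  statsAfter <- list(ids = x@ids[keep], bbox = bbox[keep, , drop = FALSE],
                     volumes = vols[keep])
  .pushVolDelta(x, "merge", idx, rep(target, length(idx)), statsAfter,
                x@nextId)
})

#' @describeIn deleteCells Delete on the volumetric store: voxels are
#'   zeroed inside the cells' bounding boxes.
#' @export
setMethod("deleteCells", "LabelVolume", function(x, ids) {
  ids <- unique(as.integer(ids))
  for (id in ids) .volRow(x, id)
  idx <- integer()
  for (id in ids) idx <- c(idx, .cellIndices(x, id))
  keep <- !(x@ids %in% ids)
  statsAfter <- list(ids = x@ids[keep], bbox = x@bbox[keep, , drop = FALSE],
                     volumes = x@volumes[keep])
  .pushVolDelta(x, "delete", idx, rep(0L, length(idx)), statsAfter,
                x@nextId)
})

#' Divide a cell into its 3D connected components
#'
#' Splits a cell whose voxels form several spatially disconnected parts
#' -- typically a cell incorrectly linked along the z axis after the
#' connecting region was erased (or never existed). The components
#' (26-connectivity by default) become separate cells: the largest keeps
#' `id`, the others receive fresh IDs in deterministic order.
#'
#' @param x A [LabelVolume].
#' @param id Cell ID.
#' @param connectivity 6, 18 or 26 (default 26, the most permissive, so
#'   anisotropic sampling does not cause spurious splits).
#' @return List with `state` (the edited `LabelVolume`) and `newIds`.
#' @export
divide3D <- function(x, id, connectivity = 26L) {
  stopifnot(is(x, "LabelVolume"))
  id <- as.integer(id)
  at <- .volRow(x, id)
  b <- x@bbox[at, ]
  sub <- x@labels[b[1]:b[2], b[3]:b[4], b[5]:b[6], drop = FALSE]
  comps <- labelComponents(sub == id, connectivity)
  np <- max(comps)
  areas <- tabulate(comps, nbins = np)
  largest <- which.max(areas)
  newIds <- integer()
  nid <- x@nextId
  idx <- integer()
  newv <- integer()
  for (j in seq_len(np)) {
    if (j == largest) next
    w <- which(comps == j)
    idx <- c(idx, .subToFull(w, b, dim(sub), dim(x@labels)))
    newIds <- c(newIds, nid)
    newv <- c(newv, rep(nid, length(w)))
    nid <- nid + 1L
  }
  x2 <- x
  x2@labels[idx] <- newv
  statsAfter <- .recomputeStats(x2, c(id, newIds), b)
  st <- .pushVolDelta(x, "divide3d", idx, newv, statsAfter, nid)
  list(state = st, newIds = newIds)
}

#' Insert a manually painted cell
#'
#' Assigns the next free ID to a painted region that the upstream
#' predictions missed. Painting over an existing cell is an error --
#' insertion targets undetected regions only.
#'
#' @param x A [LabelVolume].
#' @param painted Binary 3D array of the new cell's voxels; all of them
#'   must currently be background.
#' @return List with `state` (the edited `LabelVolume`) and `newId`.
#' @export
insertCell <- function(x, painted) {
  stopifnot(is(x, "LabelVolume"))
  if (!identical(dim(painted), dim(x@labels)))
    stop("painted shape does not match the volume")
  idx <- which(painted != 0)
  if (!length(idx)) stop("painted region is empty")
  if (any(x@labels[idx] != 0L))
    stop("painted region overlaps an existing cell")
  newId <- x@nextId
  pst <- .labelStats(array(as.integer(painted != 0), dim(x@labels)))
  b <- pst$bbox[1L, ]
  ids <- c(x@ids, newId)
  bbox <- rbind(x@bbox, b)
  vols <- c(x@volumes, length(idx))
  ord <- order(ids)
  colnames(bbox) <- .bboxCols
  statsAfter <- list(ids = ids[ord], bbox = bbox[ord, , drop = FALSE],
                     volumes = vols[ord])
  st <- .pushVolDelta(x, "insert", idx, rep(newId, length(idx)),
                      statsAfter, newId + 1L)
  list(state = st, newId = newId)
}

#' @describeIn divideCell Division on the volumetric store; any slice may
#'   be edited. Cached stats of the affected cells are updated from the
#'   affected sub-region only.
#' @export
setMethod("divideCell", "LabelVolume", function(x, z, id, mask,
                                                connectivity = 4L) {
  z <- as.integer(z)
  if (z < 1L || z > dim(x@labels)[3L]) stop("slice index out of range")
  id <- as.integer(id)
  at <- .volRow(x, id)
  slice <- x@labels[, , z]
  comps <- .dividePieces(slice, id, mask, connectivity)
  np <- max(comps)
  areas <- tabulate(comps, nbins = np)
  largest <- which.max(areas)
  pieceIds <- integer(np)
  newIds <- integer()
  nid <- x@nextId
  for (j in seq_len(np)) {
    if (j == largest) {
      pieceIds[j] <- id
    } else {
      pieceIds[j] <- nid
      newIds <- c(newIds, nid)
      nid <- nid + 1L
    }
  }
  res <- .applyPieceRelabel(x, z, id, comps, pieceIds)
  region <- x@bbox[at, ]
  x2 <- x
  x2@labels[res$idx] <- res$new
  statsAfter <- .recomputeStats(x2, c(id, newIds), region)
  st <- .pushVolDelta(x, "divide", res$idx, res$new, statsAfter, nid)
  list(state = st, newIds = newIds)
})

# voxel diff for re-assigning the pieces of cell `id` at slice z:
# erased pixels (cell minus mask) go to background, piece j to pieceIds[j].
.applyPieceRelabel <- function(x, z, id, comps, pieceIds) {
  d <- dim(x@labels)
  off <- (z - 1L) * d[1L] * d[2L]
  slice <- x@labels[, , z]
  cellpix <- which(slice == id)
  pc <- comps[cellpix]
  new <- ifelse(pc > 0L, pieceIds[pmax(pc, 1L)], 0L)
  changed <- new != id
  list(idx = off + cellpix[changed], new = as.integer(new[changed]))
}

#' @describeIn divideRelink Division plus relink on the volumetric store;
#'   any slice `z >= 2` may be edited, and pieces adopt IDs from the
#'   dense grid at `z - 1`.
#' @export
setMethod("divideRelink", "LabelVolume", function(x, z, id, mask,
                                                  params = LinkParams(),
                                                  connectivity = 4L) {
  z <- as.integer(z)
  if (z < 2L) stop("relink requires a previous slice (z >= 2)")
  if (z > dim(x@labels)[3L]) stop("slice index out of range")
  stopifnot(is(params, "LinkParams"))
  id <- as.integer(id)
  at <- .volRow(x, id)
  slice <- x@labels[, , z]
  comps <- .dividePieces(slice, id, mask, connectivity)
  np <- max(comps)
  areas <- tabulate(comps, nbins = np)
  largest <- which.max(areas)
  adopt <- .relinkAssign(comps, x@labels[, , z - 1L],
                         params@overlapThreshold)
  pieceIds <- integer(np)
  nid <- x@nextId
  for (j in seq_len(np)) {
    if (!is.na(adopt[j])) {
      pieceIds[j] <- adopt[j]
    } else if (j == largest && !(id %in% adopt)) {
      pieceIds[j] <- id
    } else {
      pieceIds[j] <- nid
      nid <- nid + 1L
    }
  }
  res <- .applyPieceRelabel(x, z, id, comps, pieceIds)
  affected <- unique(c(id, pieceIds))
  rows <- match(intersect(affected, x@ids), x@ids)
  region <- .unionBox(x@bbox[rows, , drop = FALSE])
  x2 <- x
  x2@labels[res$idx] <- res$new
  statsAfter <- .recomputeStats(x2, affected, region)
  .pushVolDelta(x, "divide_relink", res$idx, res$new, statsAfter, nid)
})

# ---------------------------------------------------------------------------
# Undo / redo

#' @describeIn undo Revert the last volumetric edit by replaying its
#'   sub-region voxel diff backwards.
#' @export
setMethod("undo", "LabelVolume", function(x) {
  if (length(x@history) == 0L) {
    warning("nothing to undo")
    return(x)
  }
  d <- x@history[[length(x@history)]]
  x@history <- x@history[-length(x@history)]
  x@labels[d$idx] <- d$old
  x@ids <- d$statsBefore$ids
  x@bbox <- d$statsBefore$bbox
  x@volumes <- d$statsBefore$volumes
  x@nextId <- d$nextIdBefore
  x@redoStack <- c(x@redoStack, list(d))
  x
})

#' @describeIn undo Re-apply the most recently undone volumetric edit.
#' @export
setMethod("redo", "LabelVolume", function(x) {
  if (length(x@redoStack) == 0L) {
    warning("nothing to redo")
    return(x)
  }
  d <- x@redoStack[[length(x@redoStack)]]
  x@redoStack <- x@redoStack[-length(x@redoStack)]
  x@labels[d$idx] <- d$new
  x@ids <- d$statsAfter$ids
  x@bbox <- d$statsAfter$bbox
  x@volumes <- d$statsAfter$volumes
  x@nextId <- d$nextIdAfter
  x@history <- c(x@history, list(d))
  if (length(x@history) > x@historyCapacity) x@history <- x@history[-1L]
  x
})
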