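# Slice-wise correction commands. Merge and delete touch only the label
# lists (any completed slice); division rewrites the base grid of the
# current working slice only. Every command records one undoable delta.

.checkIdsExist <- function(x, ids) {
  ids <- as.integer(ids)
  known <- cellIds(x)
  missing <- setdiff(ids, known)
  if (length(missing))
    stop(sprintf("unknown cell ID(s): %s", paste(missing, collapse = ", ")))
  ids
}

#' @describeIn mergeCells Merge on the slice-wise store: the groups
#'   carrying the listed IDs are re-keyed to the smallest ID in every
#'   slice where they occur; base label grids are untouched.
#' @export
setMethod("mergeCells", "LinkedStack", function(x, ids) {
  ids <- unique(.checkIdsExist(x, ids))
  if (length(ids) < 2L) stop("merge needs at least two distinct cell IDs")
  target <- min(ids)
  old <- setdiff(ids, target)
  before <- list()
  after <- list()
  for (z in seq_along(x@slices)) {
    ss <- x@slices[[z]]
    if (!any(old %in% ss@ids)) next
    before[[as.character(z)]] <- ss
    after[[as.character(z)]] <- .remapSliceIds(ss, old,
                                               rep(target, length(old)))
  }
  .pushDelta(x, op = "merge", before = before, after = after,
             nextIdBefore = x@nextId, nextIdAfter = x@nextId,
             wsBefore = x@workingSlice, wsAfter = x@workingSlice)
})

#' @describeIn deleteCells Delete on the slice-wise store: the IDs are
#'   tombstoned in every slice's label list where they occur, so the edit
#'   is cheap and fully reversible.
#' @export
setMethod("deleteCells", "LinkedStack", function(x, ids) {
  ids <- unique(.checkIdsExist(x, ids))
  before <- list()
  after <- list()
  for (z in seq_along(x@slices)) {
    ss <- x@slices[[z]]
    hit <- intersect(ids, setdiff(ss@ids, ss@deleted))
    if (!length(hit)) next
    before[[as.character(z)]] <- ss
    after[[as.character(z)]] <- SliceSeg(ss@baseLabels, ids = ss@ids,
                                         members = ss@members,
                                         deleted = sort(unique(c(ss@deleted,
                                                                 hit))))
  }
  .pushDelta(x, op = "delete", before = before, after = after,
             nextIdBefore = x@nextId, nextIdAfter = x@nextId,
             wsBefore = x@workingSlice, wsAfter = x@workingSlice)
})

# Core of division: split one cell of a resolved slice along a remaining
# mask. Returns the pieces (label matrix over the cell's pixels, ordered
# deterministically), without touching any state.
.dividePieces <- function(resolved, id, mask, connectivity) {
  cellpix <- resolved == id
  if (!any(cellpix)) stop(sprintf("cell %d has no pixels in this slice", id))
  if (!identical(dim(mask), dim(resolved)))
    stop("mask shape does not match the slice")
  mask <- mask != 0
  if (!any(mask)) stop("edited mask is empty")
  if (any(mask & !cellpix))
    stop("edited mask must be a subset of the cell's pixels")
  comps <- labelComponents(mask, connectivity)
  .orderLabelsRowMajor(comps)
}

# Rebuild slice z's SliceSeg after a division: the divided cell's base
# labels are retired, each piece gets a new base label, and `pieceIds`
# assigns the final ID of each piece (joining an existing group when the
# ID is already present in the slice).
.applyDivision <- function(ss, id, comps, pieceIds) {
  keep <- ss@ids != id
  ids <- ss@ids[keep]
  members <- ss@members[keep]
  base <- ss@baseLabels
  oldMembers <- ss@members[[which(ss@ids == id)]]
  base[base %in% oldMembers] <- 0L        # erased pixels become background
  mb <- max(ss@baseLabels)
  np <- max(comps)
  for (j in seq_len(np)) base[comps == j] <- mb + j
  for (j in seq_len(np)) {
    pid <- pieceIds[j]
    at <- match(pid, ids)
    if (is.na(at)) {
      ids <- c(ids, pid)
      members <- c(members, list(mb + j))
    } else {
      members[[at]] <- sort(c(members[[at]], mb + j))
    }
  }
  ord <- order(ids)
  # an ID now carried by a piece is active again
  SliceSeg(base, ids = ids[ord], members = members[ord],
           deleted = setdiff(ss@deleted, pieceIds))
}

#' @describeIn divideCell Division on the slice-wise store; only the
#'   current working slice may be edited (earlier slices are corrected in
#'   the volumetric store instead).
#' @export
setMethod("divideCell", "LinkedStack", function(x, z, id, mask,
                                                connectivity = 4L) {
  z <- as.integer(z)
  if (z != x@workingSlice)
    stop("division is restricted to the current working slice")
  id <- .checkIdsExist(x, id)
  resolved <- resolveSlice(x, z)
  comps <- .dividePieces(resolved, id, mask, connectivity)
  np <- max(comps)
  areas <- tabulate(comps, nbins = np)
  largest <- which.max(areas)             # ties: first in row-major order
  newIds <- integer()
  pieceIds <- integer(np)
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
  ss2 <- .applyDivision(x@slices[[z]], id, comps, pieceIds)
  st <- .pushDelta(x, op = "divide",
                   before = stats::setNames(list(x@slices[[z]]),
                                            as.character(z)),
                   after = stats::setNames(list(ss2), as.character(z)),
                   nextIdBefore = x@nextId, nextIdAfter = nid,
                   wsBefore = x@workingSlice, wsAfter = x@workingSlice)
  list(state = st, newIds = newIds)
})

# Decide which previous-slice ID each piece adopts. `pieces` is a label
# matrix (0 outside), `prev` the resolved previous slice. A piece adopts
# the qualifying (coefficient strictly > threshold) previous ID of
# maximal coefficient; when several pieces qualify for one previous ID,
# only the piece with the largest coefficient links. Returns an integer
# vector (NA = no adoption) parallel to piece numbers.
.relinkAssign <- function(pieces, prev, threshold) {
  np <- max(pieces)
  pairs <- .overlapPairs(prev, pieces)
  pairs <- pairs[pairs$coefficient > threshold, ]
  adopt <- rep(NA_integer_, np)
  if (!nrow(pairs)) return(adopt)
  best <- pairs[order(pairs$currLabel, -pairs$coefficient, pairs$prevId), ]
  best <- best[!duplicated(best$currLabel), ]   # best partner per piece
  # resolve conflicts on the previous ID: max coefficient wins, then the
  # earlier piece in deterministic order
  best <- best[order(best$prevId, -best$coefficient, best$currLabel), ]
  best <- best[!duplicated(best$prevId), ]
  adopt[best$currLabel] <- best$prevId
  adopt
}

#' @describeIn divideRelink Division plus relink on the slice-wise store;
#'   requires `z >= 2` and `z` equal to the working slice.
#' @export
setMethod("divideRelink", "LinkedStack", function(x, z, id, mask,
                                                  params = LinkParams(),
                                                  connectivity = 4L) {
  z <- as.integer(z)
  if (z != x@workingSlice)
    stop("division is restricted to the current working slice")
  if (z < 2L) stop("relink requires a previous slice (z >= 2)")
  id <- .checkIdsExist(x, id)
  stopifnot(is(params, "LinkParams"))
  resolved <- resolveSlice(x, z)
  comps <- .dividePieces(resolved, id, mask, connectivity)
  np <- max(comps)
  areas <- tabulate(comps, nbins = np)
  largest <- which.max(areas)

  prev <- resolveSlice(x, z - 1L)
  adopt <- .relinkAssign(comps, prev, params@overlapThreshold)

  pieceIds <- integer(np)
  nid <- x@nextId
  for (j in seq_len(np)) {
    if (!is.na(adopt[j])) {
      pieceIds[j] <- adopt[j]
    } else if (j == largest && !(id %in% adopt)) {
      pieceIds[j] <- id                   # largest unlinked piece keeps id
    } else {
      pieceIds[j] <- nid
      nid <- nid + 1L
    }
  }
  ss2 <- .applyDivision(x@slices[[z]], id, comps, pieceIds)
  .pushDelta(x, op = "divide_relink",
             before = stats::setNames(list(x@slices[[z]]), as.character(z)),
             after = stats::setNames(list(ss2), as.character(z)),
             nextIdBefore = x@nextId, nextIdAfter = nid,
             wsBefore = x@workingSlice, wsAfter = x@workingSlice)
})

# ---------------------------------------------------------------------------
# Autosave / resume

#' Save / resume a slice-wise project
#'
#' `saveProject` serialises a [LinkedStack] to a single versioned archive
#' holding, per slice, the base label grid plus the label list (group
#' IDs, members and deletions) together with the ID counter -- exactly
#' the state needed to resume a segmentation session. Undo/redo history
#' is deliberately not persisted: a resumed project starts with cleared
#' histories. [runSeg2DLink()] calls `saveProject` after every slice, so
#' an interrupted run resumes at the first unsegmented slice.
#'
#' @param x A [LinkedStack].
#' @param path File path of the archive.
#' @return `saveProject`: `path`, invisibly. `resumeProject`: the
#'   restored [LinkedStack] with empty undo/redo history.
#' @export
saveProject <- function(x, path) {
  stopifnot(is(x, "LinkedStack"))
  payload <- list(
    format = "SliceLinkProject", version = 1L,
    nextId = x@nextId, workingSlice = x@workingSlice,
    historyCapacity = x@historyCapacity, displayWindow = x@displayWindow,
    slices = lapply(x@slices, function(ss)
      list(base = ss@baseLabels, ids = ss@ids, members = ss@members,
           deleted = ss@deleted)))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname saveProject
#' @export
resumeProject <- function(path) {
  if (!file.exists(path)) stop("no such project archive: ", path)
  payload <- tryCatch(readRDS(path), error = function(e)
    stop("corrupt project archive: ", conditionMessage(e)))
  if (!is.list(payload) || !identical(payload$format, "SliceLinkProject"))
    stop("not a SliceLink project archive")
  if (!identical(payload$version, 1L))
    stop("unsupported project archive version")
  slices <- lapply(payload$slices, function(s)
    SliceSeg(s$base, ids = s$ids, members = s$members, deleted = s$deleted))
  st <- new("LinkedStack", slices = slices,
            nextId = payload$nextId, history = list(), redoStack = list(),
            historyCapacity = payload$historyCapacity,
            displayWindow = payload$displayWindow,
            workingSlice = payload$workingSlice)
  validObject(st)
  st
}
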