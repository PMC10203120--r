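# Generics shared between the slice-wise (LinkedStack) and volumetric
# (LabelVolume) stores. The correction semantics are identical; only the
# underlying representation (label lists vs dense voxels) differs.

#' Merge cells into one
#'
#' Collapses all listed final cell IDs onto the smallest ID in the set, in
#' every slice where they occur. On a [LinkedStack] only the per-slice
#' label lists change; on a [LabelVolume] the voxels themselves are
#' relabelled. The edit is recorded for [undo()].
#'
#' @param x A `LinkedStack` or `LabelVolume`.
#' @param ids Integer vector of at least two existing, non-deleted final
#'   cell IDs.
#' @return The edited object.
#' @export
setGeneric("mergeCells", function(x, ids) standardGeneric("mergeCells"))

#' Delete cells
#'
#' Removes the listed final cell IDs everywhere: resolved pixels become
#' background. On a [LinkedStack] the IDs are tombstoned in the label
#' lists (cheap, reversible); on a [LabelVolume] the voxels are zeroed.
#'
#' @param x A `LinkedStack` or `LabelVolume`.
#' @param ids Integer vector of existing cell IDs.
#' @return The edited object.
#' @export
setGeneric("deleteCells", function(x, ids) standardGeneric("deleteCells"))

#' Divide a cell within one slice
#'
#' Splits one cell at slice `z` according to a user-edited binary mask of
#' the pixels that remain: each connected component of the mask becomes a
#' separate cell, the largest component keeps `id`, the others receive
#' fresh IDs (in order of their first pixel), and erased pixels (cell
#' minus mask) become background. On a [LinkedStack] the division is
#' restricted to the current working slice; on a [LabelVolume] any slice
#' may be edited.
#'
#' @param x A `LinkedStack` or `LabelVolume`.
#' @param z Slice index.
#' @param id Final cell ID to divide.
#' @param mask Binary matrix, a subset of the cell's resolved pixels at
#'   slice `z`.
#' @param connectivity 4 or 8 (default 4, so one-pixel erased boundaries
#'   separate pieces).
#' @return A list with elements `state` (the edited object) and `newIds`
#'   (fresh IDs issued, possibly empty).
#' @export
setGeneric("divideCell", function(x, z, id, mask, connectivity = 4L)
  standardGeneric("divideCell"))

#' Divide a cell and relink the pieces to the previous slice
#'
#' Performs [divideCell()] and then links each resulting piece to the
#' resolved previous slice `z - 1`: a piece adopts the previous-slice ID
#' with which its overlap coefficient is maximal among those strictly
#' exceeding the link threshold. Pieces with no qualifying partner keep or
#' receive fresh IDs. If two pieces qualify for the same previous ID, only
#' the piece with the larger coefficient links, so the division is not
#' undone by the relink.
#'
#' @inheritParams divideCell
#' @param params A [LinkParams] object (overlap threshold).
#' @return The edited object.
#' @export
setGeneric("divideRelink", function(x, z, id, mask, params = LinkParams(),
                                    connectivity = 4L)
  standardGeneric("divideRelink"))

#' Undo / redo the last edit
#'
#' Each correction records a reversible delta (label-list snapshots for
#' slice-wise edits, sub-region voxel diffs for volumetric edits). `undo`
#' reverts the most recent edit, `redo` re-applies the most recently
#' undone one. History depth is bounded (default 10 steps for a
#' [LinkedStack], 5 for a [LabelVolume]); deltas evicted at capacity are
#' unrecoverable, and any new edit clears the redo stack. Calling with an
#' empty history is a warning, not an error.
#'
#' @param x A `LinkedStack` or `LabelVolume`.
#' @return The reverted / re-applied object.
#' @export
setGeneric("undo", function(x) standardGeneric("undo"))

#' @rdname undo
#' @export
setGeneric("redo", function(x) standardGeneric("redo"))

#' Active cell IDs of a store
#'
#' @param x A `LinkedStack` or `LabelVolume`.
#' @return Sorted integer vector of final cell IDs currently in use (not
#'   deleted).
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' Number of slices in a store
#'
#' @param x A `LinkedStack` or `LabelVolume`.
#' @return Integer slice count.
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' Resolve the full stack to a dense 3D label array
#'
#' @param x A `LinkedStack` (or `LabelVolume`, where this simply returns
#'   the dense grid).
#' @return Integer array with dims `(y, x, z)` of final cell IDs.
#' @export
setGeneric("resolveVolume", function(x) standardGeneric("resolveVolume"))
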