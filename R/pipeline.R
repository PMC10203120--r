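# The end-to-end slice-by-slice workflow: segment each prediction slice,
# optionally filter by an ROI mask, link to the previous slice, autosave.

#' Run the segment-and-link pipeline over a prediction stack
#'
#' For every slice `z = 1..Z`: [segmentSlice()] on the binary
#' predictions, [applyMask()] against the ROI mask when one is given,
#' then [appendSlice()] (first slice) or [linkSlice()] (subsequent
#' slices). When `project` is set, the state is autosaved after every
#' slice and an interrupted run resumes at the first unsegmented slice,
#' producing the same final volume as an uninterrupted run (resumed
#' stacks start with cleared undo history).
#'
#' @param pred Binary 3D array `(y, x, z)` of cell/non-cell predictions
#'   (any value > 0 is treated as cell).
#' @param mask Optional binary 3D array restricting segmentation to a
#'   region of interest; cells with an in-ROI proportion below
#'   `segParams@maskThreshold` are removed slice by slice.
#' @param segParams A [Seg2DParams].
#' @param linkParams A [LinkParams].
#' @param project Optional directory for autosave/resume archives.
#' @param resume Resume from an existing project archive when present
#'   (default `TRUE`).
#' @param stopAfter Segment only up to this slice (default: all), useful
#'   for interrupting and later resuming a run.
#' @return A [LinkedStack].
#' @examples
#' ph <- generatePhantom(PhantomSpec(dims = c(6L, 48L, 48L), nCells = 3L,
#'                                   radiusRange = c(12, 16), seed = 7L))
#' st <- runSeg2DLink(ph$predictions)
#' nSlices(st)
#' @export
runSeg2DLink <- function(pred, mask = NULL, segParams = Seg2DParams(),
                         linkParams = LinkParams(), project = NULL,
                         resume = TRUE, stopAfter = NULL) {
  if (length(dim(pred)) != 3L) stop("pred must be a 3D array (y, x, z)")
  pred <- array(as.integer(pred > 0), dim(pred))
  if (!is.null(mask) && !identical(dim(mask), dim(pred)))
    stop("mask shape does not match predictions")
  Z <- dim(pred)[3L]
  stopAfter <- if (is.null(stopAfter)) Z else min(Z, as.integer(stopAfter))

  archive <- NULL
  state <- LinkedStack()
  startZ <- 1L
  if (!is.null(project)) {
    if (!dir.exists(project)) dir.create(project, recursive = TRUE)
    archive <- file.path(project, "autosave.rds")
    if (resume && file.exists(archive)) {
      state <- resumeProject(archive)
      if (nSlices(state) &&
          !identical(dim(state@slices[[1L]]@baseLabels), dim(pred)[1:2]))
        stop("project archive does not match the prediction stack shape")
      startZ <- nSlices(state) + 1L
    }
  }
  if (startZ > stopAfter) return(state)

  for (z in startZ:stopAfter) {
    lab <- segmentSlice(pred[, , z], segParams)
    if (!is.null(mask))
      lab <- applyMask(lab, mask[, , z], segParams@maskThreshold)
    state <- if (nSlices(state) == 0L) appendSlice(state, lab)
             else linkSlice(state, lab, linkParams)
    if (!is.null(archive)) saveProject(state, archive)
  }
  state
}
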