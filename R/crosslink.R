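# Cross-slice identity: the overlap coefficient and the linking of a
# freshly segmented slice to the resolved previous slice.

#' Overlap coefficient of two regions
#'
#' `|A intersect B| / min(|A|, |B|)` for two pixel sets, the quantity that
#' decides whether regions in adjacent slices belong to the same cell.
#' Normalising by the smaller region makes the coefficient 1 whenever one
#' region is nested in the other, so a cell that shrinks towards its tip
#' still links slice to slice.
#'
#' @param a,b Binary arrays of identical shape, or integer vectors of
#'   pixel indices. Both regions must be non-empty.
#' @return Coefficient in `[0, 1]`.
#' @examples
#' a <- matrix(0L, 4, 4); a[1:2, ] <- 1L
#' b <- matrix(0L, 4, 4); b[2:3, 1:2] <- 1L
#' overlapCoefficient(a, b)
#' @export
overlapCoefficient <- function(a, b) {
  if (!is.null(dim(a))) {
    if (!identical(dim(a), dim(b))) stop("region shapes differ")
    a <- which(a != 0)
    b <- which(b != 0)
  }
  na <- length(a)
  nb <- length(b)
  if (na == 0L || nb == 0L) stop("regions must be non-empty")
  length(intersect(a, b)) / min(na, nb)
}

# Overlap table between a resolved previous slice and the base labels of
# the new slice: one row per (prevId, currLabel) pair with nonzero
# intersection, with per-slice areas and the coefficient.
.overlapPairs <- function(prev, newBase) {
  pv <- as.integer(prev)
  nv <- as.integer(newBase)
  sel <- pv > 0L & nv > 0L
  areaP <- tabulate(pv, nbins = max(pv, 0L))
  areaC <- tabulate(nv, nbins = max(nv, 0L))
  if (!any(sel))
    return(data.table::data.table(prevId = integer(), currLabel = integer(),
                                  areaPrev = integer(), areaCurr = integer(),
                                  intersection = integer(),
                                  coefficient = numeric()))
  dt <- data.table::data.table(prevId = pv[sel], currLabel = nv[sel])
  ct <- dt[, list(intersection = .N), by = c("prevId", "currLabel")]
  ct[, "areaPrev" := areaP[ct$prevId]]
  ct[, "areaCurr" := areaC[ct$currLabel]]
  ct[, "coefficient" := ct$intersection / pmin(ct$areaPrev, ct$areaCurr)]
  data.table::setorderv(ct, c("prevId", "currLabel"))
  ct[]
}

# minimal union-find
.ufFind <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Link a newly segmented slice to the stack
#'
#' Appends `newBase` as the next slice and transfers identity from the
#' resolved previous slice: a bipartite graph is formed between the final
#' IDs of slice `z - 1` and the base labels of the new slice, with an
#' edge wherever the overlap coefficient strictly exceeds the threshold.
#' Connected components of that graph define identity -- every base label
#' in a component adopts the smallest previous-slice ID it contains. This
#' single rule gives merge propagation in both directions: two previous
#' IDs joined through a shared current label are merged across all
#' earlier slices, and two current labels joined through a shared
#' previous ID are merged in the new slice. Base labels with no edge
#' receive fresh IDs in ascending base-label order. The whole link is one
#' undoable edit.
#'
#' @param x A [LinkedStack] with at least one slice.
#' @param newBase Integer label matrix from [segmentSlice()].
#' @param params A [LinkParams] object.
#' @return The extended stack.
#' @export
linkSlice <- function(x, newBase, params = LinkParams()) {
  stopifnot(is(x, "LinkedStack"), is(params, "LinkParams"))
  nz <- length(x@slices)
  if (nz == 0L) stop("linkSlice needs an existing slice; use appendSlice")
  storage.mode(newBase) <- "integer"
  if (!identical(dim(newBase), dim(x@slices[[1L]]@baseLabels)))
    stop("slice shape does not match the stack")

  prev <- .resolveSliceSeg(x@slices[[nz]])
  pairs <- .overlapPairs(prev, newBase)
  edges <- pairs[pairs$coefficient > params@overlapThreshold, ]

  currLabs <- sort(unique(newBase[newBase > 0L]))
  prevIds <- sort(unique(edges$prevId))

  # union-find over prev IDs and current labels
  nodes <- c(paste0("p", prevIds), paste0("c", currLabs))
  parent <- seq_along(nodes)
  names(parent) <- nodes
  lookup <- seq_along(nodes)
  names(lookup) <- nodes
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      i <- .ufFind(parent, lookup[[paste0("p", edges$prevId[k])]])
      j <- .ufFind(parent, lookup[[paste0("c", edges$currLabel[k])]])
      if (i != j) parent[max(i, j)] <- min(i, j)
    }
  }
  roots <- vapply(seq_along(nodes), function(i) .ufFind(parent, i), 0L)

  # per component: target ID = smallest previous ID, if any
  isPrev <- seq_along(nodes) <= length(prevIds)
  targets <- rep(NA_integer_, length(nodes))
  for (r in unique(roots)) {
    inComp <- which(roots == r)
    p <- inComp[isPrev[inComp]]
    if (length(p)) targets[inComp] <- min(prevIds[p])
  }

  # assignment for each current base label
  assign <- rep(NA_integer_, length(currLabs))
  for (i in seq_along(currLabs)) {
    node <- lookup[[paste0("c", currLabs[i])]]
    assign[i] <- targets[node]
  }
  fresh <- which(is.na(assign))
  nid <- x@nextId
  if (length(fresh)) {
    assign[fresh] <- nid + seq_along(fresh) - 1L   # ascending base label
    nid <- nid + length(fresh)
  }

  # merge propagation to earlier slices: previous IDs collapsing together
  mergeMap <- list()                      # id -> target
  for (i in which(isPrev)) {
    id <- prevIds[i]
    tg <- targets[i]
    if (!is.na(tg) && tg != id) mergeMap[[as.character(id)]] <- tg
  }

  before <- list()
  after <- list()
  if (length(mergeMap)) {
    oldIds <- as.integer(names(mergeMap))
    for (z in seq_len(nz)) {
      ss <- x@slices[[z]]
      if (!any(oldIds %in% ss@ids)) next
      before[[as.character(z)]] <- ss
      after[[as.character(z)]] <- .remapSliceIds(
        ss, oldIds, vapply(mergeMap, identity, 0L))
    }
  }

  # group base labels of the new slice by final ID
  grp <- split(currLabs, assign)
  newIds <- as.integer(names(grp))
  ord <- order(newIds)
  ss <- SliceSeg(newBase, ids = newIds[ord], members = grp[ord])

  .pushDelta(x, op = "link", before = before, after = after,
             appendedSlice = ss,
             nextIdBefore = x@nextId, nextIdAfter = nid,
             wsBefore = x@workingSlice, wsAfter = nz + 1L)
}

# reassign final IDs oldIds[i] -> newIds[i] in one SliceSeg, merging
# groups that collapse onto the same target ID.
.remapSliceIds <- function(ss, oldIds, newIds) {
  ids <- ss@ids
  map <- match(ids, oldIds)
  ids[!is.na(map)] <- newIds[map[!is.na(map)]]
  # merge duplicate IDs
  if (anyDuplicated(ids)) {
    grp <- split(seq_along(ids), ids)
    mem <- lapply(grp, function(ix)
      sort(unlist(ss@members[ix], use.names = FALSE)))
    ids2 <- as.integer(names(grp))
    ord <- order(ids2)
    members <- mem[ord]
    ids <- ids2[ord]
  } else {
    members <- ss@members
  }
  del <- ss@deleted
  dmap <- match(del, oldIds)
  del[!is.na(dmap)] <- newIds[dmap[!is.na(dmap)]]
  SliceSeg(ss@baseLabels, ids = ids, members = members,
           deleted = unique(del))
}
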