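# Fixture builders and independent oracles. The oracles deliberately use
# naive per-pixel code paths (explicit loops, which(..., arr.ind), igraph
# components) so they share nothing with the package's implementations.

makeDisk <- function(nr, nc, cy, cx, r) {
  m <- matrix(0L, nr, nc)
  for (y in seq_len(nr)) for (x in seq_len(nc))
    if ((y - cy)^2 + (x - cx)^2 <= r^2) m[y, x] <- 1L
  m
}

makeBall <- function(d, cy, cx, cz, r) {
  a <- array(0L, d)
  for (z in seq_len(d[3])) for (y in seq_len(d[1])) for (x in seq_len(d[2]))
    if ((y - cy)^2 + (x - cx)^2 + (z - cz)^2 <= r^2) a[y, x, z] <- 1L
  a
}

# per-pixel dictionary-substitution resolution of a LinkedStack
naiveResolveStack <- function(st) {
  nz <- nSlices(st)
  d <- dim(slot(slot(st, "slices")[[1]], "baseLabels"))
  out <- array(0L, c(d, nz))
  for (z in seq_len(nz)) {
    ss <- slot(st, "slices")[[z]]
    base <- slot(ss, "baseLabels")
    ids <- slot(ss, "ids")
    members <- slot(ss, "members")
    deleted <- slot(ss, "deleted")
    for (y in seq_len(d[1])) for (x in seq_len(d[2])) {
      b <- base[y, x]
      if (b == 0L) next
      for (k in seq_along(ids)) {
        if (b %in% members[[k]]) {
          if (!(ids[k] %in% deleted)) out[y, x, z] <- ids[k]
          break
        }
      }
    }
  }
  out
}

# exhaustive-scan bounding boxes / volumes of a dense label array
naiveStats <- function(arr) {
  ids <- sort(unique(arr[arr > 0L]))
  bbox <- matrix(0L, length(ids), 6,
                 dimnames = list(ids, c("y0", "y1", "x0", "x1", "z0", "z1")))
  vols <- numeric(length(ids))
  for (i in seq_along(ids)) {
    w <- which(arr == ids[i], arr.ind = TRUE)
    if (ncol(w) == 2) w <- cbind(w, 1L)
    bbox[i, ] <- c(range(w[, 1]), range(w[, 2]), range(w[, 3]))
    vols[i] <- nrow(w)
  }
  list(ids = ids, bbox = bbox, volumes = vols)
}

# pixel-count overlap coefficient on binary masks
pixelCountCoefficient <- function(a, b) {
  sum(a & b) / min(sum(a != 0), sum(b != 0))
}

# Brute-force linking oracle: enumerate all (prev id, new label) pairs by
# scanning pixels, connect those with coefficient > threshold, take graph
# components (igraph), and assign every new label the smallest previous
# ID in its component, or a fresh ID (ascending label order) if none.
naiveLinkAssign <- function(prev, newBase, threshold, nextId) {
  prevIds <- sort(unique(prev[prev > 0L]))
  currLabs <- sort(unique(newBase[newBase > 0L]))
  edges <- character(0)
  for (p in prevIds) for (cc in currLabs) {
    inter <- sum(prev == p & newBase == cc)
    if (inter == 0) next
    coef <- inter / min(sum(prev == p), sum(newBase == cc))
    if (coef > threshold)
      edges <- c(edges, paste0("p", p), paste0("c", cc))
  }
  assign <- setNames(rep(NA_integer_, length(currLabs)),
                     paste0("c", currLabs))
  mergeMap <- integer(0)
  if (length(edges)) {
    g <- igraph::make_graph(edges, directed = FALSE)
    comp <- igraph::components(g)$membership
    for (ci in unique(comp)) {
      nm <- names(comp)[comp == ci]
      pn <- as.integer(sub("p", "", nm[startsWith(nm, "p")]))
      cn <- nm[startsWith(nm, "c")]
      if (length(pn)) {
        tgt <- min(pn)
        assign[cn] <- tgt
        for (p in setdiff(pn, tgt)) mergeMap[as.character(p)] <- tgt
      }
    }
  }
  fresh <- which(is.na(assign))
  if (length(fresh)) assign[fresh] <- nextId + seq_along(fresh) - 1L
  list(assign = setNames(as.integer(assign),
                         sub("c", "", names(assign))),
       mergeMap = mergeMap)
}

# a small linked stack built from explicitly constructed slices
demoStack <- function() {
  b1 <- matrix(0L, 6, 6)
  b1[1:3, 1:3] <- 1L; b1[1:2, 5:6] <- 2L; b1[5:6, 1:2] <- 3L
  b2 <- b1
  b3 <- matrix(0L, 6, 6)
  b3[1:3, 1:4] <- 1L; b3[5:6, 1:2] <- 2L
  st <- LinkedStack(b1)
  st <- linkSlice(st, b2)
  st <- linkSlice(st, b3)
  st
}

expect_same_labelling <- function(a, b) {
  # identical up to a bijection of positive labels
  expect_identical(a == 0L, b == 0L)
  ta <- tapply(b[a > 0L], a[a > 0L], function(v) length(unique(v)))
  tb <- tapply(a[b > 0L], b[b > 0L], function(v) length(unique(v)))
  expect_true(all(ta == 1L) && all(tb == 1L))
}
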