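# The volumetric store: cache construction, localization, sorting,
# removal, 3D division, insertion, shared corrections, diff-based
# undo/redo, and import/export round trips.

randomVolume <- function(d = c(12, 12, 6), k = 5) {
  arr <- array(0L, d)
  for (id in seq_len(k)) {
    c0 <- c(sample(d[1], 1), sample(d[2], 1), sample(d[3], 1))
    r <- sample(2:4, 1)
    ys <- max(1, c0[1] - r):min(d[1], c0[1] + r)
    xs <- max(1, c0[2] - r):min(d[2], c0[2] + r)
    zs <- max(1, c0[3] - 1):min(d[3], c0[3] + 1)
    arr[ys, xs, zs] <- id
  }
  arr
}

expect_coherent_caches <- function(vol) {
  want <- naiveStats(resolveVolume(vol))
  expect_identical(cellIds(vol), as.integer(want$ids))
  got <- cellBoxes(vol)[as.character(want$ids), , drop = FALSE]
  expect_identical(unname(got), unname(want$bbox))
  expect_identical(unname(cellVolumes(vol)[as.character(want$ids)]),
                   want$volumes)
}

test_that("buildVolume caches match an exhaustive-scan oracle", {
  # empty volume
  v0 <- buildVolume(array(0L, c(4, 4, 2)))
  expect_identical(cellIds(v0), integer(0))

  # a 3x3x3 cube of ID 4 at the origin
  a <- array(0L, c(6, 6, 6)); a[1:3, 1:3, 1:3] <- 4L
  vol <- buildVolume(a)
  expect_identical(unname(cellVolumes(vol)), 27)
  expect_identical(unname(cellBoxes(vol)["4", ]),
                   c(1L, 3L, 1L, 3L, 1L, 3L))

  set.seed(41)
  for (rep in 1:5) expect_coherent_caches(buildVolume(randomVolume()))

  expect_error(buildVolume(array(-1L, c(2, 2, 2))), "non-negative")
})

test_that("locateCell returns the bbox z midpoint, same as a full scan", {
  a <- array(0L, c(4, 4, 25))
  a[2, 2, 11:21] <- 7L                       # spans z 11..21 -> middle 16
  vol <- buildVolume(a)
  expect_identical(locateCell(vol, 7)$middleZ, 16L)

  a2 <- array(0L, c(4, 4, 10)); a2[1, 1, 7] <- 2L
  expect_identical(locateCell(buildVolume(a2), 2)$middleZ, 7L)

  expect_error(locateCell(vol, 99), "unknown cell ID")

  set.seed(43)
  for (rep in 1:5) {
    vol <- buildVolume(randomVolume())
    for (id in cellIds(vol)) {
      got <- locateCell(vol, id)
      w <- which(resolveVolume(vol) == id, arr.ind = TRUE)  # full scan
      zr <- range(w[, 3])
      expect_identical(got$middleZ, as.integer(floor(sum(zr) / 2)))
      expect_identical(unname(got$bbox),
                       as.integer(c(range(w[, 1]), range(w[, 2]), zr)))
    }
  }
})

test_that("sortByVolume relabels largest-first with stable ties", {
  a <- array(0L, c(10, 10, 3))
  a[1:3, 1:10, 1] <- 1L      # 30 voxels
  a[1:10, 1:10, 2] <- 2L     # 100 voxels
  a[1:7, 1:10, 3] <- 3L      # 70 voxels
  vol <- sortByVolume(buildVolume(a))
  v <- resolveVolume(vol)
  expect_true(all(v[, , 2] == 1L))           # old 2 -> new 1
  expect_true(all(v[1:7, , 3] == 2L))        # old 3 -> new 2
  expect_true(all(v[1:3, , 1] == 3L))        # old 1 -> new 3
  expect_identical(unname(cellVolumes(vol)), c(100, 70, 30))
  expect_coherent_caches(vol)

  # already sorted: identity relabelling
  vol2 <- sortByVolume(vol)
  expect_identical(resolveVolume(vol2), v)

  # volumes multiset invariant under sort
  set.seed(47)
  r <- buildVolume(randomVolume())
  expect_identical(sort(unname(cellVolumes(sortByVolume(r)))),
                   sort(unname(cellVolumes(r))))
})

test_that("removeSmall removes exactly the sub-threshold cells", {
  a <- array(0L, c(10, 10, 3))
  a[1:10, 1:10, 1] <- 1L     # 100
  a[1, 1:5, 2] <- 2L         # 5
  a[1:5, 1:10, 3] <- 3L      # 50
  vol <- buildVolume(a)
  res <- removeSmall(vol, 10)
  expect_identical(res$removed, 2L)
  expect_setequal(cellIds(res$state), c(1L, 3L))
  expect_coherent_caches(res$state)

  expect_identical(removeSmall(vol, 0)$removed, integer(0))
  expect_setequal(removeSmall(vol, 1000)$removed, c(1L, 2L, 3L))
  expect_true(all(resolveVolume(removeSmall(vol, 1000)$state) == 0L))
})

test_that("divide3D separates disconnected parts of one cell", {
  a <- array(0L, c(8, 8, 9))
  a[3:6, 3:6, 2:3] <- 5L
  a[3:6, 3:6, 7:8] <- 5L                     # same ID, gap at z 4:6
  vol <- buildVolume(a)
  res <- divide3D(vol, 5)
  expect_identical(length(res$newIds), 1L)
  v <- resolveVolume(res$state)
  expect_identical(unique(as.integer(v[3:6, 3:6, 2:3])), 5L)  # first kept
  expect_identical(unique(as.integer(v[3:6, 3:6, 7:8])), res$newIds)
  expect_coherent_caches(res$state)

  # matches an independent component labelling
  comps <- labelComponents(a == 5L, 26L)
  expect_identical(v[comps == 1L], rep(5L, sum(comps == 1L)))

  # single-component cell: unchanged except history
  single <- buildVolume(array(rep(c(0L, 3L), c(10, 10)), c(4, 5, 1)))
  res2 <- divide3D(single, 3)
  expect_identical(res2$newIds, integer(0))
  expect_identical(resolveVolume(res2$state), resolveVolume(single))

  expect_error(divide3D(vol, 99), "unknown cell ID")
})

test_that("insertCell paints new IDs only over background", {
  a <- array(0L, c(6, 6, 4)); a[1:2, 1:2, 1] <- 1L
  vol <- buildVolume(a)
  paint <- array(0L, c(6, 6, 4)); paint[4:5, 4:5, 2] <- 1L
  res <- insertCell(vol, paint)
  expect_identical(res$newId, 2L)
  expect_identical(unname(cellVolumes(res$state)["2"]), 4)
  expect_coherent_caches(res$state)

  # two inserts give distinct ascending IDs
  paint2 <- array(0L, c(6, 6, 4)); paint2[1, 6, 4] <- 1L
  res2 <- insertCell(res$state, paint2)
  expect_identical(res2$newId, 3L)

  # insert then undo restores the volume bit-identically
  expect_identical(resolveVolume(undo(res$state)), a)

  over <- array(0L, c(6, 6, 4)); over[1, 1, 1] <- 1L
  expect_error(insertCell(vol, over), "existing cell")
  expect_error(insertCell(vol, array(0L, c(6, 6, 4))), "empty")
})

test_that("volume merge/delete/divide share slice-wise semantics", {
  set.seed(53)
  a <- randomVolume(c(14, 14, 6), 6)
  vol <- buildVolume(a)
  ids <- cellIds(vol)

  m <- mergeCells(vol, ids[1:2])
  expect_false(ids[2] %in% cellIds(m))
  want <- a; want[want == ids[2]] <- ids[1]
  expect_identical(resolveVolume(m), want)
  expect_coherent_caches(m)                  # bbox becomes union-tight

  d <- deleteCells(vol, ids[3])
  expect_false(any(resolveVolume(d) == ids[3]))
  expect_coherent_caches(d)

  # 2D division at a mid-stack slice touches only that slice
  id <- ids[1]
  zs <- which(apply(a == id, 3, any))
  z <- zs[ceiling(length(zs) / 2)]
  r <- a[, , z]
  mask <- (r == id)
  mask[, seq(1, ncol(mask), by = 3)] <- FALSE  # erase stripes
  if (any(mask)) {
    res <- divideCell(vol, z, id, mask)
    v <- resolveVolume(res$state)
    expect_identical(v[, , -z], a[, , -z])
    expect_coherent_caches(res$state)
    # undo is bit-identical
    expect_identical(resolveVolume(undo(res$state)), a)
  }
})

test_that("volume divideRelink adopts IDs from the slice below", {
  a <- array(0L, c(10, 14, 2))
  a[2:9, 2:6, 1] <- 1L; a[2:9, 9:13, 1] <- 2L
  a[2:9, 2:13, 2] <- 3L                      # merged cell above both
  vol <- buildVolume(a)
  mask <- a[, , 2] == 3L
  mask[, 7:8] <- FALSE
  res <- divideRelink(vol, 2, 3, mask)
  v <- resolveVolume(res)
  expect_identical(unique(as.integer(v[2:9, 2:6, 2])), 1L)
  expect_identical(unique(as.integer(v[2:9, 9:13, 2])), 2L)
  expect_coherent_caches(res)
  expect_error(divideRelink(vol, 1, 3, mask), "z >= 2")
})

test_that("random op sequences keep caches coherent and undo exactly", {
  set.seed(59)
  for (rep in 1:8) {
    a <- randomVolume(c(12, 12, 6), 5)
    vol <- buildVolume(a)                    # capacity 5 (default)
    states <- list(resolveVolume(vol))
    nops <- 0L
    for (k in 1:5) {
      ids <- cellIds(vol)
      op <- sample(c("merge", "delete", "divide3d", "insert", "remove",
                     "sort", "divide2d"), 1)
      volNew <- tryCatch(switch(op,
        merge = if (length(ids) >= 2) mergeCells(vol, sample(ids, 2)),
        delete = if (length(ids) >= 1) deleteCells(vol, sample(ids, 1)),
        divide3d = if (length(ids) >= 1)
          divide3D(vol, sample(ids, 1))$state,
        insert = {
          p <- array(0L, dim(a))
          free <- which(resolveVolume(vol) == 0L)
          p[sample(free, min(6, length(free)))] <- 1L
          insertCell(vol, p)$state
        },
        remove = removeSmall(vol, sample(c(5, 30, 80), 1))$state,
        sort = if (length(ids) >= 1) sortByVolume(vol),
        divide2d = if (length(ids) >= 1) {
          id <- sample(ids, 1)
          lv <- resolveVolume(vol)
          zs <- which(apply(lv == id, 3, any))
          z <- sample(zs, 1)
          msk <- (lv[, , z] == id) & matrix(runif(144) < 0.7, 12, 12)
          if (any(msk)) divideCell(vol, z, id, msk)$state
        }
      ), error = function(e) NULL)
      if (!is.null(volNew)) {
        vol <- volNew
        nops <- nops + 1L
        states[[nops + 1L]] <- resolveVolume(vol)
        expect_coherent_caches(vol)
        # the delta's voxel diff stays inside the recorded stats' boxes
        h <- slot(vol, "history")
        dl <- h[[length(h)]]
        if (length(dl$idx)) {
          boxes <- rbind(dl$statsBefore$bbox, dl$statsAfter$bbox)
          d <- dim(resolveVolume(vol))
          w0 <- dl$idx - 1
          yy <- w0 %% d[1] + 1
          xx <- (w0 %/% d[1]) %% d[2] + 1
          zz <- w0 %/% (d[1] * d[2]) + 1
          expect_true(all(yy >= min(boxes[, 1]) & yy <= max(boxes[, 2]) &
                          xx >= min(boxes[, 3]) & xx <= max(boxes[, 4]) &
                          zz >= min(boxes[, 5]) & zz <= max(boxes[, 6])))
        }
      }
    }
    # full undo chain restores the initial grid exactly (within capacity)
    depth <- min(nops, 5L)
    for (k in seq_len(depth)) vol <- undo(vol)
    expect_identical(resolveVolume(vol), states[[nops + 1L - depth]])
    expect_coherent_caches(vol)
    # redo replays forward exactly
    for (k in seq_len(depth)) vol <- redo(vol)
    expect_identical(resolveVolume(vol), states[[nops + 1L]])
  }
})

test_that("TIFF sequence and RDS round trips are lossless", {
  set.seed(61)
  a <- randomVolume(c(10, 12, 4), 4)
  vol <- buildVolume(a)

  dir <- file.path(tempdir(), "seq-test")
  exportVolume(vol, dir)
  files <- list.files(dir, pattern = "\\.tif$")
  expect_identical(length(files), 4L)
  expect_true(all(grepl("^seg_\\d{5}\\.tif$", files)))
  back <- importVolume(dir)
  expect_identical(resolveVolume(back), a)
  expect_identical(length(slot(back, "history")), 0L)

  # single-slice volume exports exactly one file
  d1 <- file.path(tempdir(), "seq-one")
  exportVolume(buildVolume(array(1L, c(4, 4, 1))), d1)
  expect_identical(length(list.files(d1)), 1L)

  # RDS round trip
  f <- tempfile(fileext = ".rds")
  exportVolume(vol, f)
  expect_identical(resolveVolume(importVolume(f)), a)

  # IDs beyond 16 bit use the wide sample format and still round-trip
  big <- array(0L, c(6, 6, 2))
  big[2:3, 2:3, 1] <- 70000L
  big[5, 5, 2] <- 123456L
  d2 <- file.path(tempdir(), "seq-wide")
  writeStack(big, d2)
  expect_identical(readStack(d2), big)

  # watershed3D output can be imported for correction
  ball <- makeBall(c(12, 12, 12), 6, 6, 6, 4)
  seg <- watershed3D(ball)
  f2 <- tempfile(fileext = ".rds")
  exportVolume(seg, f2)
  expect_identical(resolveVolume(importVolume(f2)), seg)

  # mixed shapes in a sequence are a format error
  d3 <- file.path(tempdir(), "seq-bad")
  dir.create(d3, showWarnings = FALSE)
  tiff::writeTIFF(matrix(0, 4, 4), file.path(d3, "s_0.tif"),
                  bits.per.sample = 16)
  tiff::writeTIFF(matrix(0, 5, 5), file.path(d3, "s_1.tif"),
                  bits.per.sample = 16)
  expect_error(readStack(d3), "inconsistent")
})
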