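test_that("luminance conversion follows Rec. 601 with rounding", {
  expect_identical(toLuminance(flatRGB(1, 1, c(255, 255, 255)))[1, 1], 255L)
  expect_identical(toLuminance(flatRGB(1, 1, c(0, 0, 0)))[1, 1], 0L)
  expect_identical(toLuminance(flatRGB(1, 1, c(255, 0, 0)))[1, 1], 76L)
  expect_error(toLuminance(matrix(0, 4, 4)), "3 array")
})

test_that("adaptive threshold segments locally bright or dark objects", {
  all1 <- matrix(TRUE, 32, 32)
  # uniform image at unit sensitivity: no pixel exceeds its own mean
  uni <- matrix(128L, 32, 32)
  cfg1 <- preprocessConfig(thresholdSensitivity = 1.0)
  expect_false(any(adaptiveThreshold(uni, all1, cfg1)))
  # bright 5x5 square (250) on a dark field (10)
  g <- matrix(10L, 32, 32)
  g[14:18, 14:18] <- 250L
  fgB <- adaptiveThreshold(g, all1, preprocessConfig(polarity = "bright"))
  expect_true(all(fgB[14:18, 14:18]))
  fgD <- adaptiveThreshold(g, all1, preprocessConfig(polarity = "dark"))
  expect_false(any(fgD[14:18, 14:18]))
  # oversized window
  expect_error(
    adaptiveThreshold(matrix(0L, 8, 8), matrix(TRUE, 8, 8),
                      preprocessConfig(thresholdWindow = 9L)),
    "larger")
})

test_that("labelling is 8-connected with per-object areas", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE  # diagonal touch: one object
  expect_equal(nObjects(labelObjects(m)), 1)
  expect_equal(nObjects(labelObjects(matrix(FALSE, 5, 5))), 0)
  m3 <- matrix(FALSE, 12, 12)
  for (o in 0:2) m3[o * 4 + 1:3, 1:3] <- TRUE
  lo <- labelObjects(m3)
  expect_equal(nObjects(lo), 3)
  expect_equal(objectTable(lo)$area, rep(9L, 3))
})

test_that("perimeter is the accumulated centre-to-centre boundary walk", {
  expect_equal(objectPerimeter(matrix(TRUE, 3, 3)), 8)
  expect_equal(objectPerimeter(matrix(TRUE, 1, 2)), 2)
  expect_equal(objectPerimeter(matrix(TRUE, 1, 1)), 0)
  # diagonal pair: out-and-back along one sqrt(2) step
  d <- matrix(FALSE, 2, 2); d[1, 1] <- TRUE; d[2, 2] <- TRUE
  expect_equal(objectPerimeter(d), 2 * sqrt(2))
  multi <- matrix(FALSE, 5, 5); multi[1, 1] <- TRUE; multi[5, 5] <- TRUE
  expect_error(objectPerimeter(multi), "single")
})

test_that("area, perimeter, circularity are invariant to translation and rotation", {
  set.seed(21)
  for (rep in 1:5) {
    m <- matrix(FALSE, 15, 15)
    m[4:9, 5:11] <- matrix(runif(42) < 0.75, 6, 7)
    m[6, 7] <- TRUE
    lo <- labelObjects(m)
    keep <- which.max(objectTable(lo)$area)
    big <- labelImage(lo) == keep
    # translate within a larger frame
    t1 <- matrix(FALSE, 20, 20); t1[3:17, 4:18] <- big
    # rotate 90 degrees
    r1 <- t(big)[ncol(big):1, , drop = FALSE]
    p0 <- objectPerimeter(big); a0 <- sum(big)
    expect_equal(objectPerimeter(t1), p0)
    expect_equal(objectPerimeter(r1), p0)
    if (p0 > 0)
      expect_equal(circularity(a0, objectPerimeter(r1)),
                   circularity(a0, p0))
  }
})

test_that("circularity matches closed forms and rejects zero perimeter", {
  r <- 5; expect_equal(circularity(pi * r^2, 2 * pi * r), 1)
  expect_equal(circularity(9, 8), 36 * pi / 64)
  expect_error(circularity(5, 0), "undefined")
})

test_that("object filter deletes small and near-circular objects only", {
  mkObjs <- function(areas, perims, circs) {
    lab <- matrix(0L, 4, length(areas))
    for (i in seq_along(areas)) lab[1, i] <- i
    new("LabeledObjects", labelImage = lab,
        objects = data.frame(object = seq_along(areas),
                             area = pmax(areas, 1L), perimeter = perims,
                             circularity = circs))
  }
  cfg <- preprocessConfig()
  tab <- attr(filterObjects(
    mkObjs(areas = c(7L, 8L, 100L, 100L),
           perims = c(10, 10, 30, 60),
           circs = c(0.9, 0.5, 0.98, 0.4)), cfg), "objects")
  expect_identical(tab$deleted, c(TRUE, FALSE, TRUE, FALSE))
  # disabled pre-processing excludes nothing
  off <- filterObjects(mkObjs(7L, 5, 1), preprocessConfig(enabled = FALSE))
  expect_false(any(off))
  # monotone in minArea: raising the threshold never un-deletes
  set.seed(3)
  areas <- sample(1:40, 12); circs <- runif(12, 0.2, 1.2)
  objs <- mkObjs(areas, rep(10, 12), circs)
  prev <- rep(FALSE, 12)
  for (ma in c(1, 5, 10, 20, 50)) {
    del <- attr(filterObjects(objs, preprocessConfig(minArea = ma)),
                "objects")$deleted
    expect_true(all(del | !prev))
    prev <- del
  }
  # decision depends only on (area, circularity): permuting ids
  perm <- sample(12)
  del1 <- attr(filterObjects(objs, cfg), "objects")$deleted
  del2 <- attr(filterObjects(mkObjs(areas[perm], rep(10, 12), circs[perm]),
                             cfg), "objects")$deleted
  expect_identical(del2, del1[perm])
})

test_that("preprocessRegion composes the stages and honours the off switch", {
  blank <- flatRGB(40, 40, c(128, 128, 128))
  mask <- matrix(TRUE, 40, 40)
  expect_false(any(preprocessRegion(blank, mask)))
  spec <- makeSpecimen(list(face = 0.4), seed = 5, patchSize = c(64, 64))
  m <- rasterizeRoi(regions(spec$roiset)[[1]],
                    imageSize(spec$roiset)["width"],
                    imageSize(spec$roiset)["height"])
  off <- preprocessRegion(spec$rgb, m, preprocessConfig(enabled = FALSE))
  expect_false(any(off))
})

test_that("injected pollen disks are recalled with few false deletions", {
  spec <- makeSpecimen(list(thorax_dorsal = 0.4), seed = 101,
                       patchSize = c(160, 160))
  w <- imageSize(spec$roiset)["width"]; h <- imageSize(spec$roiset)["height"]
  mask <- rasterizeRoi(regions(spec$roiset)[[1]], w, h)
  cont <- addPollenArtifacts(spec$rgb, n = 10, seed = 202,
                             regionMask = mask)
  excl <- preprocessRegion(cont$rgb, mask, preprocessConfig())
  circ <- cont$circles
  inDisk <- matrix(FALSE, h, w)
  recalled <- 0
  for (i in seq_len(nrow(circ))) {
    d <- diskMask(h, w, circ$x[i], circ$y[i], circ$radius[i])
    inDisk <- inDisk | d
    if (mean(excl[d]) >= 0.5) recalled <- recalled + 1
  }
  expect_gte(recalled / nrow(circ), 0.8)
  falseRate <- sum(excl & !inDisk) / sum(mask & !inDisk)
  expect_lt(falseRate, 0.02)
})
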