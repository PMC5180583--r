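test_that("disk structuring elements enumerate exact Euclidean disks", {
  expect_equal(nrow(seOffsets(diskOffsets(0))), 1)
  expect_equal(nrow(seOffsets(diskOffsets(1))), 5)   # von Neumann cross
  expect_equal(nrow(seOffsets(diskOffsets(7))), 149)
  # brute-force lattice count oracle
  for (r in c(2, 5, 7)) {
    cnt <- sum(outer((-r:r)^2, (-r:r)^2, "+") <= r^2)
    expect_equal(nrow(seOffsets(diskOffsets(r))), cnt)
  }
  expect_error(diskOffsets(-1), "non-negative")
})

test_that("local entropy has the analytic values and bounds", {
  # constant image: single-bin histogram
  expect_true(all(localEntropy(matrix(57L, 24, 24)) == 0))
  # two-value checkerboard, r = 1: interior counts {1, 4}
  ch <- matrix(0L, 20, 20)
  ch[(row(ch) + col(ch)) %% 2 == 0] <- 200L
  h <- localEntropy(ch, diskOffsets(1))
  hExpect <- -(1 / 5) * log2(1 / 5) - (4 / 5) * log2(4 / 5)
  expect_equal(h[5:16, 5:16], matrix(hExpect, 12, 12), tolerance = 1e-12)
  # support-size bound at r = 7
  set.seed(9)
  img <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  h7 <- localEntropy(img, diskOffsets(7))
  expect_true(all(h7 <= log2(149) + 1e-12))
  expect_true(all(h7 >= 0))
})

test_that("optimized entropy equals the brute-force oracle", {
  set.seed(42)
  for (rep in 1:2) {
    img <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
    se <- diskOffsets(if (rep == 1) 3 else 5)
    excl <- matrix(runif(64 * 64) < 0.05, 64, 64)
    got <- localEntropy(img, se, excl)
    want <- naiveLocalEntropy(img, seOffsets(se), excl)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("entropy is invariant under bijective gray-value remapping", {
  set.seed(5)
  img <- matrix(sample(0:255, 48 * 48, TRUE), 48, 48)
  perm <- sample(0:255)
  remap <- matrix(perm[img + 1L], 48, 48)
  se <- diskOffsets(4)
  expect_equal(localEntropy(img, se), localEntropy(remap, se),
               tolerance = 1e-12)
})

test_that("entropy layers are translation-equivariant in the interior", {
  set.seed(6)
  big <- matrix(sample(0:255, 60 * 60, TRUE), 60, 60)
  se <- diskOffsets(4)
  h1 <- localEntropy(big, se)
  h2 <- localEntropy(big[6:60, 6:60], se)
  expect_equal(h1[11:50, 11:50], h2[6:45, 6:45], tolerance = 1e-12)
})

test_that("channel combination is the per-pixel product with zero absorption", {
  a <- matrix(2, 4, 4); b <- matrix(2, 4, 4); c0 <- matrix(2, 4, 4)
  ei <- combineChannels(a, b, c0)
  expect_true(all(entropyValues(ei) == 8))
  a[2, 2] <- 0
  expect_equal(entropyValues(combineChannels(a, b, c0))[2, 2], 0)
  # grayscale input: identical layers cube
  set.seed(8)
  g <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
  h <- localEntropy(g, diskOffsets(3))
  ei3 <- combineChannels(h, h, h)
  expect_equal(entropyValues(ei3), h^3, tolerance = 1e-12)
  expect_error(combineChannels(a, b, matrix(0, 3, 3)), "dimension")
  # excluded pixels are invalid and zeroed
  excl <- matrix(FALSE, 4, 4); excl[1, 1] <- TRUE
  ei4 <- combineChannels(b, b, b, excl)
  expect_false(validMask(ei4)[1, 1])
  expect_equal(entropyValues(ei4)[1, 1], 0)
})

test_that("region summaries use valid in-region pixels and sample SD", {
  es <- matrix(5, 4, 4)
  ei <- new("EntropyImage", es = es, valid = matrix(TRUE, 4, 4))
  m <- matrix(FALSE, 4, 4); m[1:2, 1:2] <- TRUE
  s <- regionSummary(ei, m, "img", "face")
  expect_equal(s$mean_es, 5); expect_equal(s$sd_es, 0)
  expect_equal(s$n_valid, 4)
  es2 <- matrix(0, 2, 2); es2[] <- c(1, 1, 3, 3)
  ei2 <- new("EntropyImage", es = es2, valid = matrix(TRUE, 2, 2))
  s2 <- regionSummary(ei2, matrix(TRUE, 2, 2), "img", "face")
  expect_equal(s2$mean_es, 2)
  expect_equal(s2$sd_es, 2 / sqrt(3), tolerance = 1e-12)
  # fully excluded region
  eiX <- new("EntropyImage", es = matrix(0, 2, 2),
             valid = matrix(FALSE, 2, 2))
  expect_error(regionSummary(eiX, matrix(TRUE, 2, 2), "img", "face"),
               "face")
})

test_that("measured hairiness orders hairy above smooth regions", {
  spec <- makeSpecimen(list(face = 0.5, thorax_dorsal = 0), seed = 31,
                       patchSize = c(96, 96))
  res <- measureImage(spec$rgb, spec$roiset)
  expect_gt(res$mean_es[res$region == "face"],
            res$mean_es[res$region == "thorax_dorsal"])
})

test_that("disabling pre-processing changes nothing on artifact-free images", {
  spec <- makeSpecimen(list(face = 0), seed = 12, patchSize = c(64, 64))
  on <- measureImage(spec$rgb, spec$roiset, preprocessConfig())
  off <- measureImage(spec$rgb, spec$roiset,
                      preprocessConfig(enabled = FALSE))
  expect_equal(on$mean_es, off$mean_es)
  expect_equal(on$n_valid, off$n_valid)
  expect_equal(on$n_excluded, 0L)
})

test_that("summary CSV is wide, one row per image, with empty gaps", {
  rows <- rbind(
    data.frame(image_id = "a", region = c("face", "thorax_dorsal",
                                          "head_dorsal"),
               mean_es = c(1.5, 2.5, 3.5), sd_es = c(0.1, 0.2, 0.3),
               n_valid = c(10L, 20L, 30L)),
    data.frame(image_id = "b", region = c("face", "thorax_dorsal"),
               mean_es = c(4.123456, 5.5), sd_es = c(0.4, 0.5),
               n_valid = c(40L, 50L)))
  f <- file.path(tempdir(), "summaries.csv")
  writeSummariesCsv(rows, f)
  back <- read.csv(f)
  expect_equal(nrow(back), 2)
  expect_equal(back$image_id, c("a", "b"))
  expect_true(all(c("face_mean", "face_sd", "face_n_valid",
                    "head_dorsal_mean") %in% names(back)))
  expect_true(is.na(back$head_dorsal_mean[2]))  # region absent on image b
  expect_equal(back$face_mean, c(1.5, 4.123456), tolerance = 1e-6)
})
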