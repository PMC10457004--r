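test_that("component labeling agrees with a brute-force flood fill", {
  set.seed(11)
  for (k in 1:5) {
    bin <- matrix(runif(400) < 0.35, 20, 20)
    for (conn in c(8L, 4L)) {
      lab <- labelComponents(bin, conn)
      oracle <- floodFillOracle(bin, conn)
      ## same partition (labels may be permuted)
      expect_identical(lab > 0L, oracle > 0L)
      expect_identical(max(lab), max(oracle))
      for (g in seq_len(max(lab)))
        expect_identical(length(unique(oracle[lab == g])), 1L)
    }
  }
})

test_that("ROI thresholding is boundary-inclusive at 62.5% of Amax", {
  vals <- matrix(0, 64, 64)
  vals[30, 30] <- 0.8          # Amax
  vals[40, 40] <- 0.5          # exactly 0.625 * 0.8 -> included
  vals[20, 20] <- 0.499        # just below -> excluded
  img <- makeTestImage(vals)
  comp <- extractCandidateROIs(img)
  expect_length(comp, 2L)
  pix <- do.call(rbind, comp)
  expect_true(any(pix[, 1L] == 40 & pix[, 2L] == 40))
  expect_false(any(pix[, 1L] == 20 & pix[, 2L] == 20))

  ## all-zero image has no candidates
  expect_length(extractCandidateROIs(makeTestImage(matrix(0, 64, 64))), 0L)
})

test_that("two blobs separated by sub-threshold pixels form two components", {
  vals <- matrix(0, 64, 64)
  vals <- paintDisk(vals, -0.4, -0.3, 0.12, 1)
  vals <- paintDisk(vals, 0.4, -0.3, 0.12, 1)
  vals[abs(vals) < 0.5] <- 0.1    # sub-threshold background
  img <- makeTestImage(vals)
  expect_length(extractCandidateROIs(img), 2L)
})

test_that("boundary, axis-crossing and small-target exclusions apply", {
  ## blob touching the mask rim
  vals <- paintDisk(matrix(0, 64, 64), 0.9, 0.0, 0.15, 1)
  img <- makeTestImage(vals)
  expect_length(filterEffectiveROIs(extractCandidateROIs(img), img), 0L)

  ## blob crossed by the vertical axis
  vals <- paintDisk(matrix(0, 64, 64), 0.0, 0.3, 0.2, 1)
  img <- makeTestImage(vals)
  expect_length(filterEffectiveROIs(extractCandidateROIs(img), img), 0L)

  ## small target: 10 px in a ~3200 px domain is ~0.3% < 0.85%
  vals <- matrix(0, 64, 64)
  vals[30:34, 20:21] <- 1
  img <- makeTestImage(vals)
  comp <- extractCandidateROIs(img)
  expect_length(comp, 1L)
  expect_identical(nrow(comp[[1L]]), 10L)
  expect_length(filterEffectiveROIs(comp, img), 0L)

  ## two clean off-axis blobs of ~2% each survive with correct sides
  vals <- matrix(0, 64, 64)
  vals <- paintDisk(vals, -0.45, -0.35, 0.16, 1)
  vals <- paintDisk(vals, 0.45, -0.35, 0.16, 1)
  img <- makeTestImage(vals)
  rois <- filterEffectiveROIs(extractCandidateROIs(img), img)
  expect_length(rois, 2L)
  expect_setequal(vapply(rois, `[[`, "", "side"), c("left", "right"))
  for (r in rois) {
    expect_gte(r$area_px / sum(imageMask(img)), 0.0085)
    expect_true(all(r$barycenter >= 0))
  }
})

test_that("per-side features follow their definitions", {
  ## left ROI of known size: AR = area / in-mask pixels
  vals <- paintDisk(matrix(0, 64, 64), -0.45, 0.2, 0.15, 1)
  img <- makeTestImage(vals)
  rois <- filterEffectiveROIs(extractCandidateROIs(img), img)
  expect_length(rois, 1L)
  sl <- sideFeatures(img, rois, "left")
  expect_equal(sl$ar_roi, rois[[1L]]$area_px / sum(imageMask(img)))
  expect_equal(sl$mvrrc, 1)
  expect_false(sl$mirrored_fallback)

  ## empty right side: AR 0, intensity from the mirrored footprint
  sr <- sideFeatures(img, rois, "right")
  expect_identical(sr$ar_roi, 0)
  expect_true(sr$mirrored_fallback)
  ## direct average oracle over the mirrored pixels
  mirror <- cbind(rois[[1L]]$pixels[, 1L], 65L - rois[[1L]]$pixels[, 2L])
  expect_equal(sr$mvrrc, mean(abs(imageValues(img)[mirror])))

  ## no ROI at all: everything zero
  z <- makeTestImage(matrix(0, 64, 64))
  s0 <- sideFeatures(z, list(), "left")
  expect_identical(s0$ar_roi, 0)
  expect_identical(s0$mvrrc, 0)
  expect_false(s0$mirrored_fallback)
})

test_that("mvrrc uses the ROI holding the side's maximum absolute value", {
  vals <- matrix(0, 64, 64)
  vals <- paintDisk(vals, -0.5, 0.35, 0.1, 0.8)   # weaker left blob
  vals <- paintDisk(vals, -0.45, -0.3, 0.1, 1.0)  # stronger left blob
  img <- makeTestImage(vals)
  rois <- filterEffectiveROIs(extractCandidateROIs(img), img)
  expect_length(Filter(function(r) r$side == "left", rois), 2L)
  sl <- sideFeatures(img, rois, "left")
  expect_equal(sl$mvrrc, 1.0)
  ## non-fallback intensities live inside the threshold band
  expect_gte(sl$mvrrc, 0.625 * amax(img))
  expect_lte(sl$mvrrc, amax(img))
})

test_that("flipping the image left-right swaps the side features exactly", {
  set.seed(21)
  vals <- matrix(0, 64, 64)
  vals <- paintDisk(vals, -0.42, 0.25, 0.14, 0.9)
  vals <- paintDisk(vals, 0.5, -0.4, 0.12, -1)
  img <- makeTestImage(vals)
  fl <- makeTestImage(vals[, rev(seq_len(64L))])
  r1 <- filterEffectiveROIs(extractCandidateROIs(img), img)
  r2 <- filterEffectiveROIs(extractCandidateROIs(fl), fl)
  for (side in c("left", "right")) {
    a <- sideFeatures(img, r1, side)
    b <- sideFeatures(fl, r2, oppositeSide(side))
    expect_equal(a$ar_roi, b$ar_roi)
    expect_equal(a$mvrrc, b$mvrrc)
    expect_identical(a$mirrored_fallback, b$mirrored_fallback)
  }
})

test_that("side area ratios are bounded by the thresholded fraction", {
  set.seed(33)
  vals <- matrix(0, 64, 64)
  vals <- paintDisk(vals, -0.4, 0.1, 0.2, 1)
  vals <- paintDisk(vals, 0.45, -0.2, 0.15, -0.9)
  vals <- vals + matrix(rnorm(64 * 64, 0, 0.02), 64, 64)
  img <- makeTestImage(vals)
  rois <- filterEffectiveROIs(extractCandidateROIs(img), img)
  arl <- sideFeatures(img, rois, "left")$ar_roi
  arr <- sideFeatures(img, rois, "right")$ar_roi
  thr_frac <- sum(abs(imageValues(img)[imageMask(img)]) >=
                    0.625 * amax(img)) / sum(imageMask(img))
  expect_lte(arl + arr, thr_frac + 1e-12)
  expect_lte(thr_frac, 1)
})
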