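# Micrograph loading, segmentation, the sagittal gate and calibrated
# measurement.

test_that("micrographs load losslessly and RGB collapses to channel mean", {
  # 16-bit TIFF round-trips to within one sample step
  f <- tempfile(fileext = ".tif")
  set.seed(1)
  m <- matrix(runif(64 * 64), 64, 64)
  EBImage::writeImage(EBImage::Image(m), f, type = "tiff",
                      bits.per.sample = 16)
  mg <- loadMicrograph(f, SCALE)
  expect_s4_class(mg, "Micrograph")
  expect_equal(dim(mg), c(64, 64))
  expect_equal(pixelsPerMicron(mg), SCALE)
  expect_lt(max(abs(intensities(mg) - m)), 1 / 65535)

  # 8-bit PNG round-trips to within one 8-bit step
  fp <- tempfile(fileext = ".png")
  EBImage::writeImage(EBImage::Image(m), fp, type = "png")
  expect_lt(max(abs(intensities(loadMicrograph(fp)) - m)), 1 / 255)

  # RGB: luminance = plain channel mean
  frgb <- tempfile(fileext = ".png")
  arr <- array(runif(32 * 32 * 3), c(32, 32, 3))
  EBImage::writeImage(EBImage::Image(arr, colormode = "Color"), frgb,
                      type = "png")
  mg2 <- loadMicrograph(frgb)
  expect_equal(dim(mg2), c(32, 32))
  expect_lt(max(abs(intensities(mg2) - apply(arr, c(1, 2), mean))),
            1 / 255)

  # unreadable input
  bad <- tempfile(fileext = ".png")
  writeLines("not an image", bad)
  expect_error(loadMicrograph(bad), "cannot read image")
  expect_error(loadMicrograph(tempfile(fileext = ".png")), "not found")
})

test_that("segmentation finds disjoint ellipses, excludes border contacts,
           and merges overlapping blobs per 8-connectivity", {
  img <- matrix(0.9, 300, 300)
  centers <- list(c(50, 60), c(60, 200), c(150, 100), c(230, 230),
                  c(250, 60))
  for (ct in centers) {
    e <- rasterEllipse(300, 300, ct[1], ct[2], 30, 14, pi / 5)
    img[e < 0.5] <- 0.1
  }
  regs <- segmentObjects(Micrograph(img, SCALE), 1, 50)
  expect_equal(length(regs), 5L)
  expect_true(all(!regionFeatures(regs)$touches_border))
  # labels follow raster order and are 1..k
  expect_equal(regionFeatures(regs)$label, 1:5)

  # clip one ellipse by the border -> one fewer region
  img2 <- img
  e <- rasterEllipse(300, 300, 2, 150, 30, 14, 0)
  img2[e < 0.5] <- 0.1
  expect_equal(length(segmentObjects(Micrograph(img2, SCALE), 1, 50)), 5L)
  img3 <- matrix(0.9, 300, 300)
  e1 <- rasterEllipse(300, 300, 3, 150, 30, 14, 0)
  img3[e1 < 0.5] <- 0.1
  e2 <- rasterEllipse(300, 300, 150, 150, 30, 14, 0)
  img3[e2 < 0.5] <- 0.1
  expect_equal(length(segmentObjects(Micrograph(img3, SCALE), 1, 50)), 1L)

  # two overlapping ellipses form one connected component; count matches
  # an independent flood-fill oracle on the same mask
  img4 <- matrix(0.9, 200, 200)
  ea <- rasterEllipse(200, 200, 100, 90, 30, 14, 0)
  eb <- rasterEllipse(200, 200, 100, 130, 30, 14, pi / 2)
  img4[ea < 0.5 | eb < 0.5] <- 0.1
  regs4 <- segmentObjects(Micrograph(img4, SCALE), 1, 100)
  expect_equal(length(regs4), floodCount(img4 < 0.5)$n)
  expect_equal(length(regs4), 1L)

  # blank image: empty result, no error
  expect_equal(length(segmentObjects(Micrograph(matrix(0.5, 50, 50),
                                                SCALE), 1, 50)), 0L)
})

test_that("moment-equivalent ellipse axes agree with the EBImage oracle", {
  img <- rasterEllipse(160, 160, 80.3, 79.6, 34.78, 15.81, 0.4)
  regs <- segmentObjects(Micrograph(img, SCALE), 1, 50)
  f <- regionFeatures(regs)
  lab <- EBImage::bwlabel(img < 0.5)
  mom <- EBImage::computeFeatures.moment(lab)
  # the two routes differ only in the single-pixel variance correction
  expect_equal(f$major_axis_px, mom[1, "m.majoraxis"], tolerance = 2e-3,
               ignore_attr = TRUE)
  minor_ebi <- mom[1, "m.majoraxis"] *
    sqrt(1 - mom[1, "m.eccentricity"]^2)
  expect_equal(f$minor_axis_px, unname(minor_ebi), tolerance = 2e-3)
})

test_that("sagittal gate accepts prototype ellipses and rejects clumps
           and near-circles", {
  # clean ellipse, aspect 2.2
  img <- rasterEllipse(120, 120, 60, 60, 33, 15, 0.7)
  regs <- segmentObjects(Micrograph(img, SCALE), 1, 50)
  expect_true(classifySagittal(regs))

  # dumbbell from two crossed ellipses: low solidity
  img2 <- matrix(0.9, 200, 200)
  ea <- rasterEllipse(200, 200, 100, 85, 32, 13, 0)
  eb <- rasterEllipse(200, 200, 100, 125, 32, 13, pi / 2)
  img2[ea < 0.5 | eb < 0.5] <- 0.1
  regs2 <- segmentObjects(Micrograph(img2, SCALE), 1, 100)
  expect_false(classifySagittal(regs2))
  expect_lt(regionFeatures(regs2)$solidity, 0.9)

  # near-circular region, aspect ~1.05: below the default aspect floor
  img3 <- rasterEllipse(120, 120, 60, 60, 21, 20, 0)
  regs3 <- segmentObjects(Micrograph(img3, SCALE), 1, 50)
  expect_false(classifySagittal(regs3))
  asp <- regionFeatures(regs3)$major_axis_px /
    regionFeatures(regs3)$minor_axis_px
  expect_lt(asp, 1.2)
})

test_that("conidium measurement is calibrated: analytic ellipse, identity
           circle, scale invariance, calibration linearity", {
  # semi-axes 34.78 x 15.81 px at the working scale
  img <- rasterEllipse(160, 160, 80, 80, 34.78, 15.81, 0.3)
  regs <- segmentObjects(Micrograph(img, SCALE), 1, 50)
  m <- measureConidia(regs)
  expect_equal(m$length_um, 2 * 34.78 / SCALE, tolerance = 0.02)
  expect_equal(m$width_um, 2 * 15.81 / SCALE, tolerance = 0.02)
  expect_equal(m$area_um2, pi * 34.78 * 15.81 / SCALE^2, tolerance = 0.02)
  # bounding-box invariant
  expect_true(m$area_um2 <= m$length_um * m$width_um)

  # calibration linearity: area_um2 * s^2 recovers the pixel count
  expect_equal(m$area_um2 * SCALE^2, regionFeatures(regs)$area_px + 0,
               tolerance = 1e-12)

  # a circle of diameter s pixels measures 1.00 um in both axes
  imgc <- rasterEllipse(80, 80, 40, 40, SCALE / 2, SCALE / 2, 0)
  regc <- segmentObjects(Micrograph(imgc, SCALE), 0.1, 50)
  mc <- measureConidia(regc, sagittal_only = FALSE)
  expect_equal(mc$length_um, 1, tolerance = 0.02)
  expect_equal(mc$width_um, 1, tolerance = 0.02)

  # 2x upsampling with doubled calibration leaves um values unchanged
  img2 <- rasterEllipse(320, 320, 160, 160, 2 * 34.78, 2 * 15.81, 0.3)
  m2 <- measureConidia(segmentObjects(Micrograph(img2, 2 * SCALE), 1, 50))
  expect_equal(m2$length_um, m$length_um, tolerance = 0.02)
  expect_equal(m2$width_um, m$width_um, tolerance = 0.02)
  expect_equal(m2$area_um2, m$area_um2, tolerance = 0.02)
})

test_that("axis estimates are rotation-robust to < 3%", {
  base <- NULL
  for (k in 0:11) {
    th <- k * 15 * pi / 180
    img <- rasterEllipse(180, 180, 90.2, 89.7, 34.78, 15.81, th)
    m <- measureConidia(segmentObjects(Micrograph(img, SCALE), 1, 50),
                        sagittal_only = FALSE)
    expect_equal(m$length_um, 2 * 34.78 / SCALE, tolerance = 0.03)
    expect_equal(m$width_um, 2 * 15.81 / SCALE, tolerance = 0.03)
  }
})

test_that("trait summaries report mean, n-1 SD, range and count", {
  s1 <- summarizeTraits(c(4, 4, 4), "x")
  expect_equal(unlist(s1[, c("mean", "sd", "min", "max", "n")]),
               c(mean = 4, sd = 0, min = 4, max = 4, n = 3))
  s2 <- summarizeTraits(c(3, 5), "x")
  expect_equal(s2$mean, 4)
  expect_equal(s2$sd, sqrt(2), tolerance = 1e-12)
  # 3 replicates x 10 structures feeding one isolate summary
  vals <- rnorm(30, 4.4, 0.4)
  expect_equal(summarizeTraits(vals, "conidium_length_um")$n, 30)
  expect_error(summarizeTraits(numeric(), "x"), "empty")
})
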