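test_that("shape descriptors are exact on squares and disks", {
  bin <- matrix(FALSE, 14, 14); bin[3:12, 3:12] <- TRUE
  f <- areashape_features(bin)
  expect_equal(unname(f["Area"]), 100)
  expect_equal(unname(f["Perimeter"]), 36)
  expect_equal(unname(f["Extent"]), 1)
  expect_equal(unname(f["EulerNumber"]), 1)
  expect_equal(unname(f["Solidity"]), 1)
  expect_equal(unname(f["BoundingBoxWidth"]), 10)
  expect_equal(unname(f["CenterRow"]), 6.5)   # 0-based centroid of rows 3:12

  d <- disk_mask(20, n = 50)
  fd <- areashape_features(d)
  expect_gt(unname(fd["FormFactor"]), 0.9)
  expect_lt(unname(fd["FormFactor"]), 1.05)
  expect_lt(unname(fd["Eccentricity"]), 0.2)
  expect_equal(unname(fd["Compactness"]), 1, tolerance = 0.05)
  expect_equal(unname(fd["EquivalentDiameter"]), 2 * sqrt(sum(d) / pi))
  expect_equal(unname(fd["MaxFeretDiameter"]), 40, tolerance = 0.06)
  expect_equal(unname(fd["MinFeretDiameter"]), 40, tolerance = 0.06)
  expect_equal(unname(fd["MaximumRadius"]), 20, tolerance = 0.1)

  # a ring has Euler number 0
  ring <- disk_mask(8, n = 24) & !disk_mask(4, n = 24)
  expect_equal(unname(areashape_features(ring)["EulerNumber"]), 0)

  expect_error(areashape_features(matrix(FALSE, 4, 4)), "empty")
})

test_that("area and centroid agree with the per-pixel oracle on scenes", {
  sc <- small_scene(3, n_cells = 5L)
  ora <- oracle_features(sc, mask = "cells")
  H <- nrow(sc$cells)
  for (k in seq_len(nrow(ora))) {
    bin <- sc$cells == ora$object_id[k]
    f <- areashape_features(bin)
    expect_equal(unname(f["Area"]), ora$Area[k])
    expect_equal(unname(f["CenterRow"]), ora$CentroidRow[k])
    expect_equal(unname(f["CenterCol"]), ora$CentroidCol[k])
  }
})

test_that("shape features are translation invariant", {
  sc <- small_scene(19, n_cells = 4L, size = 160L)
  id <- 2L
  bin <- sc$cells == id
  shifted <- matrix(FALSE, nrow(bin) + 7L, ncol(bin) + 11L)
  shifted[8:(nrow(bin) + 7L), 12:(ncol(bin) + 11L)] <- bin
  f1 <- areashape_features(bin)
  f2 <- areashape_features(shifted)
  loc <- c("BoundingBoxMinRow", "BoundingBoxMinCol", "CenterRow", "CenterCol")
  expect_equal(f1[setdiff(names(f1), loc)], f2[setdiff(names(f2), loc)])
  expect_equal(unname(f2["CenterRow"] - f1["CenterRow"]), 7)
})

test_that("Zernike magnitudes match numerical integration and symmetry", {
  d <- disk_mask(15, n = 40)
  z <- zernike_magnitudes(d, degree = 9)
  expect_equal(length(z), 30L)
  # solid disk: Z(0,0) from direct numerical integration; n >= 1 near zero
  zo <- zernike_oracle(d, 9)
  expect_equal(unname(z), zo, tolerance = 1e-3)
  expect_lt(max(z[-1]), 0.05)

  # centered rectangle: 180-degree symmetry kills odd m
  rect <- matrix(FALSE, 30, 30); rect[9:22, 6:25] <- TRUE
  zr <- zernike_magnitudes(rect, degree = 9)
  odd_m <- grepl("_([13579])$", names(zr))
  expect_lt(max(zr[odd_m]), 1e-2)

  # rotation by 90 degrees leaves magnitudes unchanged
  blob <- matrix(FALSE, 24, 24)
  blob[5:18, 7:14] <- TRUE; blob[8:11, 15:20] <- TRUE
  z1 <- zernike_magnitudes(blob, 9)
  z2 <- zernike_magnitudes(t(blob[nrow(blob):1, ]), 9)
  expect_equal(z1, z2, tolerance = 1e-6)

  # irregular object against the integration oracle
  expect_equal(unname(zernike_magnitudes(blob, 6)),
               zernike_oracle(blob, 6), tolerance = 1e-3)
})
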