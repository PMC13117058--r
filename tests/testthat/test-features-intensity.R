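test_that("intensity features match closed forms", {
  bin <- matrix(FALSE, 8, 8); bin[3:5, 3:6] <- TRUE
  ch <- matrix(0, 8, 8); ch[bin] <- 7
  f <- intensity_features(ch, bin)
  expect_equal(unname(f["IntegratedIntensity"]), 7 * 12)
  expect_equal(unname(f["MeanIntensity"]), 7)
  expect_equal(unname(f["StdIntensity"]), 0)
  expect_equal(unname(f["MassDisplacement"]), 0)

  bin2 <- matrix(FALSE, 4, 4); bin2[2, 2:3] <- TRUE
  ch2 <- matrix(0, 4, 4); ch2[2, 2] <- 10; ch2[2, 3] <- 20
  f2 <- intensity_features(ch2, bin2)
  expect_equal(unname(f2[c("MeanIntensity", "MinIntensity", "MaxIntensity",
                           "IntegratedIntensity")]),
               c(15, 10, 20, 30))
  # mass moves towards the bright pixel: |20/30 - 0.5| along the column axis
  expect_equal(unname(f2["MassDisplacement"]), abs(20 / 30 - 0.5))
  expect_error(intensity_features(ch2, matrix(FALSE, 4, 4)), "empty")
})

test_that("integrated intensity equals mean times area everywhere", {
  sc <- small_scene(23, n_cells = 5L)
  dna <- get_channel(sc$stack, "DNA")
  for (id in sort(unique(sc$cells[sc$cells > 0L]))) {
    f <- intensity_features(dna, sc$cells == id)
    expect_equal(unname(f["IntegratedIntensity"]),
                 unname(f["MeanIntensity"]) * sum(sc$cells == id))
  }
  # and both agree exactly with the naive per-pixel oracle
  ora <- oracle_features(sc, mask = "cells")
  for (k in seq_len(nrow(ora))) {
    f <- intensity_features(dna, sc$cells == ora$object_id[k])
    expect_identical(unname(f["IntegratedIntensity"]),
                     ora$IntegratedIntensity[k])
    expect_identical(unname(f["MaxIntensity"]), ora$MaxIntensity[k])
  }
})

test_that("location features report centroid, center of mass and maxima", {
  bin <- matrix(FALSE, 14, 14); bin[1:10, 1:10] <- TRUE
  ch <- matrix(1, 14, 14)
  f <- location_features(list(DNA = ch), bin)
  expect_equal(unname(f["Location_Center_X"]), 4.5)
  expect_equal(unname(f["Location_Center_Y"]), 4.5)
  # uniform intensity: center of mass equals the binary centroid
  expect_equal(unname(f["Location_CenterMassIntensity_X_DNA"]), 4.5)
  # single bright pixel at 0-based (row 2, col 7)
  ch2 <- matrix(0, 14, 14); ch2[3, 8] <- 5
  f2 <- location_features(list(DNA = ch2), bin)
  expect_equal(unname(f2[c("Location_MaxIntensity_Y_DNA",
                           "Location_MaxIntensity_X_DNA")]), c(2, 7))
  # tie broken by raster order (first occurrence)
  ch3 <- matrix(0, 14, 14); ch3[5, 9] <- 5; ch3[5, 2] <- 5; ch3[2, 9] <- 5
  f3 <- location_features(list(DNA = ch3), bin)
  expect_equal(unname(f3[c("Location_MaxIntensity_Y_DNA",
                           "Location_MaxIntensity_X_DNA")]), c(1, 8))
})

test_that("correlation features follow regression closed forms", {
  bin <- matrix(FALSE, 4, 4); bin[1, 1:4] <- TRUE
  a <- matrix(0, 4, 4); a[1, ] <- c(1, 2, 3, 4)
  b <- matrix(0, 4, 4); b[1, ] <- c(2, 4, 6, 8)
  f <- correlation_features(a, b, bin)
  expect_equal(unname(f["Correlation"]), 1)
  expect_equal(unname(f["Slope"]), 2)
  expect_equal(unname(f["SlopeSwapped"]), 0.5)

  fid <- correlation_features(a, a, bin)
  expect_equal(unname(fid[c("Correlation", "Slope", "Overlap", "K1", "K2")]),
               c(1, 1, 1, 1, 1))

  bneg <- matrix(0, 4, 4); bneg[1, ] <- -c(1, 2, 3, 4) + 10
  expect_equal(unname(correlation_features(a, bneg, bin)["Correlation"]), -1)

  # zero variance in either channel defines correlation as 0
  const <- matrix(3, 4, 4)
  expect_equal(unname(correlation_features(a, const, bin)["Correlation"]), 0)
  expect_error(correlation_features(a, b, matrix(FALSE, 4, 4)), "2 object")
})
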