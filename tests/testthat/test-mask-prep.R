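test_that("outline inversion labels enclosed interiors and drops background", {
  # all-zero outline: the single region touches the border and is removed
  expect_equal(max(outlines_to_instances(matrix(0L, 20, 20))), 0L)

  # one closed 12x12 square outline -> one instance of area 100
  o <- rect_outline(20, 20, 5, 16, 5, 16)
  lab <- outlines_to_instances(o)
  expect_equal(max(lab), 1L)
  expect_equal(sum(lab == 1L), 100L)

  # two disjoint closed circles -> two instances with flood-fill areas
  o2 <- matrix(0L, 40, 80)
  for (ang in seq(0, 2 * pi, length.out = 200)) {
    o2[round(20 + 9 * sin(ang)), round(20 + 9 * cos(ang))] <- 255L
    o2[round(20 + 12 * sin(ang)), round(55 + 12 * cos(ang))] <- 255L
  }
  lab2 <- outlines_to_instances(o2)
  expect_equal(max(lab2), 2L)
  oracle <- flood_fill_label(o2 == 0L)
  ids <- setdiff(sort(unique(as.vector(oracle))), 0L)
  interior_areas <- sort(Filter(function(a) a >= 15,
                                sapply(ids[-1], function(i) sum(oracle == i))))
  expect_equal(sort(as.vector(table(lab2[lab2 > 0]))),
               as.vector(interior_areas))

  expect_error(outlines_to_instances(matrix(3L, 5, 5)), "binary")
})

test_that("instance labels agree with a flood-fill oracle on random outlines", {
  set.seed(101)
  for (trial in 1:5) {
    o <- matrix(0L, 30, 30)
    for (k in 1:3) {
      r <- sample(3:12, 1); c <- sample(3:12, 1)
      o2 <- rect_outline(30, 30, r, r + sample(6:10, 1), c, c + sample(6:10, 1))
      o[o2 > 0] <- 255L
    }
    lab <- outlines_to_instances(o, min_area = 4L)
    oracle <- flood_fill_label(o == 0L)
    # every produced label must be exactly one oracle component
    for (id in setdiff(unique(as.vector(lab)), 0L)) {
      comp <- oracle[lab == id]
      expect_equal(length(unique(comp)), 1L)
      expect_equal(sum(lab == id), sum(oracle == comp[1]))
    }
  }
})

test_that("border restoration dilates without merging or shrinking", {
  expect_equal(restore_borders(matrix(0L, 10, 10)), matrix(0L, 10, 10))

  m1 <- matrix(0L, 9, 9); m1[5, 5] <- 1L
  expect_equal(sum(restore_borders(m1, radius = 1) == 1L), 9L)

  m2 <- matrix(0L, 20, 20); m2[6:15, 6:15] <- 1L
  expect_equal(sum(restore_borders(m2, radius = 1) == 1L), 144L)

  # two nearby instances: count preserved, no shrink, contested pixels to
  # the nearer instance
  m3 <- matrix(0L, 12, 22); m3[4:8, 3:7] <- 1L; m3[4:8, 11:15] <- 2L
  out <- restore_borders(m3, radius = 2)
  expect_equal(sort(unique(out[out > 0L])), c(1L, 2L))
  expect_true(all(out[m3 == 1L] == 1L))
  expect_true(all(out[m3 == 2L] == 2L))
  # column 10 (1-based) is 1 px from object 2, 3 px from object 1
  expect_true(all(out[4:8, 10] == 2L))
  # column 9 is equidistant (2 px each side): tie goes to the lower label
  expect_true(all(out[4:8, 9] == 1L))
})

test_that("center ROI cropping follows the floor offset rule", {
  big <- matrix(seq_len(1080L * 1080L) %% 7L, 1080, 1080)
  roi <- crop_center_roi(big, 960)
  expect_equal(dim(roi), c(960L, 960L))
  expect_identical(roi, big[61:1020, 61:1020])   # offset (60, 60)

  m <- matrix(1:121, 11, 11)
  expect_identical(crop_center_roi(m, 11), m)
  expect_identical(crop_center_roi(m, 10), m[1:10, 1:10])  # offset (0, 0)
  expect_error(crop_center_roi(m, 12), "exceeds")

  st <- channel_stack(array(0, c(16, 16, 2)), c("DNA", "RNA"))
  expect_equal(dim(crop_center_roi(st, 8)$pixels), c(8L, 8L, 2L))
})

test_that("outline round-trip recovers synthetic masks", {
  for (seed in c(2, 9)) {
    sc <- small_scene(seed)
    for (comp in c("cell", "nucleus")) {
      truth <- if (comp == "cell") sc$cells else sc$nuclei
      lab <- restore_borders(outlines_to_instances(sc$outlines[[comp]]))
      expect_equal(max(lab), max(truth))
      m <- match_instances(truth, lab, 0.5)
      expect_equal(m$fp + m$fn, 0L)
      expect_true(min(m$pairs$iou) >= 0.8)
    }
  }
})
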