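test_that("scene generation is seeded and respects requested populations", {
  p <- scene_params(size = 160L, n_cells = 6L)
  s1 <- generate_scene(p, seed = 4)
  s2 <- generate_scene(p, seed = 4)
  expect_identical(s1$stack$pixels, s2$stack$pixels)
  expect_identical(s1$cells, s2$cells)
  expect_identical(s1$confidence$cell$class_map, s2$confidence$cell$class_map)
  # a different seed gives a different scene
  expect_false(identical(generate_scene(p, seed = 5)$cells, s1$cells))
  # coordinate-specific streams differ
  sA <- generate_scene(p, 4, plate_coord("P1", "A", 1, 5))
  sB <- generate_scene(p, 4, plate_coord("P1", "A", 2, 5))
  expect_false(identical(sA$cells, sB$cells))

  # counts: no multinucleates or fragments by default
  sc <- small_scene(6, n_cells = 10L, size = 288L)
  expect_equal(max(sc$cells), 10L)
  expect_equal(max(sc$nuclei), 10L)
  expect_equal(sc$params$n_fragments_realized, 0L)
})

test_that("multinucleate fraction plants exactly the requested cells", {
  sc <- generate_scene(scene_params(size = 288L, n_cells = 10L,
                                    multi_nucleate_fraction = 0.2,
                                    noise = "none"), seed = 8)
  expect_equal(max(sc$cells), 10L)
  owners <- cellpaintr:::centroid_owners(sc$cells, sc$nuclei)
  counts <- table(owners[owners > 0])
  expect_equal(sum(counts == 2L), 2L)
  expect_equal(sum(counts), max(sc$nuclei))
  # every nucleus lies entirely within its parent cell
  expect_true(all(sc$cells[sc$nuclei > 0L] > 0L))
  for (nid in 1:max(sc$nuclei))
    expect_equal(length(unique(sc$cells[sc$nuclei == nid])), 1L)
})

test_that("channel rendering reflects compartment staining", {
  sc <- small_scene(14, n_cells = 5L)
  dna <- get_channel(sc$stack, "DNA")
  rna <- get_channel(sc$stack, "RNA")
  nuc <- sc$nuclei > 0L
  cyto <- sc$cells > 0L & !nuc
  bg <- sc$cells == 0L
  expect_gt(mean(dna[nuc]), 10 * mean(dna[cyto]))
  expect_gt(mean(rna[cyto]), 5 * mean(rna[bg]))
  expect_true(all(sc$stack$pixels >= 0 & sc$stack$pixels <= 65535))
})

test_that("oracle features equal the fast paths on cells and nuclei", {
  sc <- small_scene(25, n_cells = 4L, size = 160L)
  dna <- get_channel(sc$stack, "DNA")
  rna <- get_channel(sc$stack, "RNA")
  for (mk in c("cells", "nuclei")) {
    ora <- oracle_features(sc, mask = mk)
    m <- sc[[mk]]
    for (k in seq_len(nrow(ora))) {
      bin <- m == ora$object_id[k]
      iv <- intensity_features(dna, bin)
      expect_identical(unname(iv["IntegratedIntensity"]),
                       ora$IntegratedIntensity[k])
      expect_equal(unname(iv["MeanIntensity"]), ora$MeanIntensity[k])
      expect_identical(unname(iv["MaxIntensity"]), ora$MaxIntensity[k])
      expect_equal(unname(areashape_features(bin)["Area"]), ora$Area[k])
      cf <- correlation_features(dna, rna, bin)
      expect_equal(unname(cf["Correlation"]), ora$PearsonCorrelation[k],
                   tolerance = 1e-12)
    }
  }
  expect_error(oracle_features(sc, subset = "Fourier"), "unsupported")
})

test_that("pearson oracle matches the closed form on a 2-pixel object", {
  sc <- small_scene(1, n_cells = 1L, size = 96L)
  # carve a 2-pixel object into the mask
  m <- matrix(0L, 96, 96); m[10, 10:11] <- 99L
  sc2 <- sc; sc2$cells <- m
  dna <- get_channel(sc$stack, "DNA"); rna <- get_channel(sc$stack, "RNA")
  a <- dna[10, 10:11]; b <- rna[10, 10:11]
  expected <- if (diff(a) == 0 || diff(b) == 0) 0 else
    sign(diff(a)) * sign(diff(b))
  ora <- oracle_features(sc2, subset = "PearsonCorrelation", mask = "cells")
  expect_equal(ora$PearsonCorrelation, expected)
})

test_that("scenes round-trip through the on-disk dataset layout", {
  dir <- withr::local_tempdir()
  sc <- small_scene(9, n_cells = 3L, size = 128L)
  sc$coord <- plate_coord("SYN01", "B", 3, 5)
  sd <- write_scene(sc, dir)
  expect_true(file.exists(file.path(sd, "DNA.tiff")))
  stack <- read_channel_stack(c(DNA = file.path(sd, "DNA.tiff")))
  expect_identical(stack$pixels[, , 1], get_channel(sc$stack, "DNA"))
  expect_identical(read_mask(file.path(sd, "truth_cells.tiff")), sc$cells)
  out <- png::readPNG(file.path(sd, "outlines_cell.png"))
  expect_identical(round(out * 255), sc$outlines$cell + 0)
})
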