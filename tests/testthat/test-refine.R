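test_that("multi-nucleated cells split by nearest nucleus centroid", {
  # one nucleus: identity
  cells <- matrix(0L, 10, 12); cells[3:8, 2:11] <- 1L
  nuc1 <- matrix(0L, 10, 12); nuc1[5:6, 5:6] <- 1L
  expect_identical(split_multinucleated(cells, nuc1), cells)

  # rectangle over columns 0-9 (0-based) with centroids at columns 2 and 7:
  # columns 0-4 one label, 5-9 the other
  nuc2 <- matrix(0L, 10, 12); nuc2[5:6, 3] <- 1L; nuc2[5:6, 8] <- 2L
  sp <- split_multinucleated(cells, nuc2)
  expect_equal(sort(unique(sp[sp > 0L])), c(2L, 3L))   # fresh labels above max
  # 0-based columns 1-4 are nearer centroid col 2; columns 5-10 nearer col 7
  expect_equal(unique(as.vector(sp[3:8, 2:5])), 2L)
  expect_equal(unique(as.vector(sp[3:8, 6:11])), 3L)

  # conservation: the split parts partition the original pixel set
  expect_identical(sp > 0L, cells > 0L)

  # nuclei mask untouched, idempotence
  expect_identical(split_multinucleated(sp, nuc2), sp)
  expect_error(split_multinucleated(cells, matrix(0L, 5, 5)), "mismatch")
})

test_that("split leaves at most one nucleus centroid per cell on scenes", {
  sc <- small_scene(21, n_cells = 8L, multi_nucleate_fraction = 0.25)
  merged <- sc$cells   # truth already contains 2-nucleus cells
  out <- split_multinucleated(merged, sc$nuclei)
  owners <- cellpaintr:::centroid_owners(out, sc$nuclei)
  owners <- owners[owners > 0]
  expect_true(all(table(owners) <= 1L))
  expect_identical(out > 0L, merged > 0L)
})

test_that("anucleate fragments are removed or merged by border evidence", {
  border <- matrix(0, 20, 30)
  # nucleated small cell: unchanged
  cells <- matrix(0L, 20, 30); cells[3:5, 3:5] <- 1L
  nuc <- matrix(0L, 20, 30); nuc[4, 4] <- 1L
  expect_identical(merge_or_remove_fragments(cells, nuc, border, 100), cells)

  # isolated anucleate fragment below min_area: removed
  cells2 <- cells; cells2[14:17, 20:24] <- 2L
  out2 <- merge_or_remove_fragments(cells2, nuc, border, 100)
  expect_equal(sum(out2 == 2L), 0L)
  expect_identical(out2 == 1L, cells2 == 1L)

  # fragment touching cells A and B: merged into the side with lower mean
  # border confidence
  cells3 <- matrix(0L, 12, 30)
  cells3[3:10, 3:10] <- 1L     # A
  cells3[3:10, 15:22] <- 2L    # B
  cells3[5:8, 11:14] <- 3L     # fragment bridging both
  nuc3 <- matrix(0L, 12, 30); nuc3[6, 6] <- 1L; nuc3[6, 18] <- 2L
  bmap <- matrix(0, 12, 30)
  bmap[, 11] <- 0.1            # quiet interface towards A
  bmap[, 14] <- 0.9            # strong border evidence towards B
  out3 <- merge_or_remove_fragments(cells3, nuc3, bmap, min_area = 50)
  expect_equal(sum(out3 == 3L), 0L)
  expect_true(all(out3[5:8, 11:14] == 1L))
  # flipped evidence merges into B
  bmap2 <- matrix(0, 12, 30); bmap2[, 11] <- 0.9; bmap2[, 14] <- 0.1
  out3b <- merge_or_remove_fragments(cells3, nuc3, bmap2, min_area = 50)
  expect_true(all(out3b[5:8, 11:14] == 2L))

  # idempotence at fixed min_area
  expect_identical(merge_or_remove_fragments(out3, nuc3, bmap, min_area = 50),
                   out3)
  expect_error(merge_or_remove_fragments(cells3, nuc3, bmap, min_area = 0),
               "positive")
})

test_that("no anucleate cell below min_area survives refinement", {
  sc <- small_scene(31, n_cells = 7L, fragment_fraction = 0.3)
  pred <- sc$cells_with_artifacts
  min_area <- 0.4 * median(table(sc$cells[sc$cells > 0]))
  out <- merge_or_remove_fragments(pred, sc$nuclei,
                                   sc$confidence$cell$border_map,
                                   min_area = min_area)
  owners <- cellpaintr:::centroid_owners(out, sc$nuclei)
  nucleated <- unique(owners[owners > 0])
  areas <- table(out[out > 0L])
  anucleate <- setdiff(as.integer(names(areas)), nucleated)
  expect_true(all(areas[as.character(anucleate)] >= min_area))
  # foreground only changed by deleting noise fragments
  expect_true(all(out[sc$cells > 0L] > 0L))
})

test_that("cytoplasm derivation is cell minus owned nucleus", {
  # nucleus identical to cell -> empty cytoplasm
  cells <- matrix(0L, 10, 10); cells[3:6, 3:6] <- 1L
  expect_equal(sum(derive_cytoplasm(cells, cells) > 0L), 0L)

  # disk cell area ~100 with concentric nucleus: exact pixel arithmetic
  d <- disk_mask(5.6, n = 20)
  cells2 <- matrix(0L, 20, 20); cells2[d] <- 1L
  dn <- disk_mask(3, n = 20)
  nuc2 <- matrix(0L, 20, 20); nuc2[dn] <- 1L
  cyt <- derive_cytoplasm(cells2, nuc2)
  expect_equal(sum(cyt == 1L), sum(d) - sum(dn))

  # additivity per object on a synthetic scene
  sc <- small_scene(17, n_cells = 6L)
  cyt2 <- derive_cytoplasm(sc$cells, sc$nuclei)
  nbc <- cellpaintr:::nuclei_by_cell(sc$cells, sc$nuclei)
  for (id in sort(unique(sc$cells[sc$cells > 0L])))
    expect_equal(sum(sc$cells == id),
                 sum(nbc == id) + sum(cyt2 == id))
})
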