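cat2 <- feature_catalog(channels = c("DNA", "RNA"),
                        compartments = c("cell", "nucleus"),
                        granularity_scales = 4L, radial_bins = 3L)

test_that("catalog column counts match the closed form across configurations", {
  configs <- list(
    feature_catalog(channels = c("DNA", "ER", "RNA", "AGP", "Mito")),
    cat2,
    feature_catalog(channels = "DNA", compartments = "nucleus",
                    zernike_degree = 4L, texture_offsets = c(1L, 3L)),
    feature_catalog(channels = c("DNA", "RNA", "ER"), radial_bins = 2L,
                    granularity_scales = 2L))
  for (cfg in configs)
    expect_equal(length(catalog_columns(cfg)), catalog_ncol(cfg))
  expect_equal(anyDuplicated(catalog_columns(configs[[1]])), 0L)
})

test_that("extraction produces one row per object and compartment", {
  sc <- small_scene(41, n_cells = 7L, size = 224L)
  tab <- extract_all(cat2, sc$stack, sc$cells, sc$nuclei,
                     coord = plate_coord("BR00116991", "A", 2, 5))
  expect_s3_class(tab, "feature_table")
  expect_equal(nrow(tab), 2L * max(sc$cells))
  expect_equal(feature_columns(tab), catalog_columns(cat2))
  expect_false(anyNA(tab))
  expect_equal(unique(tab$plate), "BR00116991")

  # empty masks: empty table with the full header
  e <- matrix(0L, 64, 64)
  empty_stack <- channel_stack(array(0, c(64, 64, 2)), c("DNA", "RNA"))
  tab0 <- extract_all(cat2, empty_stack, e, e)
  expect_equal(nrow(tab0), 0L)
  expect_equal(feature_columns(tab0), catalog_columns(cat2))

  # missing channel is reported
  expect_error(extract_all(feature_catalog(channels = c("DNA", "Mito")),
                           empty_stack, e, e), "Mito")
})

test_that("extraction is deterministic and fills empty compartments with zeros", {
  sc <- small_scene(43, n_cells = 4L, size = 160L)
  tab1 <- extract_all(cat2, sc$stack, sc$cells, sc$nuclei)
  tab2 <- extract_all(cat2, sc$stack, sc$cells, sc$nuclei)
  expect_identical(tab1, tab2)

  # remove one nucleus: that cell's nucleus row becomes all zeros
  nuk <- sc$nuclei
  gone <- sc$nuclei[which(sc$cells == 2L)[1]]
  gone <- max(nuk[sc$cells == 2L])          # nucleus owned by cell 2
  nuk[nuk == gone] <- 0L
  tab3 <- extract_all(cat2, sc$stack, sc$cells, nuk)
  row <- tab3[tab3$compartment == "nucleus" & tab3$object_id == 2L, ]
  expect_true(all(row[feature_columns(tab3)] == 0))
})

test_that("per-object features are invariant under whole-scene translation", {
  sc <- small_scene(47, n_cells = 3L, size = 128L)
  dr <- 6L; dc <- 9L
  shift <- function(m, fill = 0L) {
    out <- matrix(fill, nrow(m), ncol(m))
    out[(dr + 1):nrow(m), (dc + 1):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  px <- sc$stack$pixels
  px2 <- array(0, dim(px))
  for (k in seq_len(dim(px)[3])) px2[, , k] <- shift(px[, , k])
  st2 <- channel_stack(px2, sc$stack$channel_names)
  tabA <- extract_all(cat2, sc$stack, sc$cells, sc$nuclei)
  tabB <- extract_all(cat2, st2, shift(sc$cells), shift(sc$nuclei))
  loc_cols <- grep("^Location_|BoundingBoxMin|Center(Row|Col)",
                   feature_columns(tabA), value = TRUE)
  inv_cols <- setdiff(feature_columns(tabA), loc_cols)
  expect_equal(as.matrix(tabA[inv_cols]), as.matrix(tabB[inv_cols]),
               tolerance = 1e-9)
  expect_equal(tabB$Location_Center_Y - tabA$Location_Center_Y,
               rep(dr, nrow(tabA)))
})
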