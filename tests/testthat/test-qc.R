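make_table <- function(values, ids = seq_len(nrow(values))) {
  keys <- data.frame(plate = "P", well = "A01", site = 1L,
                     compartment = "cell", object_id = ids)
  feature_table(keys, values)
}

test_that("feature-table comparison reproduces hand-worked errors", {
  vals <- data.frame(AreaShape_Area = c(3, 1290.5),
                     Intensity_MeanIntensity_DNA = c(0.25, 0.5))
  tab <- make_table(vals)
  rep0 <- compare_feature_tables(tab, tab)
  expect_true(all(rep0$mse == 0))
  expect_true(all(rep0$mae == 0))

  # single feature, reference (0, 1), measured (0, 0.5)
  ref <- make_table(data.frame(Intensity_F = c(0, 1)))
  mea <- make_table(data.frame(Intensity_F = c(0, 0.5)))
  rep1 <- compare_feature_tables(mea, ref)
  overall <- rep1[rep1$group == "Overall", ]
  expect_equal(overall$mae, 0.25)
  expect_equal(overall$mse, 0.125)

  # zero-range reference feature: 0 where equal, 1 where different
  ref2 <- make_table(data.frame(Texture_F = c(2, 2)))
  mea2 <- make_table(data.frame(Texture_F = c(2, 7)))
  rep2 <- compare_feature_tables(mea2, ref2)
  expect_equal(rep2$mae[rep2$group == "Overall"], 0.5)

  # disjoint object keys are reported
  bad <- make_table(data.frame(Intensity_F = c(0, 1)), ids = c(7L, 8L))
  expect_error(compare_feature_tables(bad, ref), "keys")
  # column mismatch is reported by name
  expect_error(compare_feature_tables(mea2, ref), "Texture_F")
})

test_that("grouped errors satisfy mae^2 <= mse and pool into the overall row", {
  set.seed(33)
  vals <- as.data.frame(matrix(rnorm(40), 8, 5))
  names(vals) <- c("AreaShape_A", "AreaShape_B", "Intensity_A",
                   "Texture_A", "Texture_B")
  ref <- make_table(vals)
  mea <- make_table(vals + matrix(rnorm(40, sd = 0.3), 8, 5))
  rep <- compare_feature_tables(mea, ref)
  for (i in seq_len(nrow(rep)))
    expect_lte(rep$mae[i]^2, rep$mse[i] + 1e-12)
  expect_equal(rep$n_features[rep$group == "Overall"], 5L)
  expect_setequal(rep$group, c("AreaShape", "Intensity", "Texture", "Overall"))

  # pooled bounds make the comparison symmetric
  r1 <- compare_feature_tables(mea, ref, bounds = "pooled")
  r2 <- compare_feature_tables(ref, mea, bounds = "pooled")
  expect_equal(r1$mse, r2$mse)
  expect_equal(r1$mae, r2$mae)
})

test_that("prioritization keeps one representative per correlated block", {
  # two identical columns -> one retained
  t1 <- make_table(data.frame(Intensity_A = c(1, 2, 3, 4),
                              Intensity_B = c(2, 4, 6, 8)))
  expect_equal(length(prioritize_features(t1, 0.9)), 1L)

  # orthogonal columns -> all retained
  t2 <- make_table(data.frame(Intensity_A = c(1, 1, -1, -1),
                              Intensity_B = c(1, -1, 1, -1),
                              Intensity_C = c(1, -1, -1, 1)))
  expect_equal(length(prioritize_features(t2, 0.9)), 3L)

  # zero-variance features always dropped
  t3 <- make_table(data.frame(Intensity_A = c(1, 2, 3, 4),
                              Intensity_Const = c(5, 5, 5, 5)))
  expect_equal(prioritize_features(t3, 0.9), "Intensity_A")

  # 5 planted correlated blocks with seeded Gaussian data
  set.seed(123)
  n <- 60
  base <- matrix(rnorm(n * 5), n, 5)
  cols <- list()
  for (b in 1:5) for (j in 1:4)
    cols[[paste0("Intensity_B", b, "_", j)]] <-
      base[, b] * (2 - 0.1 * j) + rnorm(n, sd = 0.05)
  tab <- make_table(as.data.frame(cols))
  kept <- prioritize_features(tab, 0.9)
  expect_equal(length(kept), 5L)
  expect_equal(sort(unique(sub("_[0-9]+$", "", kept))),
               paste0("Intensity_B", 1:5))

  # invariant to object-row order
  perm <- sample(nrow(tab))
  tabp <- tab[perm, ]
  tabp$object_id <- seq_len(nrow(tabp))
  expect_equal(prioritize_features(tabp, 0.9), kept)
})
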