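test_that("Dice follows its definition and edge conventions", {
  lab <- toy_labels(12L)
  expect_equal(dice(lab, lab, 1L), 1)
  expect_equal(dice(lab, lab, 2L), 1)

  # disjoint placements of the same region
  rt <- toy_region_table(1L)
  a <- array(0L, c(6, 6, 6)); a[1:2, , ] <- 1L
  b <- array(0L, c(6, 6, 6)); b[5:6, , ] <- 1L
  la <- label_map(a, rt); lb <- label_map(b, rt)
  expect_equal(dice(la, lb, 1L), 0)

  # |A| = 4, |B| = 6, overlap 3 -> 0.6
  a2 <- array(0L, c(4, 4, 4)); a2[1:4, 1, 1] <- 1L
  b2 <- array(0L, c(4, 4, 4)); b2[2:4, 1, 1] <- 1L; b2[1:3, 2, 1] <- 1L
  expect_equal(dice(label_map(a2, rt), label_map(b2, rt), 1L), 0.6)

  # empty-region conventions and symmetry
  empty <- label_map(array(0L, c(6, 6, 6)), rt)
  expect_equal(dice(empty, empty, 1L), 1)
  expect_equal(dice(la, empty, 1L), 0)
  expect_equal(dice(la, lb, 1L), dice(lb, la, 1L))
})

test_that("global matching index aggregates region overlap and matches the voxel loop", {
  lab <- toy_labels(10L)
  expect_equal(global_index(lab, lab), 1)

  rt <- toy_region_table(3L)
  a <- random_label_map(8L, 1:3, rt, seed = 21)
  b <- random_label_map(8L, 1:3, rt, seed = 22)
  expect_equal(global_index(a, b), oracle_global_index(a, b, 1:3))
  expect_equal(global_index(a, b), global_index(b, a))

  # entirely disagreeing maps
  c1 <- label_map(array(1L, c(4, 4, 4)), rt)
  c2 <- label_map(array(2L, c(4, 4, 4)), rt)
  expect_equal(global_index(c1, c2), 0)

  # the per-region-mean variant stays within [min, max] of the Dice values
  per <- vapply(1:3, function(r) dice(a, b, r), 0)
  gm <- global_index(a, b, method = "mean")
  expect_gte(gm, min(per)); expect_lte(gm, max(per))
  agg <- global_index(a, b)
  expect_gte(agg, min(per)); expect_lte(agg, max(per))
})

test_that("confusion matrix is row-normalized and matches the double loop", {
  lab <- toy_labels(10L)
  C <- confusion_matrix(lab, lab)
  expect_equal(unname(diag(C)), rep(100, nrow(C)))
  expect_equal(unname(rowSums(C)), rep(100, nrow(C)))

  rt <- toy_region_table(3L)
  a <- random_label_map(6L, 1:3, rt, seed = 31)
  b <- random_label_map(6L, 1:3, rt, seed = 32)
  C2 <- confusion_matrix(a, b)
  expect_equal(unname(rowSums(C2)), rep(100, 4), tolerance = 1e-9)
  expect_equal(C2[, ], oracle_confusion(a, b, 0:3)[, ], tolerance = 1e-12)

  # empty reference region: zero row, flagged
  a3 <- a; a3$labels[a3$labels == 3L] <- 1L
  C3 <- confusion_matrix(label_map(a3$labels, rt), b)
  expect_equal(unname(C3["3", ]), rep(0, 4))
  expect_true(3L %in% attr(C3, "undefined_rows"))
})

test_that("bilateral merging folds 60 default regions into 35 and conserves voxels", {
  rt <- default_region_table()
  expect_equal(nrow(rt), 60L)
  expect_equal(sum(rt$hemisphere == "midline"), 10L)

  set.seed(77)
  lab <- label_map(array(sample(c(0L, rt$region_id), 12^3, replace = TRUE),
                         c(12, 12, 12)), rt)
  merged <- merge_bilateral(lab)
  expect_equal(nrow(merged$regions), 35L)
  expect_equal(sum(merged$labels != 0L), sum(lab$labels != 0L))
  # left and right voxels of one structure share a single id afterwards
  left_id <- rt$region_id[rt$name == "Thalamus (left)"]
  right_id <- rt$region_id[rt$name == "Thalamus (right)"]
  expect_equal(sum(merged$labels == min(left_id, right_id)),
               sum(lab$labels %in% c(left_id, right_id)))

  # midline-only maps pass through unchanged
  mid <- rt[rt$hemisphere == "midline", ]
  lab_mid <- label_map(array(sample(c(0L, mid$region_id), 6^3, replace = TRUE),
                             c(6, 6, 6)), region_table(mid))
  merged_mid <- merge_bilateral(lab_mid)
  expect_identical(merged_mid$labels, lab_mid$labels)
  expect_equal(nrow(merged_mid$regions), nrow(mid))
})

test_that("region statistics report fractions and normalized intensities", {
  rt <- toy_region_table(2L)
  lab <- array(0L, c(10, 10, 10))
  lab[1:10, 1:10, 1] <- 1L    # 100 voxels
  lab[1:10, 1:10, 2:10] <- 2L # 900 voxels
  lm <- label_map(lab, rt)
  const <- volume(array(7, c(10, 10, 10)))
  st <- region_statistics(const, lm, normalize = TRUE)
  expect_equal(st$volume_pct, c(10, 90))
  expect_equal(st$rel_intensity, c(1, 1))

  v2 <- volume(array(0, c(10, 10, 10)) + ifelse(lab == 1L, 20, 10))
  st2 <- region_statistics(v2, lm, normalize = TRUE)
  expect_equal(st2$mean_intensity, c(20, 10))
  expect_equal(st2$rel_intensity, c(20 / 11, 10 / 11))
  expect_error(region_statistics(const, label_map(array(0L, c(10, 10, 10)),
                                                  rt)), "no labeled")
})

test_that("phantom region statistics recover the generating relative T1 values", {
  p <- synth_params(seed = 5)
  ph <- make_phantom(p, noise = TRUE)
  st <- region_statistics(ph$volume, ph$labels, normalize = TRUE)
  rs <- p$region_specs
  ic <- match(rs$region_id[rs$name == "Internal capsule"], st$region_id)
  expect_lt(abs(st$rel_intensity[ic] - 1.28), 0.02)
  th <- match(rs$region_id[rs$name == "Thalamus"], st$region_id)
  expect_lt(abs(st$rel_intensity[th] - 1.21), 0.02)
})

test_that("evaluation reports bundle the metrics and serialize", {
  dir <- withr::local_tempdir()
  lab <- toy_labels(10L)
  rep <- evaluate_parcellation(lab, lab)
  expect_equal(rep$global_index, 1)
  expect_equal(unname(rep$per_region_dice), rep(1, 2))
  jp <- file.path(dir, "report.json")
  write_eval_report(rep, jp, file.path(dir, "confusion.tsv"))
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$global_index, 1)
  expect_true(file.exists(file.path(dir, "confusion.tsv")))
  png_path <- file.path(dir, "confusion.png")
  confusion_heatmap(rep$confusion, png_path)
  expect_gt(file.size(png_path), 0)
})
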