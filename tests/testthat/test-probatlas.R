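# A template model with identity fields lets the probability arithmetic be
# tested in isolation from registration.
identity_template <- function(vol, n) {
  structure(list(volume = vol,
                 subject_fields = replicate(n, zero_field(dim(vol$data)),
                                            simplify = FALSE),
                 subject_affines = NULL,
                 iterations_run = 1L, converged = TRUE, history = 0,
                 config = reg_config()),
            class = "template_model")
}

test_that("probability maps implement the subject-fraction rule", {
  rt <- toy_region_table(3L)
  dims <- c(4L, 4L, 4L)
  vol <- volume(array(0, dims))
  # 7 of 10 subjects label voxel [1,1,1] as region 2
  maps <- lapply(1:10, function(i) {
    lab <- array(0L, dims)
    if (i <= 7) lab[1, 1, 1] <- 2L else lab[1, 1, 1] <- 1L
    label_map(lab, rt)
  })
  atlas <- build_probability_maps(identity_template(vol, 10), maps)
  expect_equal(atlas$prob[1, 1, 1, 2], 0.7)
  expect_equal(atlas$prob[1, 1, 1, 1], 0.3)
  expect_equal(atlas$background[1, 1, 1], 0)
  expect_equal(atlas$background[2, 2, 2], 1)

  # identical label maps with identity fields: binary maps, argmax restores them
  lab <- toy_labels(8L)
  atlas2 <- build_probability_maps(
    identity_template(volume(array(0, c(8, 8, 8))), 4),
    replicate(4, lab, simplify = FALSE))
  expect_true(all(atlas2$prob %in% c(0, 1)))
  expect_identical(max_label_map(atlas2)$labels, lab$labels)
})

test_that("probabilities are multiples of 1/N and normalize with background", {
  rt <- toy_region_table(4L)
  dims <- c(6L, 6L, 6L)
  maps <- lapply(1:5, function(s) random_label_map(6L, 1:4, rt, seed = 100 + s))
  atlas <- build_probability_maps(identity_template(volume(array(0, dims)), 5),
                                  maps)
  vals <- unique(as.vector(atlas$prob))
  expect_true(all(abs(vals * 5 - round(vals * 5)) < 1e-12))
  total <- apply(atlas$prob, 1:3, sum) + atlas$background
  expect_equal(max(abs(total - 1)), 0)
  # matches the brute-force subject/label counting loop
  oracle <- oracle_prob_maps(lapply(maps, `[[`, "labels"), rt$region_id)
  expect_equal(atlas$prob, oracle)
})

test_that("max-probability labeling breaks ties toward the smaller id", {
  rt <- toy_region_table(2L)
  dims <- c(2L, 2L, 2L)
  prob <- array(0, c(dims, 2L))
  bg <- array(0, dims)
  prob[1, 1, 1, 1] <- 0.5; prob[1, 1, 1, 2] <- 0.5   # region tie -> 1
  prob[2, 1, 1, 2] <- 0.7; bg[2, 1, 1] <- 0.3        # clear winner -> 2
  bg[1, 2, 1] <- 0.5; prob[1, 2, 1, 2] <- 0.5        # bg tie -> 0
  # remaining voxels: all-zero probabilities -> background
  atlas <- structure(list(template = volume(array(0, dims)), prob = prob,
                          background = bg, n_subjects = 10L, regions = rt),
                     class = "prob_atlas")
  ml <- max_label_map(atlas)
  expect_equal(ml$labels[1, 1, 1], 1L)
  expect_equal(ml$labels[2, 1, 1], 2L)
  expect_equal(ml$labels[1, 2, 1], 0L)
  expect_equal(ml$labels[2, 2, 2], 0L)
})

test_that("segmenting the template itself reproduces the atlas labeling", {
  p <- small_params()
  pop <- synth_population(p)
  cfg <- small_cfg()
  vols <- lapply(pop$subjects, `[[`, "volume")
  labs <- lapply(pop$subjects, `[[`, "labels")
  tm <- build_template(vols, cfg, ref_index = 1L)
  atlas <- build_probability_maps(tm, labs)
  seg <- segment(atlas$template, atlas, cfg)
  ref <- max_label_map(atlas)
  rep <- evaluate_parcellation(ref, seg$labels)
  big <- rep$voxel_counts >= 100
  expect_true(all(rep$per_region_dice[big] >= 0.99))
  # the winning probability accompanies the labels
  expect_true(all(seg$maxprob$data >= 0 & seg$maxprob$data <= 1 + 1e-9))
})

test_that("probabilistic atlas round-trips through its on-disk form", {
  dir <- withr::local_tempdir()
  rt <- toy_region_table(3L)
  maps <- lapply(1:4, function(s) random_label_map(6L, 1:3, rt, seed = s))
  atlas <- build_probability_maps(
    identity_template(volume(array(rnorm(216), c(6, 6, 6))), 4), maps)
  write_prob_atlas(atlas, dir)
  back <- read_prob_atlas(dir)
  expect_equal(back$prob, atlas$prob)
  expect_equal(back$background, atlas$background)
  expect_equal(back$n_subjects, atlas$n_subjects)
  expect_equal(back$template$data, atlas$template$data)
})
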