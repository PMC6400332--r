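test_that("identity transform returns the pair unchanged", {
  set.seed(1)
  p <- random_pairs(1)[[1]]
  q <- apply_affine(p, 0, 1, 1)
  expect_identical(q$image, p$image)
  expect_identical(q$mask, p$mask)
})

test_that("90-degree rotation equals exact index permutation", {
  set.seed(2)
  p <- random_pairs(1, nr = 21, nc = 21)[[1]]
  q <- apply_affine(p, 90, 1, 1)
  n <- 21
  expect_equal(q$mask, t(p$mask[, n:1]))
  expect_equal(q$image, t(p$image[, n:1]), tolerance = 1e-12)
})

test_that("masks stay binary under arbitrary transforms", {
  set.seed(3)
  p <- random_pairs(1)[[1]]
  for (a in c(-45, 17.3, 120)) {
    q <- apply_affine(p, a, 0.9, 1.1)
    expect_true(all(q$mask %in% c(0L, 1L)))
  }
})

test_that("out-of-bound scale factors are rejected", {
  p <- random_pairs(1)[[1]]
  expect_error(apply_affine(p, 0, 1.2, 1), class = "suvseg_config_error")
  expect_error(apply_affine(p, 0, 1, 0.8), class = "suvseg_config_error")
})

test_that("augmentation config enforces the parameter table bounds", {
  expect_error(augmentation_config(rotation_angles = c(0, 190)),
               class = "suvseg_config_error")
  expect_error(augmentation_config(rotation_angles = c(45)),
               class = "suvseg_config_error")
  expect_error(augmentation_config(scale_factors_x = c(1, 1.3)),
               class = "suvseg_config_error")
  expect_error(augmentation_config(noise_specs = list(
    list(type = "gaussian", param = 15, copies = 1))),
    class = "suvseg_config_error")
  expect_error(augmentation_config(noise_specs = list(
    list(type = "salt_pepper", param = 0.7, copies = 1))),
    class = "suvseg_config_error")
  expect_error(augmentation_config(noise_specs = list(
    list(type = "speckle", param = 1, copies = 1))),
    class = "suvseg_config_error")
})

test_that("zero-sd Gaussian noise leaves the image unchanged", {
  p <- random_pairs(1)[[1]]
  q <- add_noise(p, list(type = "gaussian", param = 0, copies = 1))
  expect_equal(q$image, p$image)
})

test_that("noise touches the image only, never the mask", {
  set.seed(5)
  p <- random_pairs(1)[[1]]
  for (spec in list(list(type = "gaussian", param = 5),
                    list(type = "uniform", param = 3),
                    list(type = "salt_pepper", param = 0.2))) {
    q <- add_noise(p, spec)
    expect_identical(q$mask, p$mask)
  }
})

test_that("Gaussian noise has the specified moments at large sample size", {
  p <- slice_pair(matrix(1000, 128, 128), matrix(0L, 128, 128))
  set.seed(6)
  q <- add_noise(p, list(type = "gaussian", param = 5))
  delta <- q$image - 1000
  expect_lt(abs(mean(delta)), 0.5)
  expect_gt(sd(delta), 4.5)
  expect_lt(sd(delta), 5.5)
})

test_that("salt-and-pepper flips the requested fraction, half salt half pepper", {
  p <- slice_pair(matrix(seq_len(100) * 1.0, 10, 10), matrix(0L, 10, 10))
  set.seed(7)
  q <- add_noise(p, list(type = "salt_pepper", param = 0.2))
  changed <- sum(q$image != p$image)
  expect_lte(abs(changed - 20), 2)   # a flipped pixel may coincide with min/max
  expect_true(all(q$image[q$image != p$image] %in% c(1, 100)))
})

test_that("default config yields 27 transformed and 54 total variants", {
  cfg <- default_aug_config()
  p <- random_pairs(1)
  no_noise <- augmentation_config(rotation_angles = cfg$rotation_angles,
                                  scale_factors_x = cfg$scale_factors_x,
                                  scale_factors_y = cfg$scale_factors_y)
  expect_length(augment_dataset(p, no_noise), 27L)
  expect_length(augment_dataset(p, cfg), 54L)
})

test_that("identity-only config returns the input pair alone", {
  p <- random_pairs(1)
  out <- augment_dataset(p, augmentation_config())
  expect_length(out, 1L)
  expect_identical(out[[1]]$image, p[[1]]$image)
})

test_that("count law holds for random configs against explicit enumeration", {
  set.seed(10)
  pool_angles <- c(-90, -45, -10, 10, 45, 90, 135)
  pool_scales <- c(0.85, 0.9, 0.95, 1.05, 1.1, 1.15)
  for (rep in 1:10) {
    angles <- c(0, sample(pool_angles, sample(0:3, 1)))
    sx <- c(1, sample(pool_scales, sample(0:2, 1)))
    sy <- c(1, sample(pool_scales, sample(0:2, 1)))
    n_specs <- sample(0:2, 1)
    specs <- if (n_specs == 0) list() else lapply(seq_len(n_specs), function(i) {
      list(type = sample(c("gaussian", "uniform", "salt_pepper"), 1),
           param = 0.1, copies = sample(1:3, 1))
    })
    cfg <- augmentation_config(angles, sx, sy, specs, rng_seed = rep)
    pairs <- random_pairs(sample(1:3, 1))
    expected <- length(pairs) * length(angles) * length(sx) * length(sy) *
      (1 + sum(vapply(specs, function(s) s$copies, 0)))
    expect_length(augment_dataset(pairs, cfg), expected)
  }
})

test_that("augmentation is reproducible from its seed", {
  set.seed(11)
  pairs <- random_pairs(2)
  cfg <- default_aug_config(rng_seed = 99L)
  a <- augment_dataset(pairs, cfg)
  b <- augment_dataset(pairs, cfg)
  expect_identical(lapply(a, `[[`, "image"), lapply(b, `[[`, "image"))
})

test_that("the sink consumes every pair and returns the count", {
  set.seed(12)
  pairs <- random_pairs(2)
  seen <- 0L
  n <- augment_dataset(pairs, default_aug_config(),
                       sink = function(p) seen <<- seen + 1L)
  expect_equal(n, 108L)
  expect_equal(seen, 108L)
})

test_that("patient split is exact for balanced cohorts", {
  pairs <- random_pairs(50, n_patients = 5)   # 10 slices per patient
  sp <- split_by_patient(pairs, 0.8, seed = 1)
  expect_length(sp$train, 40L)
  expect_length(sp$test, 10L)
  sp2 <- split_by_patient(random_pairs(20, n_patients = 2), 0.5, seed = 2)
  expect_length(sp2$train, 10L)
  expect_length(sp2$test, 10L)
})

test_that("no patient appears on both sides of a split", {
  set.seed(13)
  pairs <- random_pairs(37, n_patients = 7)
  for (s in 1:5) {
    sp <- split_by_patient(pairs, 0.7, seed = s)
    tr <- unique(vapply(sp$train, function(p) p$patient_id, ""))
    te <- unique(vapply(sp$test, function(p) p$patient_id, ""))
    expect_length(intersect(tr, te), 0L)
    expect_gt(length(te), 0L)
  }
})

test_that("single-patient cohorts cannot be split", {
  pairs <- random_pairs(5, n_patients = 1)
  expect_error(split_by_patient(pairs, 0.8, 1), class = "suvseg_config_error")
  expect_error(split_by_patient(random_pairs(4), 1.0, 1),
               class = "suvseg_config_error")
})
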