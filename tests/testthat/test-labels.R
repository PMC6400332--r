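test_that("threshold is the stated fraction of the dataset maximum", {
  pet <- volume(array(c(runif(30, 0, 5), 10), c(31, 1, 1)),
                spacing = c(1, 1, 1), modality = "PET")
  expect_equal(compute_threshold(pet, threshold_rule(0.2)), 2.0)
  pet$data[31] <- 8
  expect_equal(compute_threshold(pet, threshold_rule(0.2)), 1.6)
})

test_that("a PET volume with no uptake anywhere is rejected", {
  pet <- volume(array(0, c(3, 3, 3)), spacing = c(1, 1, 1), modality = "PET")
  expect_error(compute_threshold(pet), class = "suvseg_degenerate_error")
  ct <- volume(array(0, c(3, 3, 3)), spacing = c(1, 1, 1), modality = "CT")
  expect_error(make_labels(pet, ct), class = "suvseg_degenerate_error")
  expect_error(compute_threshold(ct), class = "suvseg_config_error")
})

test_that("binarize marks strictly-above-threshold voxels only", {
  v <- volume(array(c(1, 2, 3, 5), c(1, 2, 2)), spacing = c(1, 1, 1),
              modality = "PET")
  out <- binarize(v, 2)
  expect_equal(as.vector(out), c(0L, 0L, 1L, 1L))
  # a voxel exactly at the threshold stays background
  v2 <- volume(array(c(0.5, 2, 1, 1.5), c(1, 2, 2)), spacing = c(1, 1, 1),
               modality = "PET")
  expect_true(all(binarize(v2, 2) == 0L))
  expect_true(all(binarize(v, 10) == 0L))
})

test_that("threshold fraction bounds are validated", {
  expect_error(threshold_rule(0), class = "suvseg_config_error")
  expect_error(threshold_rule(1), class = "suvseg_config_error")
})

test_that("mask size is anti-monotone in the threshold fraction", {
  cs <- generate_phantom(small_phantom_config())
  pet_r <- resample_to_reference(cs$pet, cs$ct, "trilinear")
  sizes <- vapply(c(0.1, 0.2, 0.4, 0.6, 0.8), function(f) {
    sum(binarize(pet_r, compute_threshold(pet_r, threshold_rule(f))))
  }, 0)
  expect_true(all(diff(sizes) <= 0))
})

test_that("binarize is invariant to joint monotone rescaling of PET and T", {
  set.seed(8)
  v <- volume(array(runif(4 * 6 * 6, 0, 3), c(4, 6, 6)), spacing = c(1, 1, 1),
              modality = "PET")
  m1 <- binarize(v, 1.2)
  v2 <- v; v2$data <- 5 * v$data + 1          # strictly monotone map
  expect_identical(binarize(v2, 5 * 1.2 + 1), m1)
})

test_that("slice extraction returns foreground runs plus margins in order", {
  mask <- array(0L, c(12, 4, 4))
  mask[4:8, 2, 2] <- 1L
  ct <- volume(array(rnorm(12 * 16), c(12, 4, 4)), spacing = c(5, 1, 1),
               patient_id = "P9")
  p0 <- extract_bladder_slices(ct, mask, margin = 0)
  expect_length(p0, 5L)
  expect_equal(vapply(p0, function(p) p$slice_index, 0L), 4:8)
  p1 <- extract_bladder_slices(ct, mask, margin = 1)
  expect_length(p1, 7L)
  expect_equal(vapply(p1, function(p) p$slice_index, 0L), 3:9)
  expect_true(all(vapply(p0, function(p) p$patient_id, "") == "P9"))
  expect_warning(out <- extract_bladder_slices(ct, array(0L, c(12, 4, 4))),
                 "empty")
  expect_length(out, 0L)
})

test_that("unaugmented provenance is (angle 0, scales 1, noise none)", {
  cs <- generate_phantom(small_phantom_config())
  prs <- make_labels(cs$pet, cs$ct)
  p <- prs[[1]]
  expect_equal(p$angle_deg, 0)
  expect_equal(c(p$scale_x, p$scale_y), c(1, 1))
  expect_equal(p$noise, "none")
})

test_that("thresholded labels recover the known phantom mask (DSC >= 0.95)", {
  cs <- generate_phantom(small_phantom_config(noise_sd = 2))
  prs <- make_labels(cs$pet, cs$ct)
  m3 <- array(0L, dim(cs$ct$data))
  for (p in prs) m3[p$slice_index, , ] <- p$mask
  expect_gte(dsc(m3, cs$true_mask), 0.95)
})

test_that("background far below threshold is excluded everywhere", {
  # bladder uptake 10, background 0.5; T = 2 excludes all background
  d <- c(4, 8, 8)
  pet <- array(0.5, d); pet[2:3, 3:6, 3:6] <- 10
  petv <- volume(pet, spacing = c(1, 1, 1), modality = "PET")
  ctv <- volume(array(0, d), spacing = c(1, 1, 1))
  prs <- make_labels(petv, ctv)
  m3 <- array(0L, d)
  for (p in prs) m3[p$slice_index, , ] <- p$mask
  truth <- array(0L, d); truth[2:3, 3:6, 3:6] <- 1L
  expect_identical(m3[m3 == 1 & truth == 0], integer(0))
  expect_true(all(m3[truth == 0] == 0L))
})
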