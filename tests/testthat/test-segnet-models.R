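test_that("FCN-8s emits logits at the input resolution with 2 channels", {
  sp <- model_spec("fcn8s", input_size = c(64, 64), width_scale = 0.0625)
  m <- build_fcn8s(sp, seed = 1)
  x <- suvseg:::normalize_image(matrix(rnorm(64 * 64), 64, 64))
  out <- suvseg:::model_forward(m, x)
  expect_equal(dim(out$logits), c(64L, 64L, 2L))
})

test_that("input sizes not divisible by the family stride are rejected", {
  expect_error(model_spec("fcn8s", input_size = c(100, 100)),
               class = "suvseg_config_error")
  expect_error(model_spec("upsampled_resnet", input_size = c(12, 12)),
               class = "suvseg_config_error")
  expect_silent(model_spec("fcn8s", input_size = c(256, 256)))
  expect_silent(model_spec("fcn8s", input_size = c(512, 512)))
})

test_that("upsampled ResNet has output stride 8 and full-size logits", {
  sp <- model_spec("upsampled_resnet", input_size = c(64, 64),
                   width_scale = 0.0625, blocks_per_stage = 1L)
  m <- build_upsampled_resnet(sp, seed = 1)
  x <- suvseg:::normalize_image(matrix(rnorm(64 * 64), 64, 64))
  out <- suvseg:::model_forward(m, x)
  expect_equal(dim(out$logits), c(64L, 64L, 2L))
  # deepest feature map measured from the cache is input/8
  expect_equal(out$cache$score_dim[1:2], c(8L, 8L))
})

test_that("predictions are binary and ties go to background", {
  sp <- model_spec("upsampled_resnet", input_size = c(32, 32),
                   width_scale = 0.0625, blocks_per_stage = 1L)
  m <- build_upsampled_resnet(sp, seed = 2)
  img <- matrix(rnorm(32 * 32), 32, 32)
  pm <- predict_mask(m, img)
  expect_true(all(pm %in% c(0L, 1L)))
  # zeroing every parameter gives all-equal logits -> all background
  m0 <- m
  for (nm in names(m0$params)) {
    m0$params[[nm]]$W[] <- 0; m0$params[[nm]]$b[] <- 0
  }
  expect_true(all(predict_mask(m0, img) == 0L))
  expect_error(predict_mask(m, matrix(0, 16, 16)), class = "suvseg_format_error")
})

test_that("a logit head biased to one class forces that class everywhere", {
  sp <- model_spec("upsampled_resnet", input_size = c(32, 32),
                   width_scale = 0.0625, blocks_per_stage = 1L)
  m <- build_upsampled_resnet(sp, seed = 3)
  m$params$score$b <- c(1e6, 0)      # overwhelming background bias
  expect_true(all(predict_mask(m, matrix(rnorm(1024), 32, 32)) == 0L))
  m$params$score$b <- c(0, 1e6)
  expect_true(all(predict_mask(m, matrix(rnorm(1024), 32, 32)) == 1L))
})

test_that("conv/pool backward passes match numerical gradients", {
  set.seed(44)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  p <- suvseg:::conv_param(3, 3, 2, 3, stride = 1, dil = 1)
  out <- suvseg:::conv_fwd(x, p)
  dout <- array(rnorm(length(out)), dim(out))
  bw <- suvseg:::conv_bwd(x, p, dout)
  eps <- 1e-6
  for (probe in list(c(2, 3, 1), c(5, 1, 2))) {
    xp <- x; xp[probe[1], probe[2], probe[3]] <- xp[probe[1], probe[2], probe[3]] + eps
    num <- (sum(suvseg:::conv_fwd(xp, p) * dout) - sum(out * dout)) / eps
    expect_equal(bw$dx[probe[1], probe[2], probe[3]], num, tolerance = 1e-4)
  }
  i <- 7
  pp <- p; pp$W[i] <- pp$W[i] + eps
  num <- (sum(suvseg:::conv_fwd(x, pp) * dout) - sum(out * dout)) / eps
  expect_equal(bw$dW[i], num, tolerance = 1e-4)
})

test_that("whole-model gradients agree with finite differences", {
  set.seed(45)
  for (fam in c("fcn8s", "upsampled_resnet")) {
    sp <- model_spec(fam, input_size = c(32, 32), width_scale = 0.03,
                     blocks_per_stage = 1L)
    m <- build_model(sp, seed = 5)
    x <- suvseg:::normalize_image(matrix(rnorm(1024), 32, 32))
    mask <- random_mask(32, 32, 0.3)
    loss_of <- function(model) {
      fw <- suvseg:::model_forward(model, x)
      suvseg:::softmax_xent(fw$logits, mask)$loss
    }
    fw <- suvseg:::model_forward(m, x)
    sx <- suvseg:::softmax_xent(fw$logits, mask)
    g <- suvseg:::model_backward(m, fw$cache, sx$dlogits)
    eps <- 1e-5
    for (nm in c(names(g)[1], names(g)[length(g)])) {
      i <- which.max(abs(g[[nm]]$dW))
      mp <- m; mp$params[[nm]]$W[i] <- mp$params[[nm]]$W[i] + eps
      mm <- m; mm$params[[nm]]$W[i] <- mm$params[[nm]]$W[i] - eps
      num <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
      expect_equal(g[[nm]]$dW[i], num, tolerance = 1e-2)
    }
  }
})
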