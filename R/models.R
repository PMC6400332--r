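#' Model specification
#'
#' Describes one of the two supported segmentation families:
#' * `"fcn8s"` — a VGG-16-shaped backbone whose fully connected layers are
#'   realized as convolutions, with score maps from the third and fourth
#'   pooling stages fused into the stride-32 head by elementwise addition
#'   and fixed bilinear upsampling (x2, x2, x8 back to input size).
#' * `"upsampled_resnet"` — a pre-activation residual backbone of four
#'   stages with strides 2, 2, 2, 1 and atrous (dilation 2) convolution in
#'   the last stage, so the deepest feature map is input/8 ("output stride
#'   8"), followed by a 2-class score convolution and fixed bilinear x8
#'   interpolation.
#'
#' `width_scale` shrinks every channel count so the networks train at desk
#' scale from scratch; pre-trained backbone weights are not used.
#'
#' @param family `"fcn8s"` or `"upsampled_resnet"`.
#' @param input_size integer length-2 (rows, cols); must be divisible by 32
#'   (fcn8s) or 8 (upsampled_resnet).
#' @param num_classes number of output classes; 2 (background, bladder).
#' @param width_scale in (0, 1]: channel counts are
#'   `round(full_width * width_scale)` (minimum 2).
#' @param blocks_per_stage residual blocks per stage (resnet family).
#' @return A `suvseg_model_spec`.
#' @export
model_spec <- function(family = c("fcn8s", "upsampled_resnet"),
                       input_size = c(128L, 128L), num_classes = 2L,
                       width_scale = 1, blocks_per_stage = 2L) {
  family <- match.arg(family)
  input_size <- as.integer(input_size)
  stopifnot(length(input_size) == 2L, num_classes >= 2L,
            width_scale > 0, width_scale <= 1, blocks_per_stage >= 1L)
  div <- if (family == "fcn8s") 32L else 8L
  if (any(input_size %% div != 0L)) {
    stop_suvseg(sprintf("input size must be divisible by %d for family %s",
                        div, family), class = "suvseg_config_error")
  }
  structure(list(family = family, input_size = input_size,
                 num_classes = as.integer(num_classes),
                 width_scale = width_scale,
                 blocks_per_stage = as.integer(blocks_per_stage)),
            class = "suvseg_model_spec")
}

scaled <- function(n, w) pmax(2L, as.integer(round(n * w)))

#' Build an FCN-8s-style segmentation model
#'
#' @param spec a [model_spec()] with `family = "fcn8s"`.
#' @param seed initialization seed (He-normal weights; the pool3/pool4
#'   score convolutions start at zero so skip fusion initially passes the
#'   deep head through unchanged; upsampling kernels are fixed bilinear and
#'   never trained).
#' @return A `suvseg_model`.
#' @export
build_fcn8s <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "suvseg_model_spec"))
  if (spec$family != "fcn8s") {
    stop_suvseg("spec$family must be 'fcn8s'", class = "suvseg_config_error")
  }
  w <- spec$width_scale
  ch <- scaled(c(64, 128, 256, 512, 512), w)
  cf <- scaled(4096, w)
  nc <- spec$num_classes
  params <- with_seed(seed, {
    p <- list()
    cin <- 1L
    vgg <- list(c("conv1_1", "conv1_2"), c("conv2_1", "conv2_2"),
                c("conv3_1", "conv3_2", "conv3_3"),
                c("conv4_1", "conv4_2", "conv4_3"),
                c("conv5_1", "conv5_2", "conv5_3"))
    for (s in seq_along(vgg)) {
      cout <- if (s == 5L) ch[4] else ch[s]
      for (nm in vgg[[s]]) {
        p[[nm]] <- conv_param(3, 3, cin, cout)
        cin <- cout
      }
    }
    p$fc6 <- conv_param(7, 7, ch[4], cf)
    p$fc7 <- conv_param(1, 1, cf, cf)
    p$score_fr <- conv_param(1, 1, cf, nc)
    p$score_pool4 <- conv_param(1, 1, ch[4], nc, zero_init = TRUE)
    p$score_pool3 <- conv_param(1, 1, ch[3], nc, zero_init = TRUE)
    p
  })
  structure(list(spec = spec, params = params, seed = as.integer(seed),
                 K2 = bilinear_kernel(2), K8 = bilinear_kernel(8)),
            class = c("suvseg_fcn8s", "suvseg_model"))
}

#' Build an upsampled-ResNet-style segmentation model
#'
#' @param spec a [model_spec()] with `family = "upsampled_resnet"`.
#' @param seed initialization seed.
#' @return A `suvseg_model`.
#' @export
build_upsampled_resnet <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "suvseg_model_spec"))
  if (spec$family != "upsampled_resnet") {
    stop_suvseg("spec$family must be 'upsampled_resnet'",
                class = "suvseg_config_error")
  }
  w <- spec$width_scale
  ch <- scaled(c(64, 128, 256, 512), w)
  strides <- c(2L, 2L, 2L, 1L)
  dils <- c(1L, 1L, 1L, 2L)
  B <- spec$blocks_per_stage
  params <- with_seed(seed, {
    p <- list()
    p$stem <- conv_param(3, 3, 1L, ch[1])
    cin <- ch[1]
    for (s in 1:4) {
      for (b in seq_len(B)) {
        st <- if (b == 1L) strides[s] else 1L
        pre <- sprintf("s%db%d", s, b)
        if (b == 1L && (st != 1L || cin != ch[s])) {
          p[[paste0(pre, "_proj")]] <- conv_param(1, 1, cin, ch[s], stride = st)
        }
        p[[paste0(pre, "_c1")]] <- conv_param(3, 3, cin, ch[s], stride = st,
                                              dil = dils[s])
        p[[paste0(pre, "_c2")]] <- conv_param(3, 3, ch[s], ch[s], dil = dils[s])
        cin <- ch[s]
      }
    }
    p$score <- conv_param(1, 1, ch[4], spec$num_classes)
    p
  })
  structure(list(spec = spec, params = params, seed = as.integer(seed),
                 strides = strides, dils = dils,
                 K8 = bilinear_kernel(8)),
            class = c("suvseg_resnet", "suvseg_model"))
}

#' Build a segmentation model from its specification
#'
#' @param spec a [model_spec()].
#' @param seed initialization seed.
#' @return A `suvseg_model` of the requested family.
#' @export
build_model <- function(spec, seed = 1L) {
  switch(spec$family,
         fcn8s = build_fcn8s(spec, seed),
         upsampled_resnet = build_upsampled_resnet(spec, seed))
}

#' @export
print.suvseg_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$W) + length(p$b), 0))
  cat(sprintf("<suvseg_model> %s  input %dx%d  width_scale %g  %d parameters\n",
              x$spec$family, x$spec$input_size[1], x$spec$input_size[2],
              x$spec$width_scale, np))
  invisible(x)
}

# per-image z-score normalization applied before every forward pass; keeps
# optimization conditioning independent of the HU-like intensity scale
normalize_image <- function(img) {
  s <- stats::sd(img)
  array((img - mean(img)) / (s + 1e-8), c(dim(img), 1L))
}

check_input_size <- function(model, img) {
  if (!all(dim(img)[1:2] == model$spec$input_size)) {
    stop_suvseg(sprintf("image is %dx%d but the model expects %dx%d",
                        dim(img)[1], dim(img)[2],
                        model$spec$input_size[1], model$spec$input_size[2]),
                class = "suvseg_format_error")
  }
}

# ---- FCN-8s forward/backward ------------------------------------------------

fcn8s_forward <- function(model, x) {
  p <- model$params
  cache <- list(x = x)
  h <- x
  vgg <- list(c("conv1_1", "conv1_2"), c("conv2_1", "conv2_2"),
              c("conv3_1", "conv3_2", "conv3_3"),
              c("conv4_1", "conv4_2", "conv4_3"),
              c("conv5_1", "conv5_2", "conv5_3"))
  for (s in seq_along(vgg)) {
    for (nm in vgg[[s]]) {
      cache[[paste0(nm, "_in")]] <- h
      pre <- conv_fwd(h, p[[nm]])
      cache[[paste0(nm, "_pre")]] <- pre
      h <- relu_fwd(pre)
    }
    pl <- cpp_maxpool_fwd(h)
    cache[[paste0("pool", s, "_idx")]] <- pl$idx
    cache[[paste0("pool", s, "_dim")]] <- dim(h)
    h <- pl$out
    if (s == 3L) cache$p3 <- h
    if (s == 4L) cache$p4 <- h
  }
  cache$fc6_in <- h
  pre6 <- conv_fwd(h, p$fc6); cache$fc6_pre <- pre6
  h6 <- relu_fwd(pre6)
  cache$fc7_in <- h6
  pre7 <- conv_fwd(h6, p$fc7); cache$fc7_pre <- pre7
  h7 <- relu_fwd(pre7)
  cache$score_fr_in <- h7
  sc <- conv_fwd(h7, p$score_fr)
  up1 <- cpp_upsample_fwd(sc, model$K2, 2L)
  sp4 <- conv_fwd(cache$p4, p$score_pool4)
  fuse1 <- up1 + sp4
  up2 <- cpp_upsample_fwd(fuse1, model$K2, 2L)
  sp3 <- conv_fwd(cache$p3, p$score_pool3)
  fuse2 <- up2 + sp3
  logits <- cpp_upsample_fwd(fuse2, model$K8, 8L)
  cache$fuse1_dim <- dim(fuse1); cache$fuse2_dim <- dim(fuse2)
  list(logits = logits, cache = cache)
}

fcn8s_backward <- function(model, cache, dlogits) {
  p <- model$params
  g <- list()
  d2 <- cpp_upsample_bwd(dlogits, model$K8, 8L,
                         cache$fuse2_dim[1], cache$fuse2_dim[2])
  bw <- conv_bwd(cache$p3, p$score_pool3, d2)
  g$score_pool3 <- bw; dp3_skip <- bw$dx
  d1 <- cpp_upsample_bwd(d2, model$K2, 2L,
                         cache$fuse1_dim[1], cache$fuse1_dim[2])
  bw <- conv_bwd(cache$p4, p$score_pool4, d1)
  g$score_pool4 <- bw; dp4_skip <- bw$dx
  dsc <- cpp_upsample_bwd(d1, model$K2, 2L,
                          dim(cache$score_fr_in)[1], dim(cache$score_fr_in)[2])
  bw <- conv_bwd(cache$score_fr_in, p$score_fr, dsc); g$score_fr <- bw
  dh <- relu_bwd(cache$fc7_pre, bw$dx)
  bw <- conv_bwd(cache$fc7_in, p$fc7, dh); g$fc7 <- bw
  dh <- relu_bwd(cache$fc6_pre, bw$dx)
  bw <- conv_bwd(cache$fc6_in, p$fc6, dh); g$fc6 <- bw
  dh <- bw$dx
  vgg <- list(c("conv1_1", "conv1_2"), c("conv2_1", "conv2_2"),
              c("conv3_1", "conv3_2", "conv3_3"),
              c("conv4_1", "conv4_2", "conv4_3"),
              c("conv5_1", "conv5_2", "conv5_3"))
  for (s in 5:1) {
    dm <- cache[[paste0("pool", s, "_dim")]]
    dh <- cpp_maxpool_bwd(dh, cache[[paste0("pool", s, "_idx")]], dm[1], dm[2])
    for (nm in rev(vgg[[s]])) {
      dpre <- relu_bwd(cache[[paste0(nm, "_pre")]], dh)
      bw <- conv_bwd(cache[[paste0(nm, "_in")]], p[[nm]], dpre)
      g[[nm]] <- bw
      dh <- bw$dx
    }
    # skip-connection gradients join at the pooled maps
    if (s == 5L) dh <- dh + dp4_skip
    if (s == 4L) dh <- dh + dp3_skip
  }
  g
}

# ---- upsampled ResNet forward/backward --------------------------------------

resnet_forward <- function(model, x) {
  p <- model$params
  B <- model$spec$blocks_per_stage
  cache <- list(x = x)
  cache$stem_in <- x
  h <- conv_fwd(x, p$stem)
  cache$stem_pre <- h
  h <- relu_fwd(h)
  for (s in 1:4) {
    for (b in seq_len(B)) {
      pre <- sprintf("s%db%d", s, b)
      cache[[paste0(pre, "_x")]] <- h
      hp <- relu_fwd(h)                    # pre-activation
      cache[[paste0(pre, "_hp")]] <- hp
      a_pre <- conv_fwd(hp, p[[paste0(pre, "_c1")]])
      cache[[paste0(pre, "_a_pre")]] <- a_pre
      a <- relu_fwd(a_pre)
      cache[[paste0(pre, "_a")]] <- a
      out <- conv_fwd(a, p[[paste0(pre, "_c2")]])
      proj <- p[[paste0(pre, "_proj")]]
      sc <- if (!is.null(proj)) conv_fwd(hp, proj) else h
      cache[[paste0(pre, "_proj_used")]] <- !is.null(proj)
      h <- out + sc
    }
  }
  cache$head_pre <- h
  hh <- relu_fwd(h)
  cache$score_in <- hh
  scl <- conv_fwd(hh, p$score)
  cache$score_dim <- dim(scl)
  logits <- cpp_upsample_fwd(scl, model$K8, 8L)
  list(logits = logits, cache = cache)
}

resnet_backward <- function(model, cache, dlogits) {
  p <- model$params
  B <- model$spec$blocks_per_stage
  g <- list()
  dscl <- cpp_upsample_bwd(dlogits, model$K8, 8L,
                           cache$score_dim[1], cache$score_dim[2])
  bw <- conv_bwd(cache$score_in, p$score, dscl); g$score <- bw
  dh <- relu_bwd(cache$head_pre, bw$dx)
  for (s in 4:1) {
    for (b in rev(seq_len(B))) {
      pre <- sprintf("s%db%d", s, b)
      xin <- cache[[paste0(pre, "_x")]]
      hp <- cache[[paste0(pre, "_hp")]]
      bw2 <- conv_bwd(cache[[paste0(pre, "_a")]], p[[paste0(pre, "_c2")]], dh)
      g[[paste0(pre, "_c2")]] <- bw2
      da_pre <- relu_bwd(cache[[paste0(pre, "_a_pre")]], bw2$dx)
      bw1 <- conv_bwd(hp, p[[paste0(pre, "_c1")]], da_pre)
      g[[paste0(pre, "_c1")]] <- bw1
      dhp <- bw1$dx
      if (cache[[paste0(pre, "_proj_used")]]) {
        bwp <- conv_bwd(hp, p[[paste0(pre, "_proj")]], dh)
        g[[paste0(pre, "_proj")]] <- bwp
        dhp <- dhp + bwp$dx
        dxin <- relu_bwd(xin, dhp)
      } else {
        dxin <- relu_bwd(xin, dhp) + dh    # identity shortcut from x
      }
      dh <- dxin
    }
  }
  dstem <- relu_bwd(cache$stem_pre, dh)
  g$stem <- conv_bwd(cache$stem_in, p$stem, dstem)
  g
}

model_forward <- function(model, x) {
  if (inherits(model, "suvseg_fcn8s")) fcn8s_forward(model, x)
  else resnet_forward(model, x)
}

model_backward <- function(model, cache, dlogits) {
  if (inherits(model, "suvseg_fcn8s")) fcn8s_backward(model, cache, dlogits)
  else resnet_backward(model, cache, dlogits)
}

#' Predict a binary mask for one CT slice
#'
#' Per-pixel argmax over the two class logits; ties go to background.
#'
#' @param model a trained (or freshly built) `suvseg_model`.
#' @param image 2D CT intensity matrix matching the model's input size.
#' @return Binary integer matrix (1 = bladder).
#' @export
predict_mask <- function(model, image) {
  stopifnot(inherits(model, "suvseg_model"))
  check_input_size(model, image)
  x <- normalize_image(image)
  logits <- model_forward(model, x)$logits
  mask <- (logits[, , 2] > logits[, , 1]) * 1L
  matrix(as.integer(mask), nrow(image))
}
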