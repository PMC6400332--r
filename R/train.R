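#' Training specification
#'
#' Adam with a fixed learning rate of 1e-4 (Adam performs its own per-
#' parameter step-size adaptation, so no external decay schedule is used),
#' batch size 1 (each image is processed individually; with batch size 1 no
#' batch normalization is performed anywhere in the models) and pixelwise
#' cross-entropy loss between the 2-class logits and the mask.
#'
#' @param iterations number of single-image optimization steps.
#' @param learning_rate fixed Adam learning rate; default 1e-4.
#' @param beta1,beta2,epsilon Adam moment/stabilization constants.
#' @param seed RNG seed for the image sampling order.
#' @return A `suvseg_train_spec`.
#' @export
train_spec <- function(iterations = 1000L, learning_rate = 1e-4,
                       beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                       seed = 1L) {
  stopifnot(iterations >= 0L, learning_rate > 0)
  structure(list(iterations = as.integer(iterations),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, batch_size = 1L,
                 seed = as.integer(seed)),
            class = "suvseg_train_spec")
}

# softmax cross-entropy over the channel dimension of (H, W, 2) logits;
# returns mean loss over pixels and the gradient w.r.t. the logits
softmax_xent <- function(logits, mask) {
  m <- pmax(logits[, , 1], logits[, , 2])
  e1 <- exp(logits[, , 1] - m); e2 <- exp(logits[, , 2] - m)
  z <- e1 + e2
  p2 <- e2 / z
  npix <- length(mask)
  loss <- -mean(ifelse(mask == 1, log(pmax(p2, 1e-300)),
                       log(pmax(1 - p2, 1e-300))))
  dl <- array(0, dim(logits))
  dl[, , 1] <- ((1 - p2) - (1 - mask)) / npix
  dl[, , 2] <- (p2 - mask) / npix
  list(loss = loss, dlogits = dl)
}

#' Train a segmentation model
#'
#' Runs `spec$iterations` single-image Adam steps over the training pairs
#' (images sampled uniformly with the spec's seed), minimizing pixelwise
#' cross-entropy. The fixed bilinear upsampling kernels are not parameters
#' and are never updated. Deterministic: identical model, pairs and spec
#' reproduce the loss trace bit for bit.
#'
#' @param model a `suvseg_model` from [build_model()].
#' @param pairs nonempty list of [slice_pair()]s matching the model's input
#'   size.
#' @param spec a [train_spec()].
#' @return `list(model = trained model, loss_trace = numeric vector)`.
#' @export
train_model <- function(model, pairs, spec = train_spec()) {
  stopifnot(inherits(model, "suvseg_model"), inherits(spec, "suvseg_train_spec"))
  if (length(pairs) == 0L) {
    stop_suvseg("training requires at least one slice pair",
                class = "suvseg_config_error")
  }
  for (p in pairs) {
    check_input_size(model, p$image)
    if (!all(dim(p$image) == dim(p$mask))) {
      stop_suvseg("image/mask shape mismatch in training pair",
                  class = "suvseg_format_error")
    }
  }
  if (spec$iterations == 0L) {
    return(list(model = model, loss_trace = numeric(0)))
  }
  xs <- lapply(pairs, function(p) normalize_image(p$image))
  ms <- lapply(pairs, function(p) p$mask)
  order_idx <- with_seed(spec$seed,
                         sample.int(length(pairs), spec$iterations,
                                    replace = TRUE))
  # Adam state, aligned with the trainable parameter list
  mstate <- lapply(model$params, function(p) {
    list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0)
  })
  trace <- numeric(spec$iterations)
  b1 <- spec$beta1; b2 <- spec$beta2; eps <- spec$epsilon; lr <- spec$learning_rate
  for (it in seq_len(spec$iterations)) {
    i <- order_idx[it]
    fw <- model_forward(model, xs[[i]])
    sx <- softmax_xent(fw$logits, ms[[i]])
    trace[it] <- sx$loss
    grads <- model_backward(model, fw$cache, sx$dlogits)
    corr1 <- 1 - b1^it; corr2 <- 1 - b2^it
    for (nm in names(grads)) {
      st <- mstate[[nm]]
      gW <- grads[[nm]]$dW; gb <- as.numeric(grads[[nm]]$db)
      st$mW <- b1 * st$mW + (1 - b1) * gW
      st$vW <- b2 * st$vW + (1 - b2) * gW^2
      st$mb <- b1 * st$mb + (1 - b1) * gb
      st$vb <- b2 * st$vb + (1 - b2) * gb^2
      model$params[[nm]]$W <- model$params[[nm]]$W -
        lr * (st$mW / corr1) / (sqrt(st$vW / corr2) + eps)
      model$params[[nm]]$b <- model$params[[nm]]$b -
        lr * (st$mb / corr1) / (sqrt(st$vb / corr2) + eps)
      mstate[[nm]] <- st
    }
  }
  list(model = model, loss_trace = trace)
}
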