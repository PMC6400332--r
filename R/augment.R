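#' Augmentation configuration
#'
#' Explicit lists of rotation angles and x/y scale factors plus noise
#' specifications. Every slice is expanded into the full cross-product of
#' angles and scale factors (the identity transform is required to be a
#' member), and each transformed variant is additionally duplicated with
#' noise: the per-slice output count is exactly
#' `length(angles) * length(sx) * length(sy) * (1 + sum(copies))`.
#'
#' Parameter bounds: every |angle| <= 180 degrees, every scale factor within
#' \[0.85, 1.15\], Gaussian sd <= 10, uniform amplitude <= 10, salt/pepper
#' density <= 0.5.
#'
#' @param rotation_angles degrees; must contain 0.
#' @param scale_factors_x,scale_factors_y positive scalars; must contain 1.
#' @param noise_specs list of `list(type, param, copies)` with
#'   `type` one of `"gaussian"` (param = sd), `"uniform"` (param =
#'   amplitude) or `"salt_pepper"` (param = density), and `copies` the
#'   number of noisy duplicates of each transformed slice.
#' @param rng_seed seed driving all noise generation.
#' @return A `suvseg_aug_config`.
#' @export
augmentation_config <- function(rotation_angles = 0,
                                scale_factors_x = 1,
                                scale_factors_y = 1,
                                noise_specs = list(),
                                rng_seed = 1L) {
  cfg <- list(rotation_angles = as.numeric(rotation_angles),
              scale_factors_x = as.numeric(scale_factors_x),
              scale_factors_y = as.numeric(scale_factors_y),
              noise_specs = noise_specs, rng_seed = as.integer(rng_seed))
  if (!any(cfg$rotation_angles == 0)) {
    stop_suvseg("rotation_angles must contain 0 (the identity)",
                class = "suvseg_config_error")
  }
  if (any(abs(cfg$rotation_angles) > 180)) {
    stop_suvseg("rotation angles must satisfy |angle| <= 180 degrees",
                class = "suvseg_config_error")
  }
  for (s in list(cfg$scale_factors_x, cfg$scale_factors_y)) {
    if (!any(s == 1)) {
      stop_suvseg("scale factor lists must contain 1.0 (the identity)",
                  class = "suvseg_config_error")
    }
    if (any(s < 0.85) || any(s > 1.15)) {
      stop_suvseg("scale factors must lie within [0.85, 1.15]",
                  class = "suvseg_config_error")
    }
  }
  for (ns in cfg$noise_specs) validate_noise_spec(ns)
  class(cfg) <- "suvseg_aug_config"
  cfg
}

validate_noise_spec <- function(ns) {
  if (!is.list(ns) || is.null(ns$type) || is.null(ns$param)) {
    stop_suvseg("noise spec must be list(type, param, copies)",
                class = "suvseg_config_error")
  }
  lim <- switch(ns$type,
                gaussian = 10, uniform = 10, salt_pepper = 0.5,
                stop_suvseg("unknown noise type: ", ns$type,
                            class = "suvseg_config_error"))
  if (ns$param < 0 || ns$param > lim) {
    stop_suvseg(sprintf("noise parameter %g outside [0, %g] for type %s",
                        ns$param, lim, ns$type), class = "suvseg_config_error")
  }
  if (!is.null(ns$copies) && ns$copies < 0) {
    stop_suvseg("noise copies must be >= 0", class = "suvseg_config_error")
  }
  invisible(ns)
}

#' Default augmentation configuration
#'
#' Three rotations (-45, 0, +45 degrees) crossed with three scale factors
#' per axis (0.9, 1.0, 1.1) give exactly 27 transformed variants per slice;
#' one zero-mean Gaussian noise copy (sd 5) of each variant doubles that to
#' 54 variants total, so 630 input slices yield 34,020 augmented pairs.
#'
#' @param rng_seed seed for noise generation.
#' @return A `suvseg_aug_config`.
#' @export
default_aug_config <- function(rng_seed = 1L) {
  augmentation_config(rotation_angles = c(-45, 0, 45),
                      scale_factors_x = c(0.9, 1.0, 1.1),
                      scale_factors_y = c(0.9, 1.0, 1.1),
                      noise_specs = list(list(type = "gaussian", param = 5,
                                              copies = 1L)),
                      rng_seed = rng_seed)
}

# Precomputed inverse-map sampler for rotation about the image centre by
# `angle_deg` composed with axis scaling (sx along columns/x, sy along
# rows/y). Linear gather indices and bilinear weights depend only on the
# transform and the shape, so one sampler is reused across every slice of a
# dataset.
affine_map <- function(nr, nc, angle_deg, sx, sy) {
  th <- angle_deg * pi / 180
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  r <- rep(seq_len(nr), times = nc) - cy
  cc <- rep(seq_len(nc), each = nr) - cx
  # forward map: rotate then scale; inverse: unscale then rotate back
  ry <- r / sy; rx <- cc / sx
  src_r <- cos(th) * ry + sin(th) * rx + cy
  src_c <- -sin(th) * ry + cos(th) * rx + cx
  ok <- src_r >= 1 & src_r <= nr & src_c >= 1 & src_c <= nc
  # bilinear corner indices/weights (valid pixels only)
  r0 <- pmin(pmax(floor(src_r[ok]), 1), max(nr - 1, 1))
  c0 <- pmin(pmax(floor(src_c[ok]), 1), max(nc - 1, 1))
  fr <- src_r[ok] - r0; fc <- src_c[ok] - c0
  r1 <- pmin(r0 + 1, nr); c1 <- pmin(c0 + 1, nc)
  lin <- function(rr, cc) rr + nr * (cc - 1)
  rr <- round(src_r[ok]); ccn <- round(src_c[ok])
  list(nr = nr, nc = nc, ok = ok,
       l00 = lin(r0, c0), l10 = lin(r1, c0), l01 = lin(r0, c1),
       l11 = lin(r1, c1),
       w00 = (1 - fr) * (1 - fc), w10 = fr * (1 - fc),
       w01 = (1 - fr) * fc, w11 = fr * fc,
       lnn = lin(pmin(pmax(rr, 1), nr), pmin(pmax(ccn, 1), nc)))
}

sample_bilinear <- function(img, map, fill) {
  out <- rep(fill, map$nr * map$nc)
  out[map$ok] <- img[map$l00] * map$w00 + img[map$l10] * map$w10 +
    img[map$l01] * map$w01 + img[map$l11] * map$w11
  matrix(out, map$nr, map$nc)
}

sample_nearest <- function(img, map, fill) {
  out <- rep(fill, map$nr * map$nc)
  out[map$ok] <- img[map$lnn]
  matrix(out, map$nr, map$nc)
}

#' Apply a rotation/scaling transform to a slice pair
#'
#' Both image and mask are transformed about the image centre with the same
#' affine map (rotation by `angle_deg`, axis scaling by `sx`/`sy`); the
#' image is interpolated bilinearly, the mask by nearest neighbour so it
#' stays binary. Output dimensions are unchanged; regions mapped from
#' outside the input are filled with the image minimum (mask: 0).
#'
#' @param pair a [slice_pair()].
#' @param angle_deg rotation in degrees (counter-clockwise in array
#'   coordinates).
#' @param sx,sy scale factors; each must lie within \[0.85, 1.15\].
#' @return The transformed [slice_pair()] with updated provenance.
#' @export
apply_affine <- function(pair, angle_deg, sx = 1, sy = 1) {
  stopifnot(inherits(pair, "suvseg_slice_pair"))
  if (abs(sx - 1) > 0.15 || abs(sy - 1) > 0.15) {
    stop_suvseg("scale factors outside the supported bound |s - 1| <= 0.15",
                class = "suvseg_config_error")
  }
  if (angle_deg == 0 && sx == 1 && sy == 1) return(pair)
  map <- affine_map(nrow(pair$image), ncol(pair$image), angle_deg, sx, sy)
  img <- sample_bilinear(pair$image, map, fill = min(pair$image))
  msk <- sample_nearest(pair$mask, map, fill = 0L)
  slice_pair(img, msk, patient_id = pair$patient_id,
             slice_index = pair$slice_index,
             angle_deg = angle_deg, scale_x = sx, scale_y = sy,
             noise = pair$noise)
}

#' Add noise to the image of a slice pair
#'
#' Noise is applied to the image only; the mask is returned bit-identical.
#' Gaussian noise is i.i.d. zero-mean with the given sd; uniform noise is
#' i.i.d. on \[-amplitude, +amplitude\]; salt-and-pepper sets a fraction
#' `density` of pixels to the image minimum or maximum (half each, rounded).
#'
#' @param pair a [slice_pair()].
#' @param spec `list(type, param)` (see [augmentation_config()]).
#' @return The noisy [slice_pair()]; provenance records the noise applied.
#' @export
add_noise <- function(pair, spec) {
  stopifnot(inherits(pair, "suvseg_slice_pair"))
  validate_noise_spec(spec)
  img <- pair$image
  n <- length(img)
  img <- switch(spec$type,
    gaussian = img + stats::rnorm(n, mean = 0, sd = spec$param),
    uniform = img + stats::runif(n, min = -spec$param, max = spec$param),
    salt_pepper = {
      k <- round(spec$param * n)
      if (k > 0) {
        pix <- sample.int(n, k)
        k_salt <- round(k / 2)
        img[pix[seq_len(k_salt)]] <- max(pair$image)
        if (k_salt < k) img[pix[(k_salt + 1):k]] <- min(pair$image)
      }
      img
    })
  out <- pair
  out$image <- matrix(img, nrow(pair$image))
  out$noise <- sprintf("%s(%g)", spec$type, spec$param)
  out
}

#' Expand a slice dataset by the configured augmentations
#'
#' For each input pair, emits every rotation x scale-x x scale-y variant
#' (identity included), each immediately followed by its noisy duplicates
#' (`copies` per noise spec). The output count obeys the exact law
#' `length(pairs) * |angles| * |sx| * |sy| * (1 + sum(copies))` and the
#' result is deterministic given `config$rng_seed`.
#'
#' @param pairs nonempty list of [slice_pair()]s.
#' @param config an [augmentation_config()].
#' @param sink optional `function(pair)` consuming each output pair as it is
#'   produced instead of accumulating all pairs in memory (useful for large
#'   expansions, e.g. streaming to disk); when supplied the function returns
#'   the output count invisibly.
#' @return List of augmented [slice_pair()]s, or the count when `sink` is
#'   given.
#' @export
augment_dataset <- function(pairs, config, sink = NULL) {
  stopifnot(inherits(config, "suvseg_aug_config"))
  if (length(pairs) == 0L) {
    stop_suvseg("augment_dataset requires at least one input pair",
                class = "suvseg_config_error")
  }
  grid <- expand.grid(sy = config$scale_factors_y,
                      sx = config$scale_factors_x,
                      angle = config$rotation_angles,
                      KEEP.OUT.ATTRS = FALSE)
  copies_total <- sum(vapply(config$noise_specs,
                             function(ns) as.integer(ns$copies %||% 1L), 1L))
  n_out <- length(pairs) * nrow(grid) * (1L + copies_total)
  collect <- is.null(sink)
  if (collect) {
    out <- vector("list", n_out)
  }
  count <- 0L
  emit <- function(p) {
    count <<- count + 1L
    if (collect) out[[count]] <<- p else sink(p)
  }
  # precompute one sampling map per transform (shared across slices when all
  # slices have one shape, the common case)
  shp <- dim(pairs[[1]]$image)
  maps <- lapply(seq_len(nrow(grid)), function(t) {
    affine_map(shp[1], shp[2], grid$angle[t], grid$sx[t], grid$sy[t])
  })
  with_seed(config$rng_seed, {
    for (p in pairs) {
      same_shape <- all(dim(p$image) == shp)
      for (t in seq_len(nrow(grid))) {
        a <- grid$angle[t]; sx <- grid$sx[t]; sy <- grid$sy[t]
        tp <- if (a == 0 && sx == 1 && sy == 1) {
          p
        } else if (same_shape) {
          slice_pair(sample_bilinear(p$image, maps[[t]], min(p$image)),
                     sample_nearest(p$mask, maps[[t]], 0L),
                     patient_id = p$patient_id, slice_index = p$slice_index,
                     angle_deg = a, scale_x = sx, scale_y = sy, noise = p$noise)
        } else {
          apply_affine(p, a, sx, sy)
        }
        emit(tp)
        for (ns in config$noise_specs) {
          for (cp in seq_len(as.integer(ns$copies %||% 1L))) {
            emit(add_noise(tp, ns))
          }
        }
      }
    }
  })
  if (collect) out else invisible(count)
}

#' Patient-level train/test split
#'
#' Assigns whole patients to one side only (no slice of a patient may appear
#' in both train and test). Patients are shuffled with the given seed and
#' assigned greedily to the training side until the training slice count
#' first reaches `train_fraction` of the total; the remainder is the test
#' side. With at least two patients both sides are guaranteed nonempty.
#'
#' @param pairs list of [slice_pair()]s.
#' @param train_fraction scalar in (0, 1); 0.8 is the conventional 80/20
#'   split.
#' @param seed shuffle seed.
#' @return `list(train = ..., test = ...)` of slice-pair lists.
#' @export
split_by_patient <- function(pairs, train_fraction = 0.8, seed = 1L) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop_suvseg("train_fraction must lie strictly between 0 and 1",
                class = "suvseg_config_error")
  }
  ids <- vapply(pairs, function(p) p$patient_id, "")
  upat <- unique(ids)
  if (length(upat) < 2L) {
    stop_suvseg("cannot split a single patient without leakage",
                class = "suvseg_config_error")
  }
  ord <- with_seed(seed, sample(upat))
  target <- train_fraction * length(pairs)
  counts <- vapply(ord, function(u) sum(ids == u), 0L)
  cum <- cumsum(counts)
  n_train <- which(cum >= target)[1]
  if (n_train >= length(ord)) n_train <- length(ord) - 1L  # keep test nonempty
  train_ids <- ord[seq_len(n_train)]
  list(train = pairs[ids %in% train_ids],
       test = pairs[!(ids %in% train_ids)])
}
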