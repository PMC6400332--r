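#' Phantom configuration
#'
#' Parameters of the synthetic pelvic PET/CT phantom: an ellipsoidal
#' high-uptake bladder in PET, a CT with low bladder/soft-tissue contrast,
#' a surrounding high-attenuation pelvic bone ring, optional radial streak
#' artifacts, and PET rendered at coarser in-plane resolution than CT (with
#' partial-volume Gaussian blur), emulating the imaging situation in which
#' FDG accumulation makes the bladder trivially separable in PET while CT
#' contrast stays poor.
#'
#' @param ct_shape integer length-3 (n_slices, rows, cols). Default
#'   `c(12, 128, 128)`.
#' @param ct_spacing mm, (dz, dy, dx). Default `c(5, 2, 2)`.
#' @param pet_downsample_factor integer >= 1; the PET grid is coarser than
#'   CT by this factor in-plane. Rows/cols must be divisible by it.
#' @param bladder_center fractional (z, y, x) coordinates of the ellipsoid
#'   centre within the field of view, each in \[0, 1\].
#' @param bladder_semiaxes mm, (az, ay, ax).
#' @param uptake_ratio bladder(rim)-to-background PET intensity ratio (> 1).
#'   Values > 5 guarantee that thresholding at 20% of the maximum separates
#'   bladder from background.
#' @param hot_core_ratio intensity of the central bladder core relative to
#'   the rim level (>= 1). Excreted tracer concentrates towards the bladder
#'   centre, so the dataset SUV maximum sits well above the rim level; with
#'   the default 2.75 the 20%-of-maximum threshold falls at the midpoint of
#'   the blurred bladder/background edge, where it delineates the boundary
#'   without bias.
#' @param pet_background background PET intensity (SUV-proportional).
#' @param ct_background CT soft-tissue background intensity (HU-like).
#' @param soft_tissue_contrast CT bladder-minus-background intensity gap;
#'   small and negative by default (urine is mildly hypodense).
#' @param bone_ring add a high-attenuation pelvic ring (logical).
#' @param streak_artifacts add radial streak stripes inside the ring (logical).
#' @param streak_amplitude intensity amplitude of the streaks.
#' @param noise_sd standard deviation of additive Gaussian CT noise.
#' @param pet_blur_sigma in-plane partial-volume blur of PET, in CT pixels.
#' @param seed integer RNG seed; identical seed + config give bit-identical
#'   volumes.
#' @return A `suvseg_phantom_config` list.
#' @export
phantom_config <- function(ct_shape = c(12L, 128L, 128L),
                           ct_spacing = c(5, 2, 2),
                           pet_downsample_factor = 2L,
                           bladder_center = c(0.5, 0.5, 0.5),
                           bladder_semiaxes = c(18, 40, 40),
                           uptake_ratio = 10,
                           hot_core_ratio = 2.75,
                           pet_background = 0.25,
                           ct_background = 40,
                           soft_tissue_contrast = -25,
                           bone_ring = TRUE,
                           streak_artifacts = FALSE,
                           streak_amplitude = 20,
                           noise_sd = 10,
                           pet_blur_sigma = 1.5,
                           seed = 1L) {
  cfg <- list(ct_shape = as.integer(ct_shape), ct_spacing = as.numeric(ct_spacing),
              pet_downsample_factor = as.integer(pet_downsample_factor),
              bladder_center = as.numeric(bladder_center),
              bladder_semiaxes = as.numeric(bladder_semiaxes),
              uptake_ratio = uptake_ratio, hot_core_ratio = hot_core_ratio,
              pet_background = pet_background,
              ct_background = ct_background,
              soft_tissue_contrast = soft_tissue_contrast,
              bone_ring = isTRUE(bone_ring),
              streak_artifacts = isTRUE(streak_artifacts),
              streak_amplitude = streak_amplitude, noise_sd = noise_sd,
              pet_blur_sigma = pet_blur_sigma, seed = as.integer(seed))
  if (length(cfg$ct_shape) != 3L || any(cfg$ct_shape < 1L)) {
    stop_suvseg("ct_shape must be 3 positive integers", class = "suvseg_config_error")
  }
  if (cfg$pet_downsample_factor < 1L ||
      any(cfg$ct_shape[2:3] %% cfg$pet_downsample_factor != 0L)) {
    stop_suvseg("rows/cols must be divisible by pet_downsample_factor",
                class = "suvseg_config_error")
  }
  if (cfg$uptake_ratio <= 1) {
    stop_suvseg("uptake_ratio must exceed 1", class = "suvseg_config_error")
  }
  if (cfg$hot_core_ratio < 1 || cfg$hot_core_ratio >= 5) {
    stop_suvseg("hot_core_ratio must lie in [1, 5) so the 20% threshold ",
                "stays below the bladder rim level", class = "suvseg_config_error")
  }
  if (any(cfg$bladder_center < 0) || any(cfg$bladder_center > 1)) {
    stop_suvseg("bladder ellipsoid centre lies outside the field of view",
                class = "suvseg_config_error")
  }
  if (cfg$noise_sd < 0 || any(cfg$bladder_semiaxes < 0)) {
    stop_suvseg("noise_sd and bladder_semiaxes must be non-negative",
                class = "suvseg_config_error")
  }
  class(cfg) <- "suvseg_phantom_config"
  cfg
}

# separable in-plane Gaussian blur with mass-preserving edge renormalization
blur2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  K <- max(1L, ceiling(3 * sigma))
  g <- stats::dnorm(seq(-K, K), sd = sigma)
  g <- g / sum(g)
  conv1 <- function(mat, along_rows) {
    n <- if (along_rows) nrow(mat) else ncol(mat)
    out <- matrix(0, nrow(mat), ncol(mat))
    wt <- matrix(0, nrow(mat), ncol(mat))
    for (t in seq(-K, K)) {
      w <- g[t + K + 1]
      src <- seq_len(n) + t
      ok <- src >= 1 & src <= n
      if (along_rows) {
        out[ok, ] <- out[ok, ] + w * mat[src[ok], ]
        wt[ok, ] <- wt[ok, ] + w
      } else {
        out[, ok] <- out[, ok] + w * mat[, src[ok]]
        wt[, ok] <- wt[, ok] + w
      }
    }
    out / wt
  }
  conv1(conv1(m, TRUE), FALSE)
}

#' Generate one synthetic PET/CT case with known bladder mask
#'
#' @param config a [phantom_config()].
#' @param patient_id identifier attached to the generated volumes.
#' @return A `suvseg_phantom_case` list with elements `ct`, `pet`
#'   (both [volume()]s), `true_mask` (binary array on the CT grid) and
#'   `patient_id`. The true mask always contains at least one foreground
#'   voxel: a degenerate (zero semi-axis) ellipsoid collapses to the single
#'   voxel nearest its centre.
#' @export
generate_phantom <- function(config = phantom_config(), patient_id = "P001") {
  stopifnot(inherits(config, "suvseg_phantom_config"))
  d <- config$ct_shape; sp <- config$ct_spacing
  # voxel-centre physical coordinates; fractional centre spans the index range
  zc <- (seq_len(d[1]) - 1) * sp[1]
  yc <- (seq_len(d[2]) - 1) * sp[2]
  xc <- (seq_len(d[3]) - 1) * sp[3]
  ctr <- config$bladder_center * c(max(zc), max(yc), max(xc))
  ax <- pmax(config$bladder_semiaxes, 1e-9)

  uz <- ((zc - ctr[1]) / ax[1])^2
  uy <- ((yc - ctr[2]) / ax[2])^2
  ux <- ((xc - ctr[3]) / ax[3])^2
  inside <- outer(outer(uz, uy, `+`), ux, `+`) <= 1
  mask <- array(0L, d)
  mask[inside] <- 1L
  if (sum(mask) == 0L) {
    iz <- which.min(abs(zc - ctr[1])); iy <- which.min(abs(yc - ctr[2]))
    ix <- which.min(abs(xc - ctr[3]))
    mask[iz, iy, ix] <- 1L
  }

  # ---- CT: background + small bladder offset + bone ring (+ streaks) + noise
  ct <- array(config$ct_background, d) + config$soft_tissue_contrast * mask
  ry <- (yc - max(yc) / 2) / (0.45 * max(yc))
  rx <- (xc - max(xc) / 2) / (0.45 * max(xc))
  rnorm2 <- sqrt(outer(ry^2, rx^2, `+`))
  if (config$bone_ring) {
    ring <- rnorm2 >= 0.86 & rnorm2 <= 1.0
    for (k in seq_len(d[1])) ct[k, , ][ring] <- ct[k, , ][ring] + 600
  }
  if (config$streak_artifacts && config$streak_amplitude != 0) {
    theta <- atan2(outer(ry, rep(1, d[3])), outer(rep(1, d[2]), rx))
    streak <- config$streak_amplitude * cos(16 * theta) * pmin(rnorm2, 1)
    streak[rnorm2 > 0.86] <- 0
    for (k in seq_len(d[1])) ct[k, , ] <- ct[k, , ] + streak
  }
  ct <- with_seed(config$seed, ct + array(stats::rnorm(length(ct),
                                                       sd = config$noise_sd), d))

  # ---- PET: uptake_ratio x background inside the bladder with a hotter
  # central core (the dataset SUVmax), partial-volume blur on the fine
  # grid, then in-plane block-average to the coarse grid
  core <- array(0L, d)
  core[outer(outer(uz, uy, `+`), ux, `+`) <= 0.25] <- 1L  # half semi-axes
  if (sum(core) == 0L) core[which(mask == 1L)[1]] <- 1L
  rim <- config$pet_background * config$uptake_ratio
  petf <- config$pet_background * (1 - mask) + rim * mask +
    rim * (config$hot_core_ratio - 1) * core
  f <- config$pet_downsample_factor
  By <- matrix(0, d[2], d[2] %/% f); Bx <- matrix(0, d[3], d[3] %/% f)
  for (j in seq_len(ncol(By))) By[((j - 1) * f + 1):(j * f), j] <- 1 / f
  for (j in seq_len(ncol(Bx))) Bx[((j - 1) * f + 1):(j * f), j] <- 1 / f
  pet <- array(0, c(d[1], d[2] %/% f, d[3] %/% f))
  for (k in seq_len(d[1])) {
    sl <- blur2d(petf[k, , ], config$pet_blur_sigma)
    pet[k, , ] <- t(By) %*% sl %*% Bx
  }

  ct_vol <- volume(ct, spacing = sp, modality = "CT", patient_id = patient_id)
  pet_vol <- volume(pet, spacing = c(sp[1], sp[2] * f, sp[3] * f),
                    origin = c(0, (f - 1) / 2 * sp[2], (f - 1) / 2 * sp[3]),
                    modality = "PET", patient_id = patient_id)
  structure(list(ct = ct_vol, pet = pet_vol, true_mask = mask,
                 patient_id = patient_id, config = config),
            class = "suvseg_phantom_case")
}

#' Generate a cohort of phantom patients
#'
#' Draws per-patient jitter of bladder size, in-plane position, contrast,
#' uptake and noise from a seeded RNG, and sizes each patient's ellipsoid
#' along z so that the true mask occupies an exact, requested number of
#' slices (so cohort slice totals are controllable, e.g. 29 patients
#' totalling 845 bladder-bearing slices).
#'
#' @param n_patients number of patients (>= 1).
#' @param per_patient_slices integer scalar or length-`n_patients` vector:
#'   bladder-bearing slices per patient.
#' @param base_config [phantom_config()] that jitter is applied around.
#' @param seed cohort RNG seed.
#' @return List of `suvseg_phantom_case`, with distinct patient ids.
#' @export
generate_cohort <- function(n_patients, per_patient_slices = 8L,
                            base_config = phantom_config(), seed = 1L) {
  stopifnot(n_patients >= 1)
  ks <- rep_len(as.integer(per_patient_slices), n_patients)
  if (any(ks < 1L)) stop_suvseg("per_patient_slices must be >= 1",
                                class = "suvseg_config_error")
  lapply(seq_len(n_patients), function(p) {
    k <- ks[p]
    n_sl <- k + 4L
    # centre between the two central slices (k even) or on a slice (k odd);
    # semi-axis (k/2)*dz then covers exactly k voxel-centre planes
    c_sl <- if (k %% 2L == 1L) (n_sl + 1) / 2 else n_sl / 2 + 0.5
    jit <- with_seed(derive_seed(seed, paste0("cohort", p)), {
      list(inplane = stats::runif(2, 0.85, 1.15),
           centre_yx = stats::runif(2, 0.42, 0.58),
           contrast = stats::runif(1, 0.8, 1.2),
           uptake = stats::runif(1, 1.0, 1.4),
           noise = stats::runif(1, 0.8, 1.2),
           streak = stats::runif(1) < 0.3)
    })
    cfg <- base_config
    cfg$ct_shape[1] <- n_sl
    cfg$seed <- derive_seed(seed, paste0("phantom", p))
    cfg$bladder_center <- c((c_sl - 1) / (n_sl - 1), jit$centre_yx)
    cfg$bladder_semiaxes <- c(k / 2 * cfg$ct_spacing[1],
                              base_config$bladder_semiaxes[2] * jit$inplane[1],
                              base_config$bladder_semiaxes[3] * jit$inplane[2])
    cfg$soft_tissue_contrast <- base_config$soft_tissue_contrast * jit$contrast
    cfg$uptake_ratio <- base_config$uptake_ratio * jit$uptake
    cfg$noise_sd <- base_config$noise_sd * jit$noise
    cfg$streak_artifacts <- base_config$streak_artifacts || jit$streak
    generate_phantom(cfg, patient_id = sprintf("P%03d", p))
  })
}
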