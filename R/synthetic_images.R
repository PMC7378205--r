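#' Configuration for the synthetic worm-image generator
#'
#' Bundles the parameters of a single simulated Nile red micrograph: one
#' elongated, curved worm body carrying punctate bright foci (the
#' lysosome-related organelles where ingested Nile red accumulates), on a
#' noisy dark background optionally littered with small bright bacteria-like
#' blobs. The generated worm must be large enough to survive the pipeline's
#' minimum-region-size filter (3,000 px), and every artifact must be small
#' enough to be removed by it.
#'
#' @param image_shape integer vector `c(rows, cols)` of the image in pixels.
#' @param worm_area_px target worm body area in pixels; must be >= 3000.
#' @param n_foci number of bright organelle-like foci placed inside the body.
#' @param focus_intensity mean focus brightness on the 0-255 scale.
#' @param body_intensity mean body brightness (0-255).
#' @param background_intensity background level (0-255).
#' @param body_texture_sd SD of the per-pixel intensity speckle inside the
#'   body; this is what gives the body its texture, and hence its local
#'   entropy signature, relative to the smoother background.
#' @param background_noise_sd SD of the additive background noise.
#' @param n_artifacts number of small bright blobs outside the worm.
#' @param artifact_max_area_px maximum artifact area; must be < 3000 so the
#'   size filter deletes every artifact.
#' @param artifact_margin_px minimum gap (pixels) between any artifact and
#'   the worm body, kept at least as large as the widest texture window so
#'   that artifacts cannot perturb features computed inside the worm.
#' @param seed RNG seed; the generator is a pure function of its config.
#' @return An object of class `"worm_image_config"`.
#' @export
worm_image_config <- function(image_shape = c(256L, 256L),
                              worm_area_px = 8000,
                              n_foci = 12,
                              focus_intensity = 210,
                              body_intensity = 70,
                              background_intensity = 12,
                              body_texture_sd = 12,
                              background_noise_sd = 3,
                              n_artifacts = 3,
                              artifact_max_area_px = 400,
                              artifact_margin_px = 20,
                              seed = 1L) {
  cfg <- list(image_shape = as.integer(image_shape),
              worm_area_px = worm_area_px,
              n_foci = as.integer(n_foci),
              focus_intensity = focus_intensity,
              body_intensity = body_intensity,
              background_intensity = background_intensity,
              body_texture_sd = body_texture_sd,
              background_noise_sd = background_noise_sd,
              n_artifacts = as.integer(n_artifacts),
              artifact_max_area_px = artifact_max_area_px,
              artifact_margin_px = artifact_margin_px,
              seed = as.integer(seed))
  class(cfg) <- "worm_image_config"
  validate_worm_image_config(cfg)
  cfg
}

validate_worm_image_config <- function(cfg) {
  if (length(cfg$image_shape) != 2L || any(cfg$image_shape < 32L)) {
    stop("image_shape must be c(rows, cols) with both >= 32", call. = FALSE)
  }
  if (cfg$worm_area_px < 3000) {
    stop("worm_area_px must be >= 3000: a generated worm must survive the ",
         "minimum-region-size filter", call. = FALSE)
  }
  if (cfg$artifact_max_area_px >= 3000) {
    stop("artifact_max_area_px must be < 3000 so that artifacts are deleted ",
         "by the size filter", call. = FALSE)
  }
  ints <- c(cfg$focus_intensity, cfg$body_intensity, cfg$background_intensity)
  if (any(ints < 0 | ints > 255)) {
    stop("intensities must lie in [0, 255]", call. = FALSE)
  }
  if (cfg$background_noise_sd < 0 || cfg$body_texture_sd < 0) {
    stop("noise SDs must be non-negative", call. = FALSE)
  }
  invisible(cfg)
}

# Stamp disks of radius halfw[i] centred at backbone points pts[i, ] (row, col,
# continuous coordinates) into a logical mask.
stamp_disks <- function(pts, halfw, shape, mask = NULL) {
  if (is.null(mask)) mask <- matrix(FALSE, shape[1], shape[2])
  for (i in seq_len(nrow(pts))) {
    r <- halfw[i]
    if (r < 0.5) next
    ri <- ceiling(r)
    r0 <- max(1L, floor(pts[i, 1] - ri)); r1 <- min(shape[1], ceiling(pts[i, 1] + ri))
    c0 <- max(1L, floor(pts[i, 2] - ri)); c1 <- min(shape[2], ceiling(pts[i, 2] + ri))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - pts[i, 1])^2, (cc - pts[i, 2])^2, "+")
    mask[rr, cc] <- mask[rr, cc] | (d2 <= r * r)
  }
  mask
}

# Random smooth backbone: a heading random-walk with slowly varying curvature,
# steered back toward the image centre when it approaches the border.
draw_backbone <- function(len, shape, margin) {
  rows <- shape[1]; cols <- shape[2]
  lo_r <- margin; hi_r <- rows - margin
  lo_c <- margin; hi_c <- cols - margin
  p <- c(stats::runif(1, lo_r + 0.2 * (hi_r - lo_r), hi_r - 0.2 * (hi_r - lo_r)),
         stats::runif(1, lo_c + 0.2 * (hi_c - lo_c), hi_c - 0.2 * (hi_c - lo_c)))
  theta <- stats::runif(1, 0, 2 * pi)
  kappa <- 0
  pts <- matrix(NA_real_, len + 1L, 2L)
  pts[1L, ] <- p
  for (i in seq_len(len)) {
    q <- p + c(cos(theta), sin(theta))
    if (q[1] < lo_r || q[1] > hi_r || q[2] < lo_c || q[2] > hi_c) {
      # steer toward the centre and straighten out
      ctr <- c(rows, cols) / 2
      theta <- atan2(ctr[2] - p[2], ctr[1] - p[1]) + stats::rnorm(1, 0, 0.15)
      kappa <- 0
      q <- p + c(cos(theta), sin(theta))
      q[1] <- min(max(q[1], lo_r), hi_r)
      q[2] <- min(max(q[2], lo_c), hi_c)
    }
    p <- q
    pts[i + 1L, ] <- p
    kappa <- 0.92 * kappa + stats::rnorm(1, 0, 0.035)
    kappa <- min(max(kappa, -0.25), 0.25)
    theta <- theta + kappa
  }
  pts
}

#' Generate a ground-truth synthetic worm micrograph
#'
#' Renders one curved worm (random spline-like backbone with an elliptically
#' tapered width profile) with `n_foci` bright punctate foci inside the body,
#' additive Gaussian background noise, and `n_artifacts` small bright blobs
#' placed strictly outside the worm. The rendered body area is matched to
#' `worm_area_px` within +/- 2% by bisecting a global width scale. Alongside
#' the noisy RGB image, the generator records the true worm mask and the true
#' fluorescent units, defined operationally: the measurement chain
#' (grayscale, normalization, masking with the true mask, isodata
#' binarization, white-pixel count) applied to the noise-free rendering.
#' Pushing the noise-free image through the pipeline with an ideal mask must
#' therefore recover `true_fluorescent_units` exactly.
#'
#' The artifact stream is seeded independently of the worm/noise stream, so
#' two configs differing only in `n_artifacts` produce images that are
#' bit-identical outside the artifact pixels.
#'
#' @param config a [worm_image_config()].
#' @param norm_spec the [normalization_spec()] used when computing the
#'   ground-truth fluorescent units; defaults to the pipeline default.
#' @return An object of class `"worm_image"`: a list with `pixels` (rows x
#'   cols x 3 integer RGB array, 0-255), `clean_pixels` (same, noise- and
#'   artifact-free), `worm_mask` (logical matrix), `true_fluorescent_units`,
#'   and `config`.
#' @export
generate_worm_image <- function(config, norm_spec = normalization_spec()) {
  validate_worm_image_config(config)
  shape <- config$image_shape
  npix <- prod(shape)
  if (config$worm_area_px > 0.35 * npix) {
    stop(sprintf(paste0("worm of %d px does not fit an image of %d x %d; ",
                        "increase image_shape to at least %d x %d"),
                 round(config$worm_area_px), shape[1], shape[2],
                 ceiling(sqrt(config$worm_area_px / 0.35)),
                 ceiling(sqrt(config$worm_area_px / 0.35))), call. = FALSE)
  }

  res <- with_local_seed(config$seed, {
    A <- config$worm_area_px
    len <- max(40L, round(sqrt(6 * A)))
    w_max <- 2 * A / (pi * len)   # elliptic taper: area = w_max * len * pi / 2
    margin <- w_max + 4
    if (2 * margin + 10 > min(shape)) {
      stop("worm does not fit in image_shape; increase image_shape or reduce worm_area_px",
           call. = FALSE)
    }
    pts <- draw_backbone(len, shape, margin)
    s <- seq(0, 1, length.out = nrow(pts))
    halfw <- w_max * sqrt(pmax(0, 1 - (2 * s - 1)^2))

    # self-overlap of a curved body shrinks the rasterized area below the
    # analytic one; bisect a global width scale. The rendered area is
    # matched from above — within [A, 1.05 A] — so a worm configured at the
    # minimum legal area always survives the minimum-region-size filter.
    lo <- 0.5; hi <- 2.5
    mask <- NULL
    for (iter in 1:16) {
      mid <- (lo + hi) / 2
      mask <- stamp_disks(pts, halfw * mid, shape)
      a <- sum(mask)
      if (abs(a - 1.025 * A) <= 0.02 * A) break
      if (a < 1.025 * A) lo <- mid else hi <- mid
    }
    a <- sum(mask)
    if (a < A || a > 1.05 * A) {
      stop("could not match worm_area_px within 5%; try a larger image_shape",
           call. = FALSE)
    }

    # foci centres sampled from the body interior (erode by stamping with
    # reduced half-width) so foci stay inside the mask
    inner <- stamp_disks(pts, pmax(halfw * mid - 4, 0), shape)
    cand <- which(inner)
    foci_mask <- matrix(FALSE, shape[1], shape[2])
    if (config$n_foci > 0L && length(cand) > 0L) {
      ctr_idx <- sample(cand, config$n_foci, replace = length(cand) < config$n_foci)
      ctr <- cbind((ctr_idx - 1L) %% shape[1] + 1L, (ctr_idx - 1L) %/% shape[1] + 1L)
      radii <- sample(2:4, config$n_foci, replace = TRUE)
      foci_mask <- stamp_disks(ctr, radii, shape)
      foci_mask <- foci_mask & mask
    }

    clean <- matrix(config$background_intensity, shape[1], shape[2])
    nb <- sum(mask)
    clean[mask] <- config$body_intensity + stats::rnorm(nb, 0, config$body_texture_sd)
    nf <- sum(foci_mask)
    if (nf > 0) clean[foci_mask] <- config$focus_intensity + stats::rnorm(nf, 0, 20)
    clean <- round(clamp(clean, 0, 255))

    noisy <- clean
    if (config$background_noise_sd > 0) {
      noisy <- round(clamp(clean + stats::rnorm(npix, 0, config$background_noise_sd), 0, 255))
    }
    list(mask = mask, clean = clean, noisy = noisy)
  })

  # artifacts: independent stream, placed with a clearance of
  # artifact_margin_px around the worm and around each other so that no
  # background component can reach 3,000 px and no texture window straddles
  # worm and artifact
  noisy <- res$noisy
  if (config$n_artifacts > 0L) {
    noisy <- with_local_seed(config$seed + 500009L, {
      img <- res$noisy
      occupied <- res$mask
      for (k in seq_len(config$n_artifacts)) {
        area <- stats::runif(1, min(30, config$artifact_max_area_px),
                             config$artifact_max_area_px)
        ra <- sqrt(area / pi)
        placed <- FALSE
        for (try in 1:200) {
          cr <- stats::runif(1, ra + 1, shape[1] - ra - 1)
          cc <- stats::runif(1, ra + 1, shape[2] - ra - 1)
          reach <- ceiling(ra + config$artifact_margin_px)
          r0 <- max(1L, floor(cr - reach)); r1 <- min(shape[1], ceiling(cr + reach))
          c0 <- max(1L, floor(cc - reach)); c1 <- min(shape[2], ceiling(cc + reach))
          if (!any(occupied[r0:r1, c0:c1])) {
            blob <- stamp_disks(matrix(c(cr, cc), 1L), ra, shape)
            nbl <- sum(blob)
            img[blob] <- round(clamp(0.9 * config$focus_intensity +
                                       stats::rnorm(nbl, 0, 15), 0, 255))
            occupied <- occupied | blob
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("could not place an artifact away from the worm; reduce ",
               "n_artifacts/artifact_max_area_px or enlarge image_shape",
               call. = FALSE)
        }
      }
      img
    })
  }

  pixels <- gray_to_rgb(noisy)
  clean_pixels <- gray_to_rgb(res$clean)

  # operational ground truth: the measurement chain on the noise-free image
  # under the true mask
  g <- to_grayscale(clean_pixels)
  nrm <- normalize_image(g, norm_spec)
  fg <- nrm[res$mask]
  tfu <- if (length(unique(fg)) < 2L) 0L else {
    thr <- isodata_threshold(fg)
    sum(fg > thr)
  }

  structure(list(pixels = pixels,
                 clean_pixels = clean_pixels,
                 worm_mask = res$mask,
                 true_fluorescent_units = as.integer(tfu),
                 config = config),
            class = "worm_image")
}

# red-dominant RGB rendering of a grey intensity matrix (Rhodamine-filter
# Nile red images are red/orange); channels are rounded 8-bit
gray_to_rgb <- function(v) {
  arr <- array(0, dim = c(nrow(v), ncol(v), 3L))
  arr[, , 1L] <- v
  arr[, , 2L] <- round(0.35 * v)
  arr[, , 3L] <- round(0.15 * v)
  arr
}

#' @export
print.worm_image <- function(x, ...) {
  cat(sprintf("<worm_image> %d x %d px, worm area %d px, %d true fluorescent units\n",
              dim(x$pixels)[1], dim(x$pixels)[2], sum(x$worm_mask),
              x$true_fluorescent_units))
  invisible(x)
}
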