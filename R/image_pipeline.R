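#' Convert an RGB image to 8-bit grayscale
#'
#' Luminance-weighted channel combination (ITU-R BT.601 weights 0.299, 0.587,
#' 0.114, the convention of common image-analysis software), rounded to the
#' 0-255 integer grid. Grayscale input is returned unchanged, so the
#' operation is idempotent.
#'
#' @param image a rows x cols x 3 RGB array or a rows x cols matrix, values
#'   in [0, 255].
#' @return a rows x cols numeric matrix of integers in [0, 255].
#' @export
to_grayscale <- function(image) {
  if (is.matrix(image)) {
    check_intensity_range(image)
    return(image)
  }
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("expected an RGB array (rows x cols x 3) or a grayscale matrix",
         call. = FALSE)
  }
  check_intensity_range(image)
  g <- 0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
  round(g)
}

check_intensity_range <- function(x) {
  if (length(x) == 0L) stop("empty image", call. = FALSE)
  rng <- range(x)
  if (rng[1] < 0 || rng[2] > 255) {
    stop("intensities must lie in [0, 255]", call. = FALSE)
  }
  invisible(x)
}

#' Brightness/contrast normalization target
#'
#' The normalization stage applies an affine intensity map so the image
#' attains a prescribed mean and standard deviation. The targets are
#' dimensionless and interpreted on a declared scale convention:
#' `"percent"` (default) reads them as percent of the full 8-bit range, so
#' the defaults mean 1.2 -> 3.06 and SD 6.6 -> 16.83 on the 0-255 scale —
#' a very dark background with a narrow stretched intensity band, the regime
#' a fluorescence micrograph of a single bright worm is pushed into before
#' segmentation; `"intensity"` reads them directly on the 0-255 scale.
#'
#' @param target_mean dimensionless target mean (default 1.2).
#' @param target_sd dimensionless target SD (default 6.6); must be > 0.
#' @param scale_convention `"percent"` or `"intensity"`.
#' @return an object of class `"normalization_spec"`.
#' @export
normalization_spec <- function(target_mean = 1.2, target_sd = 6.6,
                               scale_convention = c("percent", "intensity")) {
  scale_convention <- match.arg(scale_convention)
  if (target_sd <= 0) stop("target_sd must be > 0", call. = FALSE)
  structure(list(target_mean = target_mean, target_sd = target_sd,
                 scale_convention = scale_convention),
            class = "normalization_spec")
}

#' Normalize an 8-bit grayscale image to a target mean and SD
#'
#' Computes the affine transform v' = a*v + b whose output has exactly the
#' spec's target mean and SD (on the declared scale), then clips to
#' [0, 255]. The gain, offset and the achieved pre-clipping moments are
#' attached as attributes for audit. Because the map is affine, downstream
#' stages that are affine-equivariant (isodata thresholding in particular)
#' give results independent of the incidental gain of the acquisition.
#'
#' @param image grayscale matrix, values in [0, 255].
#' @param spec a [normalization_spec()].
#' @return the normalized image (numeric matrix clipped to [0, 255]) with
#'   attributes `gain`, `offset`, `achieved_mean`, `achieved_sd`.
#' @export
normalize_image <- function(image, spec = normalization_spec()) {
  if (!is.matrix(image)) stop("normalize_image expects a grayscale matrix", call. = FALSE)
  check_intensity_range(image)
  s <- stats::sd(image)
  if (s == 0) stop("contrast undefined: image has zero intensity variance", call. = FALSE)
  tm <- spec$target_mean
  tsd <- spec$target_sd
  if (spec$scale_convention == "percent") {
    tm <- tm / 100 * 255
    tsd <- tsd / 100 * 255
  }
  a <- tsd / s
  b <- tm - a * mean(image)
  out <- a * image + b
  achieved <- c(mean(out), stats::sd(out))
  out <- clamp(out, 0, 255)
  attr(out, "gain") <- a
  attr(out, "offset") <- b
  attr(out, "achieved_mean") <- achieved[1]
  attr(out, "achieved_sd") <- achieved[2]
  out
}

# circular neighbourhood kernel (dx^2 + dy^2 <= r^2), centre included
disk_kernel <- function(radius) {
  r <- ceiling(radius)
  d <- 2L * r + 1L
  off <- (-r):r
  k <- outer(off^2, off^2, "+") <= radius^2
  storage.mode(k) <- "double"
  k
}

#' Local Shannon entropy features
#'
#' For each requested window radius, every pixel receives the Shannon
#' entropy (in bits) of the intensity histogram over its circular
#' neighbourhood, the texture feature on which the worm/background pixel
#' classifier is trained: the speckled worm body has high local entropy, the
#' smooth background low. Intensities are binned into `nbins` equal-width
#' bins on [0, 256) before histogramming. Windows are clipped at the image
#' border (only in-image pixels contribute). Computed by per-bin indicator
#' convolution (FFT), so cost grows with `nbins`, not window size.
#'
#' @param image grayscale matrix, values in [0, 255] (fractional values are
#'   fine; binning handles them).
#' @param radii integer vector of window radii (>= 1).
#' @param nbins number of histogram bins (default 32).
#' @return rows x cols x length(radii) array; slices named `entropy_r<r>`.
#' @export
entropy_features <- function(image, radii = c(2, 4, 8), nbins = 32L) {
  if (!is.matrix(image)) stop("entropy_features expects a grayscale matrix", call. = FALSE)
  check_intensity_range(image)
  if (any(radii < 1)) stop("radii must be >= 1", call. = FALSE)
  if (any(2 * radii + 1 > min(dim(image)))) {
    stop("window radius larger than the image", call. = FALSE)
  }
  bins <- pmin(floor(image / 256 * nbins), nbins - 1L)
  present <- sort(unique(as.vector(bins)))
  ones <- matrix(1, nrow(image), ncol(image))
  out <- array(0, dim = c(nrow(image), ncol(image), length(radii)))
  dimnames(out) <- list(NULL, NULL, paste0("entropy_r", radii))
  for (j in seq_along(radii)) {
    k <- disk_kernel(radii[j])
    valid <- EBImage::filter2(ones, k, boundary = 0)
    h <- matrix(0, nrow(image), ncol(image))
    for (b in present) {
      cnt <- EBImage::filter2((bins == b) * 1, k, boundary = 0)
      p <- pmax(cnt, 0) / valid
      nz <- p > 1e-12
      h[nz] <- h[nz] - p[nz] * log2(p[nz])
    }
    out[, , j] <- pmax(h, 0)
  }
  out
}

#' Label connected components of a binary mask
#'
#' 8-connectivity by default (the common default for blob analysis);
#' 4-connectivity available. Labels are assigned in raster order of each
#' component's first pixel.
#'
#' @param mask logical matrix.
#' @param connectivity 8 or 4.
#' @return integer matrix of component labels (0 = background), with
#'   attribute `areas`: named integer vector of component areas.
#' @export
label_components <- function(mask, connectivity = 8) {
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  fg <- which(mask)
  if (length(fg) == 0L) {
    attr(labels, "areas") <- integer(0)
    return(labels)
  }
  id <- matrix(0L, nr, nc)
  id[fg] <- seq_along(fg)
  rr <- (fg - 1L) %% nr + 1L
  cc <- (fg - 1L) %/% nr + 1L
  shifts <- list(c(1L, 0L), c(0L, 1L))               # S, E
  if (connectivity == 8) {
    shifts <- c(shifts, list(c(1L, 1L), c(-1L, 1L))) # SE, NE
  } else if (connectivity != 4) {
    stop("connectivity must be 4 or 8", call. = FALSE)
  }
  edges <- integer(0)
  for (sh in shifts) {
    r2 <- rr + sh[1]; c2 <- cc + sh[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) next
    nb <- id[cbind(r2[ok], c2[ok])]
    hit <- nb > 0L
    if (any(hit)) {
      edges <- c(edges, rbind(id[fg][ok][hit], nb[hit]))
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(fg), directed = FALSE)
  memb <- igraph::components(g)$membership
  # relabel in raster order of first occurrence
  first <- match(unique(memb), memb)
  ord <- order(fg[first])
  relab <- integer(max(memb))
  relab[unique(memb)[ord]] <- seq_along(ord)
  labels[fg] <- relab[memb]
  areas <- tabulate(labels[fg])
  names(areas) <- seq_along(areas)
  attr(labels, "areas") <- areas
  labels
}

#' Construct a worm segmentation from a binary mask
#'
#' @param mask logical matrix (TRUE = worm).
#' @param connectivity component connectivity (default 8).
#' @return object of class `"worm_segmentation"`: list with `mask`, `labels`
#'   (integer component matrix) and `areas` (per-component pixel counts).
#' @export
worm_segmentation <- function(mask, connectivity = 8) {
  labels <- label_components(mask, connectivity)
  structure(list(mask = labels > 0L, labels = labels,
                 areas = attr(labels, "areas"),
                 connectivity = connectivity),
            class = "worm_segmentation")
}

#' Delete regions smaller than a minimum area
#'
#' Every connected region with area strictly smaller than `min_area` pixels
#' is removed; a region of exactly `min_area` is retained. The default of
#' 3,000 px is the size below which candidate regions are bacteria or debris
#' rather than a worm. Surviving regions are relabeled 1..k in their
#' original order. An empty result is allowed.
#'
#' @param seg a [worm_segmentation()].
#' @param min_area minimum surviving region area in pixels (default 3000).
#' @return a `"worm_segmentation"` containing only regions with
#'   area >= `min_area`.
#' @export
remove_small_regions <- function(seg, min_area = 3000) {
  stopifnot(inherits(seg, "worm_segmentation"))
  keep <- which(seg$areas >= min_area)
  labels <- seg$labels
  relab <- integer(length(seg$areas))
  relab[keep] <- seq_along(keep)
  fg <- labels > 0L
  labels[fg] <- relab[labels[fg]]
  structure(list(mask = labels > 0L, labels = labels,
                 areas = stats::setNames(unname(seg$areas[keep]),
                                         seq_along(keep)),
                 connectivity = seg$connectivity),
            class = "worm_segmentation")
}

#' Multiply a segmentation mask into a normalized image
#'
#' Pixel-wise product of the binary mask with the normalized intensities:
#' background becomes exactly 0, worm pixels keep their normalized values.
#'
#' @param seg a [worm_segmentation()].
#' @param normalized_image numeric matrix of matching shape.
#' @return masked image matrix.
#' @export
apply_mask <- function(seg, normalized_image) {
  stopifnot(inherits(seg, "worm_segmentation"))
  if (!all(dim(seg$mask) == dim(normalized_image))) {
    stop("mask and image shapes differ", call. = FALSE)
  }
  out <- normalized_image * (seg$mask * 1)
  attributes(out) <- list(dim = dim(out))
  out
}

#' Isodata ("default") threshold of an intensity sample
#'
#' The iterative intermeans rule: starting from the midpoint of the
#' occupied intensity range (the initialization of the common
#' default-threshold implementations, which keeps the iteration in the gap
#' between a dominant dark mode and a small bright mode instead of stalling
#' at a fixed point inside the dark mode), iterate
#' T <- (mean(v <= T) + mean(v > T)) / 2 until the fixed point
#' T = (mean below + mean above) / 2 is reached. For integer-valued data the
#' returned T satisfies floor(T) = t where t is an integer fixed point of
#' the histogram form t = floor((mean(v <= t) + mean(v > t)) / 2), which an
#' exhaustive scan over all 256 candidate thresholds verifies. The rule is
#' equivariant under affine intensity maps with positive gain.
#'
#' @param v numeric vector of intensities with at least two distinct values.
#' @return the converged threshold (numeric scalar); classify white as
#'   `v > T`.
#' @export
isodata_threshold <- function(v) {
  v <- as.numeric(v)
  if (length(unique(v)) < 2L) {
    stop("threshold undefined: fewer than two distinct intensities", call. = FALSE)
  }
  t_cur <- (min(v) + max(v)) / 2
  for (iter in 1:200) {
    lo <- v[v <= t_cur]
    hi <- v[v > t_cur]
    if (length(hi) == 0L) { t_cur <- max(v[v < max(v)]); next }
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t_cur) < 1e-9) return(t_new)
    t_cur <- t_new
  }
  t_cur
}

#' Binarize a masked image with the default (isodata) threshold
#'
#' The threshold is computed on the foreground intensities only — the
#' mask-interior pixels — never on the exact-zero background introduced by
#' masking, so T reflects the worm's intensity structure, not its size.
#' Pixels strictly greater than T become white.
#'
#' @param masked_image matrix as produced by [apply_mask()].
#' @param foreground logical matrix marking foreground pixels; defaults to
#'   `masked_image > 0`.
#' @return list with `binary` (logical matrix, TRUE = white) and
#'   `threshold`.
#' @export
binarize_default_threshold <- function(masked_image, foreground = NULL) {
  if (is.null(foreground)) foreground <- masked_image > 0
  if (!all(dim(foreground) == dim(masked_image))) {
    stop("foreground and image shapes differ", call. = FALSE)
  }
  v <- masked_image[foreground]
  if (length(unique(v)) < 2L) {
    stop("threshold undefined: constant foreground", call. = FALSE)
  }
  thr <- isodata_threshold(v)
  binary <- matrix(FALSE, nrow(masked_image), ncol(masked_image))
  binary[foreground] <- masked_image[foreground] > thr
  list(binary = binary, threshold = thr)
}

#' Count fluorescent units of a binarized worm image
#'
#' The fluorescent units of a single worm are the total area of white pixels
#' of its binarized, masked image (a dimensionless pixel-area count).
#'
#' @param binary logical matrix (TRUE = white), or the list returned by
#'   [binarize_default_threshold()].
#' @param seg optional [worm_segmentation()] supplying the worm area.
#' @param image_id optional identifier carried into the result.
#' @return one-row data.frame: `image_id`, `fluorescent_units`,
#'   `worm_area_px`.
#' @export
quantify_fluorescence <- function(binary, seg = NULL, image_id = NA_character_) {
  if (is.list(binary) && !is.null(binary$binary)) binary <- binary$binary
  units <- sum(binary)
  area <- if (is.null(seg)) NA_integer_ else sum(seg$mask)
  if (!is.na(area) && units > area) {
    stop("white pixels exceed worm area: binarization was not restricted to the mask",
         call. = FALSE)
  }
  data.frame(image_id = image_id, fluorescent_units = as.integer(units),
             worm_area_px = as.integer(area), stringsAsFactors = FALSE)
}

#' Measure a single worm micrograph end to end
#'
#' Full quantification chain: grayscale conversion, pixel classification of
#' the original grayscale image, minimum-size filtering, multiplication of
#' the surviving mask into the brightness/contrast-normalized version of
#' the original, isodata binarization of the mask interior, white-pixel
#' counting. Classification and normalization are parallel branches off the
#' original image: the classifier sees the unadjusted grayscale (so the
#' worm mask cannot depend on how bright blobs elsewhere in the frame tilt
#' the global normalization moments), while the mask is applied to the
#' normalized intensities. Together with the affine-equivariance of the
#' isodata rule this makes the measured units exactly invariant to
#' sub-threshold artifacts outside the worm. If more than one region
#' survives the size filter all are kept and a warning is emitted (set
#' `largest_only = TRUE` to keep the largest region instead). An empty mask
#' yields 0 fluorescent units.
#'
#' @param image RGB array or grayscale matrix (0-255).
#' @param model a [train_pixel_classifier()] model trained on unadjusted
#'   grayscale images.
#' @param spec the [normalization_spec()] for the quantification branch.
#' @param min_area minimum surviving region area (default 3000 px).
#' @param largest_only keep only the largest surviving region.
#' @param image_id identifier for the measurement row.
#' @return one-row data.frame as in [quantify_fluorescence()].
#' @export
measure_worm_image <- function(image, model, spec = normalization_spec(),
                               min_area = 3000, largest_only = FALSE,
                               image_id = NA_character_) {
  g <- to_grayscale(image)
  nrm <- normalize_image(g, spec)
  seg <- classify_pixels(model, g)
  seg <- remove_small_regions(seg, min_area)
  if (length(seg$areas) > 1L) {
    if (largest_only) {
      keep <- which.max(seg$areas)
      labels <- seg$labels
      labels[labels != keep] <- 0L
      labels[labels == keep] <- 1L
      seg <- structure(list(mask = labels > 0L, labels = labels,
                            areas = stats::setNames(max(seg$areas), "1"),
                            connectivity = seg$connectivity),
                       class = "worm_segmentation")
    } else {
      warning(sprintf("%d regions survive the size filter; keeping all",
                      length(seg$areas)), call. = FALSE)
    }
  }
  if (!any(seg$mask)) {
    return(data.frame(image_id = image_id, fluorescent_units = 0L,
                      worm_area_px = 0L, stringsAsFactors = FALSE))
  }
  masked <- apply_mask(seg, nrm)
  fgv <- masked[seg$mask]
  if (length(unique(fgv)) < 2L) {
    return(data.frame(image_id = image_id, fluorescent_units = 0L,
                      worm_area_px = as.integer(sum(seg$mask)),
                      stringsAsFactors = FALSE))
  }
  bin <- binarize_default_threshold(masked, foreground = seg$mask)
  quantify_fluorescence(bin$binary, seg, image_id)
}
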