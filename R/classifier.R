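#' Default feature specification for pixel classification
#'
#' The classifier decides worm vs background per pixel from a small texture
#' feature vector: the raw (normalized) intensity plus local Shannon entropy
#' at several window radii. Entropy is the feature that carries the texture
#' contrast between the speckled worm body and the smooth background; raw
#' intensity adds the brightness contrast.
#'
#' @param raw_intensity include the pixel intensity itself.
#' @param entropy_radii window radii for [entropy_features()].
#' @param nbins histogram bins used by the entropy filter.
#' @return object of class `"feature_spec"`.
#' @export
feature_spec <- function(raw_intensity = TRUE, entropy_radii = c(2, 4, 8),
                         nbins = 32L) {
  if (!raw_intensity && length(entropy_radii) == 0L) {
    stop("feature_spec must contain at least one feature", call. = FALSE)
  }
  structure(list(raw_intensity = raw_intensity,
                 entropy_radii = entropy_radii, nbins = as.integer(nbins)),
            class = "feature_spec")
}

feature_names <- function(spec) {
  c(if (spec$raw_intensity) "intensity",
    if (length(spec$entropy_radii)) paste0("entropy_r", spec$entropy_radii))
}

#' Compute the per-pixel feature stack for an image
#'
#' @param image normalized grayscale matrix (values in [0, 255]).
#' @param spec a [feature_spec()].
#' @return rows x cols x n_features array with named slices.
#' @export
pixel_features <- function(image, spec = feature_spec()) {
  stopifnot(inherits(spec, "feature_spec"))
  layers <- list()
  if (spec$raw_intensity) layers$intensity <- image
  if (length(spec$entropy_radii)) {
    ent <- entropy_features(image, spec$entropy_radii, spec$nbins)
    for (j in seq_along(spec$entropy_radii)) {
      layers[[paste0("entropy_r", spec$entropy_radii[j])]] <- ent[, , j]
    }
  }
  out <- array(0, dim = c(nrow(image), ncol(image), length(layers)))
  dimnames(out) <- list(NULL, NULL, names(layers))
  for (j in seq_along(layers)) out[, , j] <- layers[[j]]
  out
}

features_to_df <- function(stack) {
  nf <- dim(stack)[3]
  df <- as.data.frame(matrix(stack, ncol = nf))
  names(df) <- dimnames(stack)[[3]]
  df
}

#' Train the worm/background pixel classifier
#'
#' Fits a pruned decision tree (CART with the entropy/information split
#' criterion and cost-complexity pruning — a pruned-tree surrogate of the
#' C4.5 family) on per-pixel (feature, label) pairs drawn from normalized
#' training images with known worm masks. Pixels are subsampled per image,
#' stratified by class, to keep training tractable; training is
#' deterministic given images, masks and `seed`.
#'
#' @param images list of grayscale matrices (or a single matrix); the
#'   pipeline trains on unadjusted 8-bit grayscale images and classifies
#'   the same representation, see [measure_worm_image()].
#' @param masks list of logical truth masks (TRUE = worm) matching `images`.
#' @param spec a [feature_spec()].
#' @param max_pixels_per_image per-image subsample cap (default 4000).
#' @param seed RNG seed for the subsample and the pruning cross-validation.
#' @return object of class `"segmentation_model"`: the pruned `rpart` tree,
#'   the feature spec and the class labels.
#' @export
train_pixel_classifier <- function(images, masks, spec = feature_spec(),
                                   max_pixels_per_image = 4000L, seed = 1L) {
  if (is.matrix(images)) images <- list(images)
  if (is.matrix(masks)) masks <- list(masks)
  if (length(images) != length(masks)) {
    stop("images and masks must have equal length", call. = FALSE)
  }
  dfs <- with_local_seed(seed, {
    lapply(seq_along(images), function(i) {
      img <- images[[i]]; msk <- masks[[i]]
      if (!all(dim(img) == dim(msk))) {
        stop("image and mask shapes differ", call. = FALSE)
      }
      st <- pixel_features(img, spec)
      df <- features_to_df(st)
      df$class <- factor(ifelse(as.vector(msk), "worm", "background"),
                         levels = c("background", "worm"))
      # stratified subsample so a small worm is not swamped by background
      take <- unlist(lapply(split(seq_len(nrow(df)), df$class), function(ix) {
        if (length(ix) > max_pixels_per_image / 2) {
          sample(ix, max_pixels_per_image / 2)
        } else ix
      }), use.names = FALSE)
      df[take, , drop = FALSE]
    })
  })
  train <- do.call(rbind, dfs)
  if (length(unique(train$class)) < 2L) {
    stop("training labels cover a single class; both worm and background ",
         "pixels are required", call. = FALSE)
  }
  tree <- with_local_seed(seed, {
    fit <- rpart::rpart(class ~ ., data = train, method = "class",
                        parms = list(split = "information"),
                        control = rpart::rpart.control(cp = 1e-3,
                                                       minsplit = 20,
                                                       xval = 10,
                                                       maxsurrogate = 0))
    cpt <- fit$cptable
    best <- cpt[which.min(cpt[, "xerror"]), "CP"]
    rpart::prune(fit, cp = best)
  })
  structure(list(tree = tree, feature_spec = spec,
                 classes = c("background", "worm")),
            class = "segmentation_model")
}

#' Classify every pixel of an image into worm or background
#'
#' Computes the model's feature stack on the image, predicts a class for
#' every pixel and returns the resulting segmentation with its connected
#' components. The image must be in the same photometric representation as
#' the training images (the pipeline uses the unadjusted 8-bit grayscale
#' for both).
#'
#' @param model a [train_pixel_classifier()] model.
#' @param image grayscale matrix.
#' @param connectivity component connectivity (default 8).
#' @return a [worm_segmentation()].
#' @export
classify_pixels <- function(model, image, connectivity = 8) {
  if (!inherits(model, "segmentation_model")) {
    stop("model must be a segmentation_model", call. = FALSE)
  }
  st <- pixel_features(image, model$feature_spec)
  df <- features_to_df(st)
  need <- attr(stats::terms(model$tree), "term.labels")
  if (!all(need %in% names(df))) {
    stop(sprintf("feature_spec mismatch: model needs {%s}, image stack has {%s}",
                 paste(need, collapse = ", "),
                 paste(names(df), collapse = ", ")), call. = FALSE)
  }
  cls <- predict(model$tree, df, type = "class")
  mask <- matrix(cls == "worm", nrow(image), ncol(image))
  worm_segmentation(mask, connectivity)
}

#' Serialize a segmentation model to a single portable file
#'
#' The fitted tree plus its feature spec round-trip through one RDS file
#' with identical predictions on reload.
#'
#' @param model a `"segmentation_model"`.
#' @param path file path.
#' @export
save_segmentation_model <- function(model, path) {
  stopifnot(inherits(model, "segmentation_model"))
  saveRDS(model, path, version = 2)
  invisible(path)
}

#' @rdname save_segmentation_model
#' @export
load_segmentation_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "segmentation_model")) {
    stop("file does not contain a segmentation_model", call. = FALSE)
  }
  model
}
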