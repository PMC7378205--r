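# file interfaces: 8-bit TIFF images, CSV logs and tables

#' Read and write worm micrographs as 8-bit TIFF
#'
#' Images are held in-package as 0-255 numeric arrays (rows x cols x 3 for
#' RGB, matrix for grey); on disk they are standard 8-bit TIFFs.
#'
#' @param image array or matrix with values in [0, 255].
#' @param path file path.
#' @return `write_worm_tiff`: the path, invisibly. `read_worm_tiff`: the
#'   image array (0-255).
#' @export
write_worm_tiff <- function(image, path) {
  check_intensity_range(image)
  tiff::writeTIFF(image / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_worm_tiff
#' @export
read_worm_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  round(img * 255)
}

#' Write the ground-truth sidecar of a set of synthetic images
#'
#' One row per image: identifier, true worm area, true fluorescent units.
#'
#' @param images named list of [generate_worm_image()] objects; names are
#'   the image ids.
#' @param path CSV path.
#' @export
write_truth_sidecar <- function(images, path) {
  if (is.null(names(images))) names(images) <- sprintf("img%03d", seq_along(images))
  df <- do.call(rbind, lapply(names(images), function(id) {
    data.frame(image_id = id,
               worm_area_px = sum(images[[id]]$worm_mask),
               true_fluorescent_units = images[[id]]$true_fluorescent_units,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a survival observation log from CSV
#'
#' Expected columns: `well_id`, `condition`, `day`, `n_alive`, `n_total`.
#' The log is validated on read.
#'
#' @param path CSV path.
#' @return validated survival data.frame.
#' @export
read_survival_log <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_survival_data(d)
  d
}

#' @rdname read_survival_log
#' @param data survival data.frame.
#' @export
write_survival_log <- function(data, path) {
  validate_survival_data(data)
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-worm fluorescence measurement table from CSV
#'
#' @param path CSV path; needs at least a `fluorescent_units` column.
#' @return data.frame.
#' @export
read_worm_measurements <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"fluorescent_units" %in% names(d)) {
    stop("measurement table lacks a fluorescent_units column", call. = FALSE)
  }
  d
}

#' Read a plate map from CSV
#'
#' @param path CSV path; needs columns `well_id`, `condition`, `experiment`.
#' @return data.frame.
#' @export
read_plate_map <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well_id", "condition", "experiment")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("plate map lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d
}
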