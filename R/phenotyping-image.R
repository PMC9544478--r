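#' Class codes of segmentation label images
#'
#' Label images are integer matrices with codes 0 = background, 1 = vital
#' tissue, 2 = necrotic tissue, 3 = scale label (the white reference used to
#' normalise areas across zoom levels).
#'
#' @format A named integer vector.
#' @export
pixel_classes <- c(background = 0L, vital = 1L, necrotic = 2L, scale_label = 3L)

#' Read / write a segmentation label image
#'
#' Label maps are stored as single-channel PNG (or TIFF, if the `tiff`
#' package is installed) with the integer class code in the pixel value
#' (`code / 255` in the file).
#'
#' @param path File path (`.png`, `.tif`/`.tiff`).
#' @return `read_label_image()`: an integer matrix of class codes.
#' @export
read_label_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        abort("Reading TIFF label maps requires the 'tiff' package.")
      }
      tiff::readTIFF(path)
    },
    abort(sprintf("Unsupported label-image format '%s'.", ext)))
  if (length(dim(img)) == 3) img <- img[, , 1]
  m <- round(img * 255)
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_label_image
#' @param image Integer matrix of class codes.
#' @export
write_label_image <- function(image, path) {
  check_label_image(image)
  png::writePNG(image / 255, path)
  invisible(path)
}

check_label_image <- function(image) {
  if (!is.matrix(image) || length(image) == 0) {
    abort("A label image must be a non-empty integer matrix.")
  }
  bad <- setdiff(unique(as.integer(image)), unname(pixel_classes))
  if (length(bad)) {
    abort(sprintf("Unknown class code(s) in label image: %s.",
                  paste(bad, collapse = ", ")))
  }
  invisible(image)
}

#' Count pixels per segmentation class
#'
#' Exact histogram of the class codes of a label image, the raw material for
#' all leaf-area measures.
#'
#' @param image Integer matrix of class codes (see [pixel_classes]).
#' @return A tibble with columns `class`, `code`, `pixels`; every class is
#'   reported (zero counts included) and counts sum to the grid size.
#' @examples
#' img <- matrix(0L, 10, 10); img[3:5, 3:5] <- 1L
#' count_class_pixels(img)
#' @export
count_class_pixels <- function(image) {
  check_label_image(image)
  tab <- tabulate(as.integer(image) + 1L, nbins = 4L)
  tibble::tibble(class = names(pixel_classes), code = unname(pixel_classes),
                 pixels = tab)
}

#' Calibrate raw pixel counts by the in-image scale label
#'
#' Converts raw class pixel counts into areas in units of the scale label:
#' `normalized = pixels * nominal_label_area / label_pixels`. Because the
#' label is photographed in the same frame, the normalised areas are
#' invariant to zoom changes between imaging days. The physical area of the
#' label is not part of the imaging record; with the default
#' `nominal_label_area = 1` areas are expressed in label units.
#'
#' @param counts A tibble from [count_class_pixels()], or a label-image
#'   matrix (counted on the fly).
#' @param nominal_label_area Physical (or nominal) area of the scale label.
#' @param label_pixels Measured label pixels; defaults to the `scale_label`
#'   count in `counts` (supply explicitly when a paired calibrator image is
#'   used for the day).
#' @return The counts tibble with an added `area` column.
#' @examples
#' img <- matrix(0L, 50, 50); img[1:10, 1:10] <- 3L; img[20:40, 20:40] <- 1L
#' calibrate_area(count_class_pixels(img))
#' @export
calibrate_area <- function(counts, nominal_label_area = 1,
                           label_pixels = NULL) {
  if (is.matrix(counts)) counts <- count_class_pixels(counts)
  if (is.null(label_pixels)) {
    label_pixels <- counts$pixels[counts$class == "scale_label"]
  }
  if (length(label_pixels) != 1 || is.na(label_pixels) || label_pixels <= 0) {
    abort("No calibrator found: the scale label has zero pixels and no `label_pixels` was supplied.")
  }
  dplyr::mutate(counts, area = .data$pixels * nominal_label_area / label_pixels)
}

#' Percentage of vital tissue
#'
#' `100 * vital / (vital + necrotic)`, the per-plant vitality measure.
#' Background is excluded deliberately: it dominates the frame and carries no
#' information about the plant. A plant with neither vital nor necrotic
#' pixels (absent plant) yields `NA` with a warning.
#'
#' @param vital,necrotic Vital and necrotic areas or pixel counts
#'   (vectorised).
#' @return Percent vital tissue in `[0, 100]` (or `NA`).
#' @examples
#' vitality_percent(979, 21) # 97.9
#' @export
vitality_percent <- function(vital, necrotic) {
  if (any(vital < 0 | necrotic < 0, na.rm = TRUE)) {
    abort("Areas must be non-negative.")
  }
  total <- vital + necrotic
  if (any(total == 0, na.rm = TRUE)) {
    warn("Plant absent (vital + necrotic = 0): vitality undefined, returning NA.")
  }
  ifelse(total > 0, 100 * vital / total, NA_real_)
}

#' Classify a line as drought tolerant
#'
#' A line is called tolerant when its mean vital leaf area across replicates
#' is strictly greater than 50%. Ties at exactly 50% are non-tolerant.
#'
#' @param per_replicate_percents Numeric vector of per-replicate vitality
#'   percentages; `NA`s (missing images) are dropped.
#' @return `TRUE`/`FALSE`.
#' @examples
#' classify_tolerant(c(100, 100, 100, 100, 90)) # TRUE
#' classify_tolerant(c(50, 50, 50))             # FALSE (strict)
#' @export
classify_tolerant <- function(per_replicate_percents) {
  x <- per_replicate_percents[!is.na(per_replicate_percents)]
  if (!length(x)) abort("No replicate vitality values supplied.")
  mean(x) > 50
}

#' Regression check of disc-assay linearity
#'
#' In the disc assay, known numbers of punched vital/necrotic leaf discs are
#' photographed; pixel counts must scale linearly with disc number for the
#' segmentation-based area measure to be trusted. Per class, regresses pixel
#' count on disc number.
#'
#' @param data A tibble with columns `class` (`"vital"`/`"necrotic"`),
#'   `n_discs`, `pixels`.
#' @return A tibble per class: `slope` (pixels per disc), `intercept`,
#'   `r_squared`, `n`.
#' @export
disc_linearity_check <- function(data) {
  stopifnot(all(c("class", "n_discs", "pixels") %in% names(data)))
  data %>%
    dplyr::group_by(.data$class) %>%
    dplyr::group_modify(function(d, key) {
      if (dplyr::n_distinct(d$n_discs) < 2) {
        abort(sprintf("Class '%s' has a single disc-count value; cannot regress.",
                      key$class))
      }
      fit <- lm(pixels ~ n_discs, data = d)
      tibble::tibble(slope = coef(fit)[["n_discs"]],
                     intercept = coef(fit)[["(Intercept)"]],
                     r_squared = summary(fit)$r.squared,
                     n = nrow(d))
    }) %>%
    dplyr::ungroup()
}
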