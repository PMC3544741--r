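#' Intensity thresholds and weights for positive pixel counting
#'
#' Staining is quantified on a single 8-bit intensity channel where
#' darker pixels mean stronger staining (brightfield absorbance).
#' Pixels are binned by intensity `I` into four bands:
#' strong `I <= strong_upper`, medium `strong_upper < I <=
#' medium_upper`, weak `medium_upper < I <= weak_upper`, and negative
#' `I > weak_upper`.  The published thresholds 220 / 175 / 100 and the
#' weights 1 / 2 / 3 for weak / medium / strong are the defaults.
#'
#' @param weak_upper,medium_upper,strong_upper band boundaries on the
#'   0-255 intensity scale; must satisfy
#'   `0 <= strong_upper < medium_upper < weak_upper <= 255`.
#' @param weights named numeric vector of band weights.
#' @return object of class `"threshold_config"`.
#' @export
threshold_config <- function(weak_upper = 220, medium_upper = 175,
                             strong_upper = 100,
                             weights = c(weak = 1, medium = 2, strong = 3)) {
  if (!(0 <= strong_upper && strong_upper < medium_upper &&
        medium_upper < weak_upper && weak_upper <= 255))
    stop("need 0 <= strong_upper < medium_upper < weak_upper <= 255")
  stopifnot(all(c("weak", "medium", "strong") %in% names(weights)))
  structure(list(weak_upper = weak_upper, medium_upper = medium_upper,
                 strong_upper = strong_upper, weights = weights),
            class = "threshold_config")
}

# coerce an image to an integer 0-255 intensity matrix; [0,1] doubles
# (e.g. from png::readPNG) are rescaled with a warning
.as_intensity <- function(image) {
  img <- as.matrix(image)
  if (!is.numeric(img)) stop("image must be numeric")
  if (max(img, na.rm = TRUE) <= 1 && min(img, na.rm = TRUE) >= 0 &&
      any(img != round(img))) {
    warning("image looks like [0,1] doubles; rescaling to 0-255")
    img <- img * 255
  }
  round(img)
}

#' Classify masked pixels into staining-intensity bands
#'
#' Counts the pixels of a region of interest falling into the
#' negative / weak / medium / strong intensity bands of a
#' [threshold_config()].  Band edges are inclusive toward stronger
#' staining (e.g. a pixel exactly at `strong_upper` is strong).
#'
#' @param image numeric matrix of 8-bit intensities.
#' @param mask logical (or 0/1) matrix of the same shape selecting
#'   region pixels; `NULL` selects the whole image.
#' @param cfg a [threshold_config()].
#' @return object of class `"pixel_class_counts"`: list with
#'   `n_negative`, `n_weak`, `n_medium`, `n_strong`, `n_total`.
#' @examples
#' img <- matrix(c(50, 120, 200, 240), 2)
#' classify_pixels(img)
#' @export
classify_pixels <- function(image, mask = NULL, cfg = threshold_config()) {
  img <- .as_intensity(image)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  mask <- as.logical(mask)
  if (length(mask) != length(img))
    stop("image and mask must have the same shape")
  px <- img[mask]
  if (!length(px)) stop("mask selects no pixels")
  counts <- list(
    n_negative = sum(px > cfg$weak_upper),
    n_weak = sum(px > cfg$medium_upper & px <= cfg$weak_upper),
    n_medium = sum(px > cfg$strong_upper & px <= cfg$medium_upper),
    n_strong = sum(px <= cfg$strong_upper),
    n_total = length(px))
  structure(counts, class = "pixel_class_counts")
}

#' @export
print.pixel_class_counts <- function(x, ...) {
  cat("Pixel class counts (", x$n_total, " pixels)\n", sep = "")
  cat(sprintf("  negative %d | weak %d | medium %d | strong %d\n",
              x$n_negative, x$n_weak, x$n_medium, x$n_strong))
  invisible(x)
}

#' Strong-pixel ratio (NSR)
#'
#' The number of strong positive pixels divided by the total number of
#' positive (weak + medium + strong) pixels — a density-of-staining
#' statistic normalised to the stained area.
#'
#' @param counts a [classify_pixels()] result.
#' @return proportion in [0, 1], or `NA` with a warning when the
#'   region has no positive pixels (such regions are excluded from
#'   group statistics).
#' @export
nsr <- function(counts) {
  pos <- counts$n_weak + counts$n_medium + counts$n_strong
  if (pos == 0) {
    warning("no positive pixels; NSR undefined")
    return(NA_real_)
  }
  counts$n_strong / pos
}

#' Weighted staining intensity per unit area
#'
#' Weights the positive bands (weak = 1, medium = 2, strong = 3 by
#' default), sums, and divides by the total pixel count of the region
#' (negative and positive), yielding labeling intensity per unit area
#' in [0, 3].
#'
#' @inheritParams nsr
#' @param cfg the [threshold_config()] providing the weights.
#' @return weighted score in `[0, max(weights)]`.
#' @export
weighted_score <- function(counts, cfg = threshold_config()) {
  if (counts$n_total == 0) stop("empty region")
  w <- cfg$weights
  (w[["weak"]] * counts$n_weak + w[["medium"]] * counts$n_medium +
      w[["strong"]] * counts$n_strong) / counts$n_total
}

#' Default pseudocolor palette
#'
#' Blue, yellow, orange and red RGB triples for the negative, weak,
#' medium and strong bands.
#'
#' @return 4 x 3 numeric matrix in [0, 1], rows named by band.
#' @export
pseudocolor_palette <- function() {
  rbind(negative = c(0, 0, 1),
        weak = c(1, 1, 0),
        medium = c(1, 0.647, 0),
        strong = c(1, 0, 0))
}

#' Pseudocolor an intensity image by staining band
#'
#' Maps every pixel to its band's color (blue / yellow / orange / red
#' for negative / weak / medium / strong).  The mapping is lossless:
#' [pseudocolor_to_bands()] recovers the band of every pixel, so
#' re-counting colors reproduces [classify_pixels()] exactly.
#'
#' @inheritParams classify_pixels
#' @param palette 4 x 3 RGB matrix as from [pseudocolor_palette()].
#' @return height x width x 3 numeric array with values in [0, 1].
#' @export
pseudocolor <- function(image, cfg = threshold_config(),
                        palette = pseudocolor_palette()) {
  img <- .as_intensity(image)
  band <- matrix(1L, nrow(img), ncol(img))  # negative
  band[img <= cfg$weak_upper] <- 2L
  band[img <= cfg$medium_upper] <- 3L
  band[img <= cfg$strong_upper] <- 4L
  out <- array(0, c(nrow(img), ncol(img), 3L))
  for (ch in 1:3)
    out[, , ch] <- matrix(palette[band, ch], nrow(img), ncol(img))
  out
}

#' Recover staining bands from a pseudocolored image
#'
#' Inverse of [pseudocolor()]: matches each pixel's RGB triple back to
#' its band.
#'
#' @param rgb height x width x 3 array from [pseudocolor()].
#' @param palette the palette used to colorize.
#' @return integer matrix of band codes 1-4 (negative, weak, medium,
#'   strong) with class labels in attribute `"bands"`.
#' @export
pseudocolor_to_bands <- function(rgb, palette = pseudocolor_palette()) {
  key <- apply(palette, 1L, paste, collapse = "/")
  px <- paste(rgb[, , 1], rgb[, , 2], rgb[, , 3], sep = "/")
  band <- match(px, key)
  if (anyNA(band)) stop("pixel color not in the palette")
  out <- matrix(band, dim(rgb)[1], dim(rgb)[2])
  attr(out, "bands") <- rownames(palette)
  out
}

#' Score a named set of regions of interest
#'
#' Applies [classify_pixels()], [nsr()] and [weighted_score()] to each
#' named mask.  For masks named as glands (`gland_names` prefix),
#' lumen exclusion optionally removes pixels brighter than the weak
#' threshold before scoring, mirroring software that recognises gland
#' lumen and drops those unstained pixels.
#'
#' @param image numeric intensity matrix.
#' @param masks named list of logical masks, one per region.
#' @param cfg a [threshold_config()].
#' @param exclude_lumen drop pixels with intensity above
#'   `cfg$weak_upper` inside gland regions before scoring.
#' @param gland_names regular expression identifying gland region
#'   names (default any name starting with "gland").
#' @return data.frame with one row per region: counts, `nsr`,
#'   `weighted_score`.
#' @export
region_scores <- function(image, masks, cfg = threshold_config(),
                          exclude_lumen = TRUE,
                          gland_names = "^gland") {
  if (is.null(names(masks)) || any(!nzchar(names(masks))))
    stop("all masks must be named")
  img <- .as_intensity(image)
  rows <- lapply(names(masks), function(nm) {
    m <- as.logical(masks[[nm]])
    if (length(m) != length(img)) stop("mask '", nm, "' has wrong shape")
    m <- matrix(m, nrow(img), ncol(img))
    if (exclude_lumen && grepl(gland_names, nm))
      m <- m & img <= cfg$weak_upper
    if (!any(m)) stop("mask '", nm, "' selects no pixels after exclusions")
    cc <- classify_pixels(img, m, cfg)
    data.frame(region_id = nm, n_negative = cc$n_negative,
               n_weak = cc$n_weak, n_medium = cc$n_medium,
               n_strong = cc$n_strong, n_total = cc$n_total,
               nsr = suppressWarnings(nsr(cc)),
               weighted_score = weighted_score(cc, cfg),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Welch comparison of two groups of region scores
#'
#' Two-sided Welch two-sample t-test used to compare staining scores
#' between groups (e.g. gland vs stroma regions, or cancer vs normal
#' samples).  When both groups are constant with equal means the
#' comparison is degenerate and p = 1 is returned.
#'
#' @param scores_a,scores_b numeric vectors, each of length >= 2;
#'   `NA`s (e.g. undefined NSRs) are dropped.
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
compare_groups <- function(scores_a, scores_b) {
  a <- scores_a[is.finite(scores_a)]
  b <- scores_b[is.finite(scores_b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 finite values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = NA_real_, p = 1,
                  mean_a = mean(a), mean_b = mean(b)))
    return(list(t = Inf * sign(mean(a) - mean(b)), df = NA_real_, p = 0,
                mean_a = mean(a), mean_b = mean(b)))
  }
  ht <- stats::t.test(a, b)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Write an intensity or RGB image as PNG
#'
#' @param image intensity matrix (0-255) or RGB array in [0, 1].
#' @param path output path.
#' @export
write_image_png <- function(image, path) {
  if (length(dim(image)) == 2L) image <- .as_intensity(image) / 255
  png::writePNG(image, path)
  invisible(path)
}

#' Read a PNG as an 8-bit intensity matrix
#'
#' Color images are collapsed to intensity by channel averaging.
#'
#' @param path PNG file path.
#' @return numeric matrix with values 0-255.
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
  round(img * 255)
}
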