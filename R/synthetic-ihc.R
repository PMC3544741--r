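#' Describe a circular gland region for image synthesis
#'
#' @param cx,cy center pixel coordinates (column, row).
#' @param r radius in pixels.
#' @param intensity mean 8-bit staining intensity of the gland
#'   epithelium (lower = darker = stronger staining).
#' @param lumen if `TRUE` the gland gets a central unstained lumen of
#'   radius `r / 3` at near-white intensity.
#' @return list describing the gland.
#' @export
gland_region <- function(cx, cy, r, intensity, lumen = FALSE) {
  if (intensity < 0 || intensity > 255) stop("intensity must be in [0, 255]")
  list(cx = cx, cy = cy, r = r, intensity = intensity, lumen = lumen)
}

#' Generate a synthetic IHC-like image with region masks
#'
#' Paints circular glands of specified staining intensity on a stromal
#' background, optionally with bright central lumina, and returns the
#' 8-bit image together with labeled masks (`gland`, `stroma`,
#' `lumen`, plus one mask per gland `gland_1`, `gland_2`, ...).  Pixel
#' intensities are drawn tightly around the specified values (uniform
#' integer jitter of `+/- jitter`, clamped to [0, 255]); lumen pixels
#' sit near white, above the weak threshold, as unstained area.
#'
#' Glands must not overlap; overlapping layouts raise an error.
#'
#' @param width,height image size in pixels.
#' @param glands list of [gland_region()] descriptions.
#' @param stroma_intensity 8-bit background intensity.
#' @param lumen_intensity intensity of lumen pixels (default 250).
#' @param jitter half-width of the uniform intensity jitter (default
#'   3; use 0 for exact intensities).
#' @param seed integer RNG seed.
#' @return list with `image` (height x width intensity matrix) and
#'   `masks` (named list of logical matrices).
#' @export
generate_ihc_image <- function(width = 256, height = 256,
                               glands = list(),
                               stroma_intensity = 230,
                               lumen_intensity = 250,
                               jitter = 3, seed = 1L) {
  if (stroma_intensity < 0 || stroma_intensity > 255)
    stop("stroma_intensity must be in [0, 255]")
  set.seed(seed)
  xs <- matrix(rep(seq_len(width), each = height), height, width)
  ys <- matrix(rep(seq_len(height), times = width), height, width)
  jit <- function(mu, n) {
    v <- mu + if (jitter > 0) sample(-jitter:jitter, n, replace = TRUE) else 0
    pmin(pmax(v, 0), 255)
  }
  img <- matrix(jit(stroma_intensity, height * width), height, width)
  gland_mask <- matrix(FALSE, height, width)
  lumen_mask <- matrix(FALSE, height, width)
  masks <- list()
  for (k in seq_along(glands)) {
    g <- glands[[k]]
    inside <- (xs - g$cx)^2 + (ys - g$cy)^2 <= g$r^2
    if (any(inside & gland_mask))
      stop("gland ", k, " overlaps an earlier gland")
    lum <- matrix(FALSE, height, width)
    if (isTRUE(g$lumen))
      lum <- (xs - g$cx)^2 + (ys - g$cy)^2 <= (g$r / 3)^2
    epi <- inside & !lum
    img[epi] <- jit(g$intensity, sum(epi))
    img[lum] <- jit(lumen_intensity, sum(lum))
    gland_mask <- gland_mask | inside
    lumen_mask <- lumen_mask | lum
    masks[[paste0("gland_", k)]] <- inside
  }
  masks$gland <- gland_mask
  masks$lumen <- lumen_mask
  masks$stroma <- !gland_mask
  list(image = img, masks = masks)
}
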