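#' Ultrasound image container
#'
#' Wraps a 2-D grid of gray levels with its physical pixel spacing and an
#' optional binary marker mask (caliper overlays to be inpainted).
#'
#' @param pixels Numeric matrix of gray levels in \[0, 255\] (rows = image
#'   rows, row-major, 0-based coordinates are used in all pixel interfaces).
#' @param spacing Isotropic pixel spacing in mm/pixel; must be positive.
#' @param marker_mask Optional logical matrix (same shape as `pixels`) marking
#'   caliper/annotation pixels.
#'
#' @return An object of class `us_image`: a list with elements `pixels`,
#'   `spacing` and `marker_mask`.
#' @export
us_image <- function(pixels, spacing = 0.5, marker_mask = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (any(!is.finite(pixels)))
    stop("`pixels` must be finite")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("gray levels must lie in [0, 255]")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("`spacing` must be a positive scalar (mm/pixel)")
  if (!is.null(marker_mask)) {
    marker_mask <- as_mask(marker_mask)
    if (!identical(dim(marker_mask), dim(pixels)))
      stop("`marker_mask` must have the same shape as `pixels`")
  }
  structure(list(pixels = pixels, spacing = spacing, marker_mask = marker_mask),
            class = "us_image")
}

#' @export
print.us_image <- function(x, ...) {
  cat(sprintf("<us_image> %d x %d pixels, %.3g mm/pixel, gray [%.4g, %.4g]%s\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing,
              min(x$pixels), max(x$pixels),
              if (is.null(x$marker_mask)) "" else
                sprintf(", %d marker px", sum(x$marker_mask))))
  invisible(x)
}

#' @export
dim.us_image <- function(x) dim(x$pixels)

#' Read / write 8-bit grayscale images
#'
#' Thin wrappers around [EBImage::readImage()] / [EBImage::writeImage()] that
#' convert between the package's \[0, 255\] gray convention (matrix indexed
#' `[row, col]`) and EBImage's \[0, 1\] `(x, y)` convention.
#'
#' @param path File path (PNG or TIFF).
#' @param spacing Pixel spacing in mm/pixel to attach on read.
#' @return `read_us_image` returns a [us_image]; `write_us_image` invisibly
#'   returns `path`.
#' @export
read_us_image <- function(path, spacing = 0.5) {
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) > 2L) dat <- dat[, , 1L]
  us_image(t(dat) * 255, spacing = spacing)
}

#' @rdname read_us_image
#' @param image A [us_image] (or numeric/logical matrix; logical masks are
#'   written as 0/255).
#' @export
write_us_image <- function(image, path) {
  px <- if (inherits(image, "us_image")) image$pixels else image
  if (is.logical(px)) px <- px * 255
  EBImage::writeImage(EBImage::Image(t(px / 255)), path)
  invisible(path)
}

# internal: coerce numeric/logical matrix to logical mask
as_mask <- function(m) {
  if (!is.matrix(m)) stop("mask must be a matrix")
  if (!is.logical(m)) m <- m != 0
  m
}

# internal: physical length (mm) to pixel radius
mm_to_px <- function(mm, spacing) as.integer(round(mm / spacing))

# internal: exact Euclidean disc structuring element of pixel radius r
disc_kernel <- function(r) {
  r <- as.integer(r)
  if (r < 0L) stop("radius must be >= 0")
  d <- 2L * r + 1L
  idx <- seq_len(d) - (r + 1L)
  outer(idx^2, idx^2, `+`) <= r^2
}

# internal: binary dilation by an arbitrary kernel, clipped at borders
dilate_binary <- function(mask, kern) {
  if (all(!kern)) return(mask)
  out <- EBImage::dilate(mask * 1, kern * 1)
  matrix(out > 0, nrow(mask), ncol(mask))
}

# internal: run body with a private RNG stream seeded at `seed`
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  expr
}
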