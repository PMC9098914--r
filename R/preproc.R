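# Offsets of the 4-/8-neighborhoods (row, col)
neighbor_offsets <- function(connectivity = 8L) {
  if (connectivity == 4L)
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  else
    cbind(dr = rep(-1:1, 3L), dc = rep(-1:1, each = 3L))[-5L, , drop = FALSE]
}

#' Remove marked pixels by coherence-weighted inpainting
#'
#' Fills a target region (typically caliper markers) by marching inward from
#' the region boundary: each layer of unknown pixels adjacent to known data is
#' filled with a weighted average of its known 8-neighbors, with weights
#' favoring neighbors lying along the local image structure (the isophote
#' direction, estimated from the smoothed gradient), so that edges are
#' transported into the hole rather than blurred across it. Pixels outside
#' the target are returned bit-identical; every filled value is a convex
#' combination of known neighboring values and therefore bounded by them.
#'
#' @param image A [us_image].
#' @param target_mask Logical matrix of pixels to replace; defaults to the
#'   image's own `marker_mask`.
#' @return A [us_image] with the target filled and `marker_mask` cleared.
#' @export
inpaint <- function(image, target_mask = image$marker_mask) {
  stopifnot(inherits(image, "us_image"))
  if (is.null(target_mask)) return(image)
  target_mask <- as_mask(target_mask)
  if (!identical(dim(target_mask), dim(image$pixels)))
    stop("`target_mask` must match the image shape")
  if (all(target_mask)) stop("target mask covers the whole image: no boundary data")
  if (!any(target_mask)) { image$marker_mask <- NULL; return(image) }

  px <- image$pixels
  known <- !target_mask
  h <- nrow(px); w <- ncol(px)

  # orientation field from a smoothed version with unknowns set to the
  # known-pixel mean (only used for weighting, never copied into values)
  tmp <- px; tmp[!known] <- mean(px[known])
  sg <- min(1.5, (min(h, w) - 1) / 7)
  sm <- if (sg < 0.3) tmp else
    t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(tmp)), sigma = sg)))
  gr <- matrix(0, h, w); gc <- matrix(0, h, w)
  gr[2:(h - 1), ] <- (sm[3:h, ] - sm[1:(h - 2), ]) / 2
  gc[, 2:(w - 1)] <- (sm[, 3:w] - sm[, 1:(w - 2)]) / 2
  gn <- sqrt(gr^2 + gc^2)

  offs <- neighbor_offsets(8L)
  inv_len <- 1 / sqrt(offs[, 1]^2 + offs[, 2]^2)
  while (any(!known)) {
    idx <- which(!known, arr.ind = TRUE)
    vals <- numeric(nrow(idx)); wts <- numeric(nrow(idx))
    for (k in seq_len(nrow(offs))) {
      nr <- idx[, 1] + offs[k, 1]; nc <- idx[, 2] + offs[k, 2]
      ok <- nr >= 1 & nr <= h & nc >= 1 & nc <= w
      ok[ok] <- known[cbind(nr[ok], nc[ok])]
      if (!any(ok)) next
      i <- which(ok)
      p <- cbind(idx[i, 1], idx[i, 2])
      # coherence: down-weight neighbors across the gradient direction
      dot <- (gr[p] * offs[k, 1] + gc[p] * offs[k, 2]) * inv_len[k]
      coh <- 1 - 0.9 * ifelse(gn[p] > 1e-8, (dot / pmax(gn[p], 1e-8))^2, 0)
      wk <- inv_len[k] * coh
      vals[i] <- vals[i] + wk * px[cbind(nr[i], nc[i])]
      wts[i] <- wts[i] + wk
    }
    layer <- wts > 0
    if (!any(layer)) stop("inpainting target has an unreachable component")
    fill <- cbind(idx[layer, 1], idx[layer, 2])
    px[fill] <- vals[layer] / wts[layer]
    known[fill] <- TRUE
  }
  out <- image
  out$pixels <- px
  out$marker_mask <- NULL
  out
}

#' Seeded region growing
#'
#' Segments the hypoechoic lesion by iteratively admitting pixels from the
#' region frontier whose gray level differs from the current region mean by
#' at most `tolerance`. The frontier is processed best-first (smallest
#' difference first) and the region mean is updated after every admission, so
#' the result does not depend on neighbor enumeration order. The grown region
#' is hole-filled before being returned.
#'
#' @param image A [us_image].
#' @param seed `(row, col)` seed point (0-based), inside the image and not on
#'   a marker pixel.
#' @param tolerance Maximum admissible absolute gray-level difference from
#'   the running region mean (>= 0).
#' @param connectivity Pixel connectivity, 8 (default) or 4.
#' @return Logical matrix: the connected lesion mask containing the seed.
#' @export
region_grow <- function(image, seed, tolerance, connectivity = 8L) {
  stopifnot(inherits(image, "us_image"))
  if (tolerance < 0) stop("`tolerance` must be >= 0")
  px <- image$pixels
  h <- nrow(px); w <- ncol(px)
  r0 <- as.integer(seed[1]) + 1L; c0 <- as.integer(seed[2]) + 1L
  if (r0 < 1L || r0 > h || c0 < 1L || c0 > w) stop("seed outside the image")
  if (!is.null(image$marker_mask) && image$marker_mask[r0, c0])
    stop("seed lies on a marker pixel: inpaint the image first")

  offs <- neighbor_offsets(as.integer(connectivity))
  region <- matrix(FALSE, h, w)
  in_frontier <- matrix(FALSE, h, w)
  region[r0, c0] <- TRUE
  mu <- px[r0, c0]; n_reg <- 1L

  f_idx <- integer(0)  # linear indices of frontier pixels
  push_neighbors <- function(r, c) {
    nr <- r + offs[, 1]; nc <- c + offs[, 2]
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    nr <- nr[ok]; nc <- nc[ok]
    lin <- (nc - 1L) * h + nr
    new <- !region[lin] & !in_frontier[lin]
    if (any(new)) {
      in_frontier[lin[new]] <<- TRUE
      f_idx <<- c(f_idx, lin[new])
    }
  }
  push_neighbors(r0, c0)

  while (length(f_idx)) {
    d <- abs(px[f_idx] - mu)
    i <- which.min(d)
    if (d[i] > tolerance) break
    lin <- f_idx[i]
    f_idx <- f_idx[-i]
    in_frontier[lin] <- FALSE
    region[lin] <- TRUE
    mu <- mu + (px[lin] - mu) / (n_reg + 1L)
    n_reg <- n_reg + 1L
    push_neighbors((lin - 1L) %% h + 1L, (lin - 1L) %/% h + 1L)
  }
  filled <- EBImage::fillHull(region * 1)
  matrix(as.numeric(filled) > 0, h, w)
}

#' Dilate a binary mask by a physical radius
#'
#' Morphological dilation by a discrete Euclidean disc of pixel radius
#' `round(radius_mm / spacing)`, clipped at the image borders. Radius 0 is
#' the identity; dilation is extensive (`output >= input`) and monotone.
#'
#' @param mask Logical matrix.
#' @param radius_mm Dilation radius in mm (>= 0).
#' @param spacing Pixel spacing in mm/pixel.
#' @return Logical matrix of the same shape.
#' @export
dilate_mask <- function(mask, radius_mm, spacing) {
  if (radius_mm < 0) stop("`radius_mm` must be >= 0")
  mask <- as_mask(mask)
  r <- mm_to_px(radius_mm, spacing)
  if (r == 0L) return(mask)
  dilate_binary(mask, disc_kernel(r))
}

#' Construct the four regions of interest around a lesion
#'
#' From an intra-tumoral mask, builds the ROI set used throughout the
#' pipeline: the combined ROI (intra-tumoral mask dilated by `ring_mm`,
#' 20 mm = 2 cm by default), the peritumoral ROI (combined minus intra), and
#' the original ROI (bounding box of the combined mask expanded by
#' `box_margin_mm` and clipped to the image).
#'
#' @param image A [us_image] (the cleaned image the masks refer to).
#' @param intra_mask Non-empty logical matrix: the lesion segmentation.
#' @param ring_mm Peritumoral dilation radius in mm.
#' @param box_margin_mm Margin added around the combined mask's bounding box
#'   to form the original ROI.
#' @return An object of class `roi_set` with elements `intra_mask`,
#'   `peri_mask`, `combined_mask`, `original_box` (0-based half-open
#'   `(row0, col0, row1, col1)`) and `source` (the image).
#' @export
build_roi_set <- function(image, intra_mask, ring_mm = 20, box_margin_mm = 5) {
  stopifnot(inherits(image, "us_image"))
  intra_mask <- as_mask(intra_mask)
  if (!any(intra_mask)) stop("`intra_mask` is empty")
  if (!identical(dim(intra_mask), dim(image$pixels)))
    stop("`intra_mask` must match the image shape")
  combined <- dilate_mask(intra_mask, ring_mm, image$spacing)
  peri <- combined & !intra_mask

  idx <- which(combined, arr.ind = TRUE)
  m <- mm_to_px(box_margin_mm, image$spacing)
  box <- c(max(0L, min(idx[, 1]) - 1L - m), max(0L, min(idx[, 2]) - 1L - m),
           min(nrow(combined), max(idx[, 1]) + m), min(ncol(combined), max(idx[, 2]) + m))
  structure(list(intra_mask = intra_mask, peri_mask = peri,
                 combined_mask = combined, original_box = box, source = image),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf(paste0("<roi_set> intra %d px | peri %d px | combined %d px | ",
                     "original box [%d,%d)x[%d,%d)\n"),
              sum(x$intra_mask), sum(x$peri_mask), sum(x$combined_mask),
              x$original_box[1], x$original_box[3],
              x$original_box[2], x$original_box[4]))
  invisible(x)
}

# internal: logical mask of the original-ROI rectangle
box_mask <- function(box, dims) {
  m <- matrix(FALSE, dims[1], dims[2])
  m[(box[1] + 1L):box[3], (box[2] + 1L):box[4]] <- TRUE
  m
}
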