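#' Specification of a synthetic ultrasound phantom
#'
#' Describes a speckle-textured image containing a hypoechoic elliptical
#' lesion on a brighter background, with an optional peritumoral ring whose
#' texture (like the lesion's) is shifted for positive-class patients.
#'
#' The speckle model is multiplicative: a unit-mean gamma field is lightly
#' Gaussian-smoothed and scaled per region, so `speckle_scale = 0` yields a
#' piecewise-constant image and `class_effect` inflates the speckle contrast
#' of the lesion and its surrounding ring without moving region means.
#'
#' @param image_height,image_width Image size in pixels.
#' @param pixel_spacing Pixel spacing in mm/pixel.
#' @param lesion_center `(row, col)` center of the lesion ellipse (0-based).
#' @param lesion_radii `(r_row, r_col)` ellipse radii in pixels (each >= 3).
#' @param background_mean,lesion_mean Region mean gray levels in \[0, 255\];
#'   the lesion must be hypoechoic (`background_mean > lesion_mean`).
#' @param speckle_scale Dimensionless multiplicative-noise amplitude (>= 0).
#' @param class_effect Dimensionless relative shift applied to the lesion and
#'   ring speckle amplitude (positive-class texture effect).
#' @param ring_width_px Width in pixels of the textured ring surrounding the
#'   lesion that carries the class effect.
#' @param marker_positions List of `(row, col)` caliper marker positions.
#' @param seed Integer seed; phantom generation is deterministic given it.
#'
#' @return An object of class `phantom_spec`.
#' @seealso [gen_phantom()], [gen_cohort()]
#' @export
phantom_spec <- function(image_height = 128, image_width = 128,
                         pixel_spacing = 0.5,
                         lesion_center = c(round(image_height / 2), round(image_width / 2)),
                         lesion_radii = c(18, 22),
                         background_mean = 170, lesion_mean = 70,
                         speckle_scale = 0.25, class_effect = 0,
                         ring_width_px = max(3L, round(0.4 * mean(lesion_radii))),
                         marker_positions = list(), seed = 1L) {
  spec <- structure(list(
    image_height = as.integer(image_height), image_width = as.integer(image_width),
    pixel_spacing = pixel_spacing,
    lesion_center = as.numeric(lesion_center), lesion_radii = as.numeric(lesion_radii),
    background_mean = background_mean, lesion_mean = lesion_mean,
    speckle_scale = speckle_scale, class_effect = class_effect,
    ring_width_px = as.integer(ring_width_px),
    marker_positions = marker_positions, seed = as.integer(seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (any(lesion_radii < 3)) stop("lesion radii must be >= 3 pixels")
    if (background_mean <= lesion_mean)
      stop("lesion must be hypoechoic: background_mean > lesion_mean")
    if (speckle_scale < 0) stop("speckle_scale must be >= 0")
    if (pixel_spacing <= 0) stop("pixel_spacing must be > 0")
    r0 <- lesion_center[1]; c0 <- lesion_center[2]
    if (r0 - lesion_radii[1] < 0 || r0 + lesion_radii[1] > image_height - 1 ||
        c0 - lesion_radii[2] < 0 || c0 + lesion_radii[2] > image_width - 1)
      stop("lesion ellipse must lie fully inside the image")
  })
  invisible(spec)
}

# internal: logical ellipse mask (0-based center/radii)
ellipse_mask <- function(h, w, center, radii) {
  rr <- matrix(seq_len(h) - 1, h, w)
  cc <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  ((rr - center[1]) / radii[1])^2 + ((cc - center[2]) / radii[2])^2 <= 1
}

#' Generate a synthetic ultrasound phantom
#'
#' Builds the image described by a [phantom_spec()]: a two-region mean map
#' (hypoechoic lesion ellipse on a brighter background) multiplied by a
#' smoothed unit-mean gamma speckle field, with the lesion and its
#' peritumoral ring receiving a speckle amplitude inflated by
#' `1 + class_effect`. Deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `image` (a [us_image]) and `lesion_mask` (logical
#'   matrix, the exact ellipse — the segmentation ground truth).
#' @examples
#' ph <- gen_phantom(phantom_spec(speckle_scale = 0))
#' sort(unique(as.vector(ph$image$pixels)))  # exactly the two region means
#' @export
gen_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  h <- spec$image_height; w <- spec$image_width
  lesion <- ellipse_mask(h, w, spec$lesion_center, spec$lesion_radii)
  ring <- dilate_binary(lesion, disc_kernel(spec$ring_width_px)) & !lesion

  mean_map <- matrix(spec$background_mean, h, w)
  mean_map[lesion] <- spec$lesion_mean

  scale_map <- matrix(spec$speckle_scale, h, w)
  scale_map[lesion | ring] <- spec$speckle_scale * (1 + spec$class_effect)

  img <- with_seed(spec$seed, {
    if (spec$speckle_scale > 0) {
      # class effect acts on both the speckle amplitude (visible in ROIs
      # mixing lesion and background) and its correlation length, i.e. the
      # speckle grain becomes coarser — a texture shift that survives the
      # per-ROI gray-range quantization of the feature extractor
      g <- matrix(stats::rgamma(h * w, shape = 4, rate = 4), h, w)
      blur <- function(mat, sigma) {
        sigma <- min(sigma, (min(h, w) - 1) / 7)
        if (sigma < 0.05) return(mat)
        t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(mat)),
                                            sigma = sigma)))
      }
      field <- blur(g, 0.7)
      if (spec$class_effect != 0) {
        coarse <- blur(g, 0.7 * (1 + spec$class_effect))
        field[lesion | ring] <- coarse[lesion | ring]
      }
      mean_map * (1 + scale_map * (field - 1))
    } else mean_map
  })
  img <- pmin(pmax(img, 0), 255)

  out <- us_image(img, spacing = spec$pixel_spacing)
  if (length(spec$marker_positions)) {
    marked <- overlay_markers(out, spec$marker_positions)
    out <- marked$image
    out$marker_mask <- marked$marker_mask
  }
  list(image = out, lesion_mask = lesion)
}

#' Overlay caliper markers on an image
#'
#' Draws saturated-white '+'-shaped crosses at the given positions, as left
#' by measurement calipers during screening, and returns the exact binary
#' mask of altered pixels (the inpainting target).
#'
#' @param image A [us_image].
#' @param positions List of `(row, col)` marker centers (0-based, inside the
#'   image).
#' @param arm_length Arm length of each cross in pixels; a marker covers
#'   `4 * arm_length + 1` pixels when fully inside the image.
#' @return List with `image` (marked copy) and `marker_mask` (logical).
#' @export
overlay_markers <- function(image, positions, arm_length = 3L) {
  stopifnot(inherits(image, "us_image"))
  h <- nrow(image$pixels); w <- ncol(image$pixels)
  mask <- matrix(FALSE, h, w)
  if (length(positions) == 0L)
    return(list(image = image, marker_mask = mask))
  a <- as.integer(arm_length)
  for (p in positions) {
    r <- as.integer(p[1]) + 1L; c <- as.integer(p[2]) + 1L
    if (r < 1L || r > h || c < 1L || c > w)
      stop("marker position outside the image")
    rows <- pmax(1L, r - a):pmin(h, r + a)
    cols <- pmax(1L, c - a):pmin(w, c + a)
    mask[cbind(rows, c)] <- TRUE
    mask[cbind(r, cols)] <- TRUE
  }
  image$pixels[mask] <- 255
  image$marker_mask <- mask
  list(image = image, marker_mask = mask)
}

# Published-cohort-like clinical marginals used as generator defaults: median age 60
# [48, 69]; diameter T1a/T1b/T1c/T2 = 12/42/57/30; grading 40/62/38;
# histology ductal/lobular/other = 115/21/4; ER median 98 [95, 98];
# PgR median 40 [5, 80]; ki67 median 18 [12, 30]; HER2 0..3 = 87/30/13/10;
# quadrant 8 levels; multifocality 22.5%, angioinvasion 14.8%, in-situ 7.9%.
clinical_marginals <- function() {
  list(
    diameter = c(T1a = 12, T1b = 42, T1c = 57, T2 = 30) / 141,
    grading = c(`1` = 40, `2` = 62, `3` = 38) / 140,
    histological_type = c(ductal = 115, lobular = 21, other = 4) / 140,
    her2 = c(`0` = 87, `1` = 30, `2` = 13, `3` = 10) / 140,
    quadrant = c(QSM = 20, QSE = 46, QEE = 20, QIE = 15,
                 QIM = 1, QII = 8, QEI = 9, QSI = 23) / 142,
    p_multifocal = 32 / 142, p_angioinvasion = 21 / 142, p_insitu = 11 / 140)
}

#' Default per-variable missingness rates
#'
#' Missing-at-random rates for the synthetic clinical table, one per clinical
#' variable, defaulting to the observed rates of the emulated cohort (age
#' 9.2%, most others under 1.5%, several complete).
#'
#' @return Named numeric vector over the 12 clinical variables.
#' @export
default_missing_rates <- function() {
  c(age = 13 / 142, diameter = 1 / 142, grading = 2 / 142,
    histological_type = 2 / 142, er = 1 / 142, pgr = 1 / 142,
    ki67 = 2 / 142, her2 = 2 / 142, quadrant = 0,
    multifocality = 0, angioinvasion = 0, invasiveness = 2 / 142)
}

# internal: one synthetic clinical table (no missingness yet)
gen_clinical_raw <- function(n, labels, clinical_effects) {
  m <- clinical_marginals()
  d <- clinical_effects
  pos <- labels == 1L
  age <- round(stats::rnorm(n, 58.5, 15.5) + d * 15.5 * pos)
  age <- pmin(pmax(age, 25), 92)
  er <- round(pmin(pmax(100 * stats::rbeta(n, 14, 0.9), 0), 100))
  pgr <- round(stats::runif(n, 0, 100))
  ki67 <- round(pmin(exp(stats::rnorm(n, log(18), 0.55) + d * 0.55 * pos), 95))
  samp <- function(p) names(p)[1L + findInterval(stats::runif(n), cumsum(p))]
  tilt <- function(p) stats::plogis(stats::qlogis(p) + d * pos)
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age = age,
    diameter = factor(samp(m$diameter), levels = names(m$diameter)),
    grading = factor(samp(m$grading), levels = names(m$grading)),
    histological_type = factor(samp(m$histological_type),
                               levels = names(m$histological_type)),
    er = er, pgr = pgr, ki67 = ki67,
    her2 = factor(samp(m$her2), levels = names(m$her2)),
    quadrant = factor(samp(m$quadrant), levels = names(m$quadrant)),
    multifocality = factor(ifelse(stats::runif(n) < tilt(m$p_multifocal),
                                  "present", "absent"),
                           levels = c("absent", "present")),
    angioinvasion = factor(ifelse(stats::runif(n) < tilt(m$p_angioinvasion),
                                  "present", "absent"),
                           levels = c("absent", "present")),
    invasiveness = factor(ifelse(stats::runif(n) < m$p_insitu,
                                 "in_situ", "infiltrating"),
                          levels = c("infiltrating", "in_situ")),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic patient cohort
#'
#' Draws `n` patients with binary nodal-status labels at the requested
#' prevalence, per-patient phantom ultrasound images whose lesion/ring
#' speckle texture is shifted by `class_effect` for positives, ground-truth
#' lesion masks, and a 12-variable clinical table with configurable
#' class-conditional shifts and per-variable missingness.
#'
#' `clinical_effects` is a single standardized effect size: positive-class
#' patients have `age` and `ki67` shifted upward by that many within-class
#' standard deviations and the multifocality/angioinvasion odds tilted by the
#' same amount on the logit scale (the variables the emulated cohort found
#' class-associated).
#'
#' @param n Number of patients (>= 10).
#' @param prevalence Positive-class fraction in (0, 1); the realized count is
#'   `round(n * prevalence)`.
#' @param class_effect Texture effect passed to [phantom_spec()] for
#'   positive patients.
#' @param clinical_effects Standardized shift of class-associated clinical
#'   variables (0 = null clinical signal).
#' @param missing_rates Named per-variable missingness rates in \[0, 1\]
#'   (see [default_missing_rates()]).
#' @param seed Integer seed; the cohort is bit-reproducible given it.
#' @param with_images If `FALSE`, skip image synthesis (clinical-only
#'   cohorts are much faster to draw).
#' @param image_args Named list overriding [phantom_spec()] arguments
#'   (e.g. smaller images for quick experiments).
#' @param marker_rate Fraction of images receiving caliper markers.
#'
#' @return An object of class `sln_cohort`: list with `images`,
#'   `lesion_masks`, `seeds` (per-image lesion centers, usable as
#'   region-growing seed points), `clinical` (a data.frame of the 12
#'   variables plus `patient_id`), `labels` (integer 0/1) and `prevalence`.
#' @export
gen_cohort <- function(n, prevalence = 27 / 142, class_effect = 0.5,
                       clinical_effects = 0.8,
                       missing_rates = default_missing_rates(),
                       seed = 1L, with_images = TRUE,
                       image_args = list(), marker_rate = 0.5) {
  if (n < 10) stop("`n` must be >= 10")
  if (prevalence <= 0 || prevalence >= 1) stop("`prevalence` must be in (0, 1)")
  if (any(missing_rates < 0 | missing_rates > 1))
    stop("missing rates must lie in [0, 1]")
  vars <- setdiff(clinical_variables(), character(0))
  rates <- default_missing_rates()
  rates[names(missing_rates)] <- missing_rates

  with_seed(seed, {
    n_pos <- round(n * prevalence)
    if (n_pos < 1 || n_pos > n - 1) stop("prevalence incompatible with n")
    labels <- integer(n)
    labels[sample.int(n, n_pos)] <- 1L

    clin <- gen_clinical_raw(n, labels, clinical_effects)
    for (v in vars) {
      if (rates[[v]] > 0) {
        miss <- stats::runif(n) < rates[[v]]
        clin[[v]][miss] <- NA
      }
    }
    clin <- clinical_table(clin)

    images <- lesion_masks <- seeds <- NULL
    if (with_images) {
      images <- vector("list", n); lesion_masks <- vector("list", n)
      seeds <- vector("list", n)
      base <- list(image_height = 128, image_width = 128)
      base[names(image_args)] <- image_args
      h <- base$image_height %||% 128; w <- base$image_width %||% 128
      for (i in seq_len(n)) {
        args <- base
        rr <- round(stats::runif(1, 0.10, 0.16) * h)
        rc <- round(stats::runif(1, 0.12, 0.19) * w)
        args$lesion_radii <- c(max(3, rr), max(3, rc))
        args$lesion_center <- c(
          round(h / 2 + stats::runif(1, -0.05, 0.05) * h),
          round(w / 2 + stats::runif(1, -0.05, 0.05) * w))
        if (is.null(args$background_mean))
          args$background_mean <- round(stats::runif(1, 155, 185))
        if (is.null(args$lesion_mean))
          args$lesion_mean <- round(stats::runif(1, 55, 85))
        if (is.null(args$speckle_scale)) args$speckle_scale <- 0.25
        args$class_effect <- if (labels[i] == 1L) class_effect else 0
        args$seed <- sample.int(.Machine$integer.max - 1L, 1)
        if (stats::runif(1) < marker_rate) {
          off <- round(0.8 * args$lesion_radii)
          args$marker_positions <- list(
            args$lesion_center + c(-off[1], 0), args$lesion_center + c(off[1], 0),
            args$lesion_center + c(0, -off[2]), args$lesion_center + c(0, off[2]))
        }
        ph <- gen_phantom(do.call(phantom_spec, args))
        images[[i]] <- ph$image
        lesion_masks[[i]] <- ph$lesion_mask
        seeds[[i]] <- args$lesion_center
      }
    }
    structure(list(images = images, lesion_masks = lesion_masks, seeds = seeds,
                   clinical = clin, labels = labels, prevalence = prevalence),
              class = "sln_cohort")
  })
}

#' @export
print.sln_cohort <- function(x, ...) {
  cat(sprintf("<sln_cohort> %d patients (%d positive), %s images\n",
              length(x$labels), sum(x$labels),
              if (is.null(x$images)) "no" else length(x$images)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes images as 8-bit grayscale PNG, ground-truth lesion masks as 0/255
#' PNG, the clinical table as CSV, and labels plus per-image metadata as a
#' JSON sidecar.
#'
#' @param cohort An [gen_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sln_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- cohort$clinical$patient_id
  if (!is.null(cohort$images)) {
    for (i in seq_along(cohort$images)) {
      write_us_image(cohort$images[[i]],
                     file.path(dir, sprintf("%s_image.png", ids[i])))
      write_us_image(cohort$lesion_masks[[i]],
                     file.path(dir, sprintf("%s_lesion.png", ids[i])))
    }
  }
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  meta <- list(labels = cohort$labels, prevalence = cohort$prevalence,
               seeds = cohort$seeds,
               spacing = if (is.null(cohort$images)) NULL
                         else cohort$images[[1]]$spacing)
  jsonlite::write_json(meta, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
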