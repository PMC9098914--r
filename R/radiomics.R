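# The four in-plane directions (row, col offsets): 0, 45, 90, 135 degrees.
texture_directions <- function() {
  list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L), `135` = c(-1L, -1L))
}

#' Quantize a masked region of interest
#'
#' Equal-width binning of the in-mask gray range into `levels` bins; a
#' constant region maps entirely to bin 1. Pixels outside the mask are `NA`.
#'
#' @param image A [us_image] or numeric matrix.
#' @param mask Non-empty logical matrix (same shape).
#' @param levels Number of gray bins (>= 2); 32 by default.
#' @return An object of class `quantized_roi`: list with `levels`, `grid`
#'   (integer bins in `1..levels`, `NA` outside the mask), `mask`,
#'   `n_pixels`.
#' @export
quantize <- function(image, mask, levels = 32L) {
  px <- if (inherits(image, "us_image")) image$pixels else image
  mask <- as_mask(mask)
  if (!identical(dim(mask), dim(px))) stop("mask and image shapes differ")
  if (!any(mask)) stop("mask is empty")
  if (levels < 2L) stop("`levels` must be >= 2")
  v <- px[mask]
  lo <- min(v); hi <- max(v)
  g <- matrix(NA_integer_, nrow(px), ncol(px))
  if (hi == lo) {
    g[mask] <- 1L
  } else {
    b <- floor((px[mask] - lo) / (hi - lo) * levels) + 1L
    g[mask] <- pmin(as.integer(b), as.integer(levels))
  }
  structure(list(levels = as.integer(levels), grid = g, mask = mask,
                 n_pixels = sum(mask)), class = "quantized_roi")
}

# internal: aligned (value, shifted-value) pairs along an offset
offset_pairs <- function(grid, off) {
  h <- nrow(grid); w <- ncol(grid)
  dr <- off[1]; dc <- off[2]
  rs <- max(1L, 1L - dr):min(h, h - dr)
  cs <- max(1L, 1L - dc):min(w, w - dc)
  a <- grid[rs, cs, drop = FALSE]
  b <- grid[rs + dr, cs + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  list(a = a[ok], b = b[ok])
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered in-mask pixel pairs `(p, p + offset)` accumulated
#' symmetrically; the normalized form sums to 1 unless no valid pair exists
#' (degenerate, flagged).
#'
#' @param q A [quantize()] result.
#' @param direction One of `"0"`, `"45"`, `"90"`, `"135"`.
#' @return List with `counts` (levels x levels), `prob`, `degenerate`.
#' @export
glcm <- function(q, direction = "0") {
  stopifnot(inherits(q, "quantized_roi"))
  off <- texture_directions()[[as.character(direction)]]
  if (is.null(off)) stop("direction must be one of 0, 45, 90, 135")
  L <- q$levels
  pr <- offset_pairs(q$grid, off)
  cnt <- matrix(tabulate((pr$a - 1L) * L + pr$b, L * L), L, L, byrow = TRUE)
  cnt <- cnt + t(cnt)
  tot <- sum(cnt)
  list(counts = cnt, prob = if (tot > 0) cnt / tot else cnt,
       degenerate = tot == 0)
}

# internal: per-line pixel sequences along a direction, NA-broken runs
direction_lines <- function(grid, direction) {
  h <- nrow(grid); w <- ncol(grid)
  rr <- matrix(seq_len(h), h, w); cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  key <- switch(as.character(direction),
                `0` = rr, `90` = cc, `45` = rr + cc, `135` = rr - cc)
  pos <- switch(as.character(direction),
                `0` = cc, `90` = rr, `45` = cc, `135` = cc)
  ord <- order(key, pos)
  split(as.vector(grid)[ord], as.vector(key)[ord])
}

#' Gray-level run-length matrix
#'
#' Counts maximal runs of consecutive same-level in-mask pixels along the
#' given direction. Column `j` of the result corresponds to run length `j`;
#' `sum(j * counts[, j])` equals the number of in-mask pixels.
#'
#' @inheritParams glcm
#' @return List with `counts` (levels x max run length), `degenerate`.
#' @export
glrlm <- function(q, direction = "0") {
  stopifnot(inherits(q, "quantized_roi"))
  if (!as.character(direction) %in% names(texture_directions()))
    stop("direction must be one of 0, 45, 90, 135")
  L <- q$levels
  lev <- integer(0); len <- integer(0)
  for (line in direction_lines(q$grid, direction)) {
    r <- rle(ifelse(is.na(line), -1L, line))
    keep <- r$values > 0L
    lev <- c(lev, r$values[keep]); len <- c(len, r$lengths[keep])
  }
  if (!length(lev))
    return(list(counts = matrix(0L, L, 1L), degenerate = TRUE))
  jmax <- max(len)
  cnt <- matrix(tabulate((lev - 1L) * jmax + len, L * jmax), L, jmax, byrow = TRUE)
  list(counts = cnt, degenerate = FALSE)
}

# internal: connected-component labels of same-level in-mask zones.
# Iterative minimum-label propagation over the neighborhood shifts;
# converges once labels stop changing.
label_zones <- function(grid, connectivity = 8L) {
  h <- nrow(grid); w <- ncol(grid)
  lab <- matrix(seq_len(h * w), h, w)
  lab[is.na(grid)] <- NA_integer_
  offs <- neighbor_offsets(as.integer(connectivity))
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(offs))) {
      dr <- offs[k, 1]; dc <- offs[k, 2]
      rs <- max(1L, 1L - dr):min(h, h - dr)
      cs <- max(1L, 1L - dc):min(w, w - dc)
      a <- lab[rs, cs, drop = FALSE]
      b <- lab[rs + dr, cs + dc, drop = FALSE]
      same <- !is.na(a) & !is.na(b) &
        grid[rs, cs, drop = FALSE] == grid[rs + dr, cs + dc, drop = FALSE]
      upd <- same & b < a
      if (any(upd)) {
        a[upd] <- b[upd]
        lab[rs, cs] <- a
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

#' Gray-level size-zone matrix
#'
#' Counts connected zones of same-level in-mask pixels by (level, size);
#' zones partition the mask, so `sum(j * counts[, j])` equals the pixel
#' count. 8-connectivity by default, 4-connectivity as an option.
#'
#' @inheritParams glcm
#' @param connectivity Zone connectivity, 8 (default) or 4.
#' @return List with `counts` (levels x max zone size), `degenerate`.
#' @export
glszm <- function(q, connectivity = 8L) {
  stopifnot(inherits(q, "quantized_roi"))
  lab <- label_zones(q$grid, connectivity)
  ok <- !is.na(lab)
  if (!any(ok)) return(list(counts = matrix(0L, q$levels, 1L), degenerate = TRUE))
  zones <- table(lab[ok])
  zlev <- q$grid[ok][match(names(zones), lab[ok])]
  sz <- as.integer(zones)
  jmax <- max(sz)
  L <- q$levels
  cnt <- matrix(tabulate((zlev - 1L) * jmax + sz, L * jmax), L, jmax, byrow = TRUE)
  list(counts = cnt, degenerate = FALSE)
}

#' Neighborhood gray-tone difference matrix
#'
#' For each level `i`: `n_i` counts in-mask pixels of level `i` with at least
#' one in-mask 8-neighbor, `s_i` sums the absolute difference between `i` and
#' the mean level of those neighbors, and `p_i = n_i / sum(n_i)`.
#'
#' @inheritParams glcm
#' @return List with `s`, `n`, `p` (length-`levels` vectors), `degenerate`.
#' @export
ngtdm <- function(q) {
  stopifnot(inherits(q, "quantized_roi"))
  g <- q$grid
  h <- nrow(g); w <- ncol(g)
  nb_sum <- matrix(0, h, w); nb_cnt <- matrix(0L, h, w)
  for (k in seq_len(8L)) {
    off <- neighbor_offsets(8L)[k, ]
    rs <- max(1L, 1L - off[1]):min(h, h - off[1])
    cs <- max(1L, 1L - off[2]):min(w, w - off[2])
    b <- g[rs + off[1], cs + off[2], drop = FALSE]
    okb <- !is.na(b)
    add <- matrix(0, h, w); addc <- matrix(0L, h, w)
    add[rs, cs][okb] <- b[okb]
    addc[rs, cs][okb] <- 1L
    nb_sum <- nb_sum + add; nb_cnt <- nb_cnt + addc
  }
  valid <- !is.na(g) & nb_cnt > 0L
  L <- q$levels
  s <- numeric(L); n <- integer(L)
  if (any(valid)) {
    lev <- g[valid]
    dev <- abs(lev - nb_sum[valid] / nb_cnt[valid])
    for (i in sort(unique(lev))) {
      sel <- lev == i
      s[i] <- sum(dev[sel]); n[i] <- sum(sel)
    }
  }
  tot <- sum(n)
  list(s = s, n = n, p = if (tot > 0) n / tot else rep(0, L),
       degenerate = tot == 0)
}

#' Compute all four texture-matrix families for a quantized ROI
#'
#' @inheritParams glcm
#' @param connectivity Zone connectivity for the size-zone matrix.
#' @return An object of class `texture_matrices`: per-direction GLCM and
#'   GLRLM, GLSZM, NGTDM, the direction set and `n_pixels`.
#' @export
texture_matrices <- function(q, connectivity = 8L) {
  dirs <- names(texture_directions())
  structure(list(
    glcm = lapply(stats::setNames(dirs, dirs), function(d) glcm(q, d)),
    glrlm = lapply(stats::setNames(dirs, dirs), function(d) glrlm(q, d)),
    glszm = glszm(q, connectivity),
    ngtdm = ngtdm(q),
    directions = dirs, n_pixels = q$n_pixels, levels = q$levels),
    class = "texture_matrices")
}

# ---- per-family statistic evaluators -------------------------------------

zero_if_bad <- function(x) if (length(x) != 1L || !is.finite(x)) 0 else x

glcm_stats <- function(P, L) {
  if (sum(P) == 0) {
    nm <- glcm_stat_names()
    return(stats::setNames(rep(0, length(nm)), nm))
  }
  i <- matrix(seq_len(L), L, L); j <- t(i)
  px <- rowSums(P)
  mu <- sum(i * P)            # symmetric: mu_x = mu_y
  sig2 <- sum((i - mu)^2 * P)
  ks <- 2:(2 * L); psum <- sapply(ks, function(k) sum(P[i + j == k]))
  kd <- 0:(L - 1); pdiff <- sapply(kd, function(k) sum(P[abs(i - j) == k]))
  da <- sum(kd * pdiff)
  ent0 <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  sa <- sum(ks * psum)
  out <- c(
    autocorrelation = sum(i * j * P),
    cluster_prominence = sum((i + j - 2 * mu)^4 * P),
    cluster_shade = sum((i + j - 2 * mu)^3 * P),
    cluster_tendency = sum((i + j - 2 * mu)^2 * P),
    contrast = sum((i - j)^2 * P),
    correlation = zero_if_bad((sum(i * j * P) - mu^2) / sig2),
    difference_average = da,
    difference_entropy = ent0(pdiff),
    difference_variance = sum((kd - da)^2 * pdiff),
    energy = sum(P^2),
    entropy = ent0(P),
    inverse_difference = sum(P / (1 + abs(i - j))),
    inverse_difference_moment = sum(P / (1 + (i - j)^2)),
    idmn = sum(P / (1 + (i - j)^2 / L^2)),
    idn = sum(P / (1 + abs(i - j) / L)),
    inverse_variance = sum(P[i != j] / (i - j)[i != j]^2),
    joint_average = mu,
    maximum_probability = max(P),
    sum_average = sa,
    sum_entropy = ent0(psum),
    sum_variance = sum((ks - sa)^2 * psum),
    variance = sig2)
  vapply(out, zero_if_bad, numeric(1))
}

glcm_stat_names <- function() {
  c("autocorrelation", "cluster_prominence", "cluster_shade",
    "cluster_tendency", "contrast", "correlation", "difference_average",
    "difference_entropy", "difference_variance", "energy", "entropy",
    "inverse_difference", "inverse_difference_moment", "idmn", "idn",
    "inverse_variance", "joint_average", "maximum_probability",
    "sum_average", "sum_entropy", "sum_variance", "variance")
}

glrlm_stats <- function(R, n_pixels) {
  nm <- glrlm_stat_names()
  Nr <- sum(R)
  if (Nr == 0) return(stats::setNames(rep(0, length(nm)), nm))
  L <- nrow(R); J <- ncol(R)
  i <- matrix(seq_len(L), L, J); j <- matrix(seq_len(J), L, J, byrow = TRUE)
  out <- c(
    short_run_emphasis = sum(R / j^2) / Nr,
    long_run_emphasis = sum(R * j^2) / Nr,
    gray_level_nonuniformity = sum(rowSums(R)^2) / Nr,
    run_length_nonuniformity = sum(colSums(R)^2) / Nr,
    run_percentage = Nr / n_pixels,
    low_gray_level_run_emphasis = sum(R / i^2) / Nr,
    high_gray_level_run_emphasis = sum(R * i^2) / Nr)
  vapply(stats::setNames(out, nm), zero_if_bad, numeric(1))
}

glrlm_stat_names <- function() {
  c("short_run_emphasis", "long_run_emphasis", "gray_level_nonuniformity",
    "run_length_nonuniformity", "run_percentage",
    "low_gray_level_run_emphasis", "high_gray_level_run_emphasis")
}

glszm_stats <- function(Z, n_pixels) {
  nm <- glszm_stat_names()
  Nz <- sum(Z)
  if (Nz == 0) return(stats::setNames(rep(0, length(nm)), nm))
  L <- nrow(Z); J <- ncol(Z)
  i <- matrix(seq_len(L), L, J); j <- matrix(seq_len(J), L, J, byrow = TRUE)
  p <- Z / Nz
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  pe <- p[p > 0]
  out <- c(
    small_area_emphasis = sum(Z / j^2) / Nz,
    large_area_emphasis = sum(Z * j^2) / Nz,
    gray_level_nonuniformity = sum(rowSums(Z)^2) / Nz,
    gray_level_nonuniformity_normalized = sum(rowSums(Z)^2) / Nz^2,
    size_zone_nonuniformity = sum(colSums(Z)^2) / Nz,
    size_zone_nonuniformity_normalized = sum(colSums(Z)^2) / Nz^2,
    zone_percentage = Nz / n_pixels,
    gray_level_variance = sum((i - mu_i)^2 * p),
    zone_variance = sum((j - mu_j)^2 * p),
    zone_entropy = -sum(pe * log2(pe)),
    low_gray_level_zone_emphasis = sum(Z / i^2) / Nz,
    high_gray_level_zone_emphasis = sum(Z * i^2) / Nz,
    small_area_low_gray_level_emphasis = sum(Z / (i^2 * j^2)) / Nz)
  vapply(stats::setNames(out, nm), zero_if_bad, numeric(1))
}

glszm_stat_names <- function() {
  c("small_area_emphasis", "large_area_emphasis", "gray_level_nonuniformity",
    "gray_level_nonuniformity_normalized", "size_zone_nonuniformity",
    "size_zone_nonuniformity_normalized", "zone_percentage",
    "gray_level_variance", "zone_variance", "zone_entropy",
    "low_gray_level_zone_emphasis", "high_gray_level_zone_emphasis",
    "small_area_low_gray_level_emphasis")
}

ngtdm_stats <- function(ng) {
  nm <- ngtdm_stat_names()
  p <- ng$p; s <- ng$s; n <- ng$n
  N <- sum(n)
  if (N == 0) return(stats::setNames(rep(0, length(nm)), nm))
  act <- which(p > 0)
  Ngp <- length(act)
  lev <- seq_along(p)
  coars_den <- sum(p * s)
  contrast <- if (Ngp > 1) {
    (sum(outer(p[act], p[act]) * outer(lev[act], lev[act], `-`)^2) /
       (Ngp * (Ngp - 1))) * (sum(s) / N)
  } else 0
  busy_den <- sum(abs(outer(lev[act] * p[act], lev[act] * p[act], `-`)))
  cplx <- 0; strength_num <- 0
  if (Ngp > 1) {
    pi_ <- p[act]; si <- s[act]; li <- lev[act]
    dd <- abs(outer(li, li, `-`))
    cplx <- sum(dd * (outer(pi_ * si, rep(1, Ngp)) + outer(rep(1, Ngp), pi_ * si)) /
                  (outer(pi_, rep(1, Ngp)) + outer(rep(1, Ngp), pi_))) / N
    strength_num <- sum((outer(pi_, rep(1, Ngp)) + outer(rep(1, Ngp), pi_)) * dd^2)
  }
  out <- c(
    coarseness = if (coars_den > 0) 1 / coars_den else 0,
    contrast = contrast,
    busyness = if (busy_den > 0) coars_den / busy_den else 0,
    complexity = cplx,
    strength = if (sum(s) > 0) strength_num / sum(s) else 0)
  vapply(stats::setNames(out, nm), zero_if_bad, numeric(1))
}

ngtdm_stat_names <- function() {
  c("coarseness", "contrast", "busyness", "complexity", "strength")
}

#' The 134-feature catalogue
#'
#' Reads the feature manifest shipped with the package: 22 co-occurrence
#' statistics in 4 directions (88), 7 run-length statistics in 4 directions
#' (28), 13 size-zone statistics and 5 neighborhood gray-tone difference
#' statistics — 134 named features in all. The manifest is data: a different
#' breakdown totalling 134 may be substituted by pointing `path` at another
#' manifest file.
#'
#' @param path Manifest JSON path (defaults to the installed manifest).
#' @return Data frame with columns `name`, `family`, `statistic`,
#'   `direction` (`NA` for direction-free families).
#' @export
feature_manifest <- function(path = system.file("extdata", "feature_manifest.json",
                                                package = "slnradiomics")) {
  man <- jsonlite::fromJSON(path)
  man$direction <- as.character(man$direction)
  man
}

#' Evaluate the named feature catalogue on texture matrices
#'
#' Produces the 134-feature vector (always finite: degenerate statistics
#' fall back to 0, with a warning when an entire family is degenerate).
#'
#' @param m A [texture_matrices()] result.
#' @param manifest A [feature_manifest()] data frame.
#' @return Named numeric vector, one value per manifest row.
#' @export
features_from_matrices <- function(m, manifest = feature_manifest()) {
  stopifnot(inherits(m, "texture_matrices"))
  if (m$glcm[[1]]$degenerate)
    warning("degenerate ROI: no valid pixel pair; co-occurrence features are 0")
  pools <- list()
  for (d in m$directions) {
    pools[[paste0("glcm.", d)]] <- glcm_stats(m$glcm[[d]]$prob, m$levels)
    pools[[paste0("glrlm.", d)]] <- glrlm_stats(m$glrlm[[d]]$counts, m$n_pixels)
  }
  pools[["glszm"]] <- glszm_stats(m$glszm$counts, m$n_pixels)
  pools[["ngtdm"]] <- ngtdm_stats(m$ngtdm)

  vals <- numeric(nrow(manifest))
  for (r in seq_len(nrow(manifest))) {
    key <- if (is.na(manifest$direction[r])) manifest$family[r]
           else paste0(manifest$family[r], ".", manifest$direction[r])
    vals[r] <- pools[[key]][[manifest$statistic[r]]]
  }
  stats::setNames(vals, manifest$name)
}

#' Radiomic feature vector of one masked region
#'
#' Convenience wrapper: quantize, build the four matrix families, evaluate
#' the 134-feature catalogue.
#'
#' @inheritParams quantize
#' @param connectivity Zone connectivity for the size-zone matrix.
#' @param manifest Feature catalogue (see [feature_manifest()]).
#' @return Named numeric vector of 134 finite values.
#' @export
radiomic_features <- function(image, mask, levels = 32L, connectivity = 8L,
                              manifest = feature_manifest()) {
  q <- quantize(image, mask, levels)
  features_from_matrices(texture_matrices(q, connectivity), manifest)
}

#' Radiomic features for the four ROI types
#'
#' Runs quantize, matrix construction and the feature catalogue
#' independently on each ROI of a [build_roi_set()] result; the original ROI
#' uses its full bounding rectangle as mask.
#'
#' @param image A [us_image] (the cleaned image).
#' @param roi_set A [build_roi_set()] result.
#' @inheritParams radiomic_features
#' @return Named list `original`, `intra`, `peri`, `combined`, each a
#'   134-feature named numeric vector.
#' @export
extract_roi_features <- function(image, roi_set, levels = 32L,
                                 connectivity = 8L,
                                 manifest = feature_manifest()) {
  stopifnot(inherits(roi_set, "roi_set"))
  masks <- list(
    original = box_mask(roi_set$original_box, dim(image$pixels)),
    intra = roi_set$intra_mask,
    peri = roi_set$peri_mask,
    combined = roi_set$combined_mask)
  out <- vector("list", length(masks)); names(out) <- names(masks)
  for (ty in names(masks)) {
    out[[ty]] <- tryCatch(
      radiomic_features(image, masks[[ty]], levels, connectivity, manifest),
      error = function(e) stop(sprintf("ROI '%s': %s", ty, conditionMessage(e))))
  }
  out
}
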