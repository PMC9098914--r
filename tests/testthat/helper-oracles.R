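# Independent brute-force oracles used to validate the texture-matrix
# builders, the rank AUC and the exact Mann-Whitney p. These deliberately
# share no code with the implementations they check.

oracle_dirs <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L),
                    `135` = c(-1L, -1L))

# symmetric co-occurrence counts by explicit enumeration of every pixel pair
oracle_glcm <- function(grid, direction, L) {
  off <- oracle_dirs[[as.character(direction)]]
  cnt <- matrix(0L, L, L)
  for (r in seq_len(nrow(grid))) for (c in seq_len(ncol(grid))) {
    r2 <- r + off[1]; c2 <- c + off[2]
    if (r2 < 1 || r2 > nrow(grid) || c2 < 1 || c2 > ncol(grid)) next
    a <- grid[r, c]; b <- grid[r2, c2]
    if (is.na(a) || is.na(b)) next
    cnt[a, b] <- cnt[a, b] + 1L
    cnt[b, a] <- cnt[b, a] + 1L
  }
  cnt
}

# maximal runs by walking each line pixel by pixel
oracle_glrlm <- function(grid, direction, L) {
  off <- oracle_dirs[[as.character(direction)]]
  h <- nrow(grid); w <- ncol(grid)
  starts <- list()
  for (r in seq_len(h)) for (c in seq_len(w)) {
    pr <- r - off[1]; pc <- c - off[2]
    if (pr < 1 || pr > h || pc < 1 || pc > w)
      starts[[length(starts) + 1L]] <- c(r, c)
  }
  runs <- list()
  for (s in starts) {
    r <- s[1]; c <- s[2]
    cur <- NA_integer_; len <- 0L
    while (r >= 1 && r <= h && c >= 1 && c <= w) {
      v <- grid[r, c]
      if (!is.na(v) && !is.na(cur) && v == cur) {
        len <- len + 1L
      } else {
        if (!is.na(cur)) runs[[length(runs) + 1L]] <- c(cur, len)
        cur <- v; len <- 1L
      }
      r <- r + off[1]; c <- c + off[2]
    }
    if (!is.na(cur)) runs[[length(runs) + 1L]] <- c(cur, len)
  }
  if (!length(runs)) return(matrix(0L, L, 1L))
  jmax <- max(vapply(runs, `[`, integer(1), 2L))
  cnt <- matrix(0L, L, jmax)
  for (rn in runs) cnt[rn[1], rn[2]] <- cnt[rn[1], rn[2]] + 1L
  cnt
}

# connected same-level zones by breadth-first flood fill
oracle_glszm <- function(grid, L, connectivity = 8L) {
  h <- nrow(grid); w <- ncol(grid)
  offs <- if (connectivity == 4L) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else {
    ol <- list()
    for (dr in -1:1) for (dc in -1:1)
      if (dr != 0 || dc != 0) ol[[length(ol) + 1L]] <- c(dr, dc)
    ol
  }
  seen <- matrix(FALSE, h, w)
  zones <- list()
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (seen[r, c] || is.na(grid[r, c])) next
    lv <- grid[r, c]
    queue <- list(c(r, c)); seen[r, c] <- TRUE; size <- 0L
    while (length(queue)) {
      p <- queue[[1L]]; queue[[1L]] <- NULL
      size <- size + 1L
      for (o in offs) {
        nr <- p[1] + o[1]; nc <- p[2] + o[2]
        if (nr < 1 || nr > h || nc < 1 || nc > w) next
        if (seen[nr, nc] || is.na(grid[nr, nc]) || grid[nr, nc] != lv) next
        seen[nr, nc] <- TRUE
        queue[[length(queue) + 1L]] <- c(nr, nc)
      }
    }
    zones[[length(zones) + 1L]] <- c(lv, size)
  }
  if (!length(zones)) return(matrix(0L, L, 1L))
  jmax <- max(vapply(zones, `[`, numeric(1), 2L))
  cnt <- matrix(0L, L, jmax)
  for (z in zones) cnt[z[1], z[2]] <- cnt[z[1], z[2]] + 1L
  cnt
}

# per-level neighborhood gray-tone sums by direct enumeration
oracle_ngtdm <- function(grid, L) {
  h <- nrow(grid); w <- ncol(grid)
  s <- numeric(L); n <- integer(L)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    v <- grid[r, c]
    if (is.na(v)) next
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nr <- r + dr; nc <- c + dc
      if (nr < 1 || nr > h || nc < 1 || nc > w) next
      if (!is.na(grid[nr, nc])) nb <- c(nb, grid[nr, nc])
    }
    if (!length(nb)) next
    s[v] <- s[v] + abs(v - mean(nb))
    n[v] <- n[v] + 1L
  }
  list(s = s, n = n)
}

# AUC by all-pairs comparison
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  if (!length(sp) || !length(sn)) return(NA_real_)
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# exact two-sided Mann-Whitney p by enumerating all label assignments
oracle_mw_exact_p <- function(x, y) {
  n <- length(x) + length(y)
  vals <- c(x, y)
  u_of <- function(ix) {
    xs <- vals[ix]; ys <- vals[-ix]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_along(x))
  us <- apply(utils::combn(n, length(x)), 2, u_of)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(p, 1)
}

# random quantized ROI (possibly with holes) for oracle comparisons
random_qgrid <- function(h = 8L, w = 8L, L = 4L, mask_prob = 0.85) {
  g <- matrix(sample.int(L, h * w, replace = TRUE), h, w)
  g[matrix(runif(h * w) > mask_prob, h, w)] <- NA_integer_
  if (all(is.na(g))) g[1, 1] <- 1L
  g
}

# wrap a raw quantized grid as the package's quantized_roi container
as_qroi <- function(grid, L) {
  structure(list(levels = as.integer(L), grid = grid, mask = !is.na(grid),
                 n_pixels = sum(!is.na(grid))), class = "quantized_roi")
}
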