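#' Derive an independent sub-seed from a master seed
#'
#' All generators draw their randomness from a single integer seed. Where a
#' generator needs several independent random streams (e.g. one per session or
#' per channel), sub-seeds are split off deterministically with a counter, so
#' each sub-stream is reproducible on its own.
#'
#' @param seed integer master seed.
#' @param counter non-negative integer stream index.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
split_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(counter))
  # Weyl-style mixing; stays inside 32-bit signed range via double arithmetic
  s <- (as.double(seed) %% 2147483647) + 1
  k <- (as.double(counter) %% 2147483647)
  v <- (s * 48271 + k * 30269 + 11) %% 2147483629
  as.integer(v)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Boxcar (moving-average) smoothing with shrinking edge windows
#' @keywords internal
boxcar_smooth <- function(x, half_width) {
  n <- length(x)
  if (half_width < 1L || n == 0L) {
    return(x)
  }
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half_width, 1L)
  hi <- pmin(i + half_width, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Otsu threshold for bimodal intensity histograms
#'
#' Maximizes between-class variance over a fixed number of histogram bins.
#' Used as the "auto" threshold for unattended mask creation; the returned
#' value is a cut in original intensity units, applied strictly (`> thr`).
#'
#' @param x numeric vector or matrix of intensities.
#' @param n_bins number of histogram bins.
#' @return threshold on the original intensity scale.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("no finite intensities")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    return(rng[1])
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  # an empty valley gives a plateau of equally optimal splits; take its middle
  best <- which(sigma_b >= max(sigma_b) * (1 - 1e-12))
  breaks[best[ceiling(length(best) / 2)] + 1L]
}

#' Label connected components in a binary matrix
#'
#' Two-pass union-find labelling. Connectivity is 8-neighbor by default
#' (diagonals connect), switchable to 4.
#'
#' @param mask logical matrix.
#' @param connectivity 8 or 4.
#' @return integer matrix of the same shape; 0 = background, components
#'   numbered from 1 in raster order of first occurrence.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  mask <- mask & !is.na(mask)
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (!any(mask)) {
    return(lab)
  }
  parent <- integer(0)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]] # path halving
      i <- parent[i]
    }
    i
  }
  next_label <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!mask[i, j]) next
      nb <- integer(0)
      if (i > 1L && lab[i - 1L, j] > 0L) nb <- c(nb, lab[i - 1L, j])
      if (j > 1L && lab[i, j - 1L] > 0L) nb <- c(nb, lab[i, j - 1L])
      if (connectivity == 8L && j > 1L) {
        if (i > 1L && lab[i - 1L, j - 1L] > 0L) nb <- c(nb, lab[i - 1L, j - 1L])
        if (i < nr && lab[i + 1L, j - 1L] > 0L) nb <- c(nb, lab[i + 1L, j - 1L])
      }
      if (length(nb) == 0L) {
        next_label <- next_label + 1L
        parent[next_label] <- next_label
        lab[i, j] <- next_label
      } else {
        roots <- vapply(unique(nb), find_root, integer(1))
        r <- min(roots)
        lab[i, j] <- r
        for (q in roots) parent[q] <- r
      }
    }
  }
  # second pass: resolve to roots, renumber compactly
  roots <- vapply(seq_len(next_label), find_root, integer(1))
  remap <- integer(next_label)
  remap[unique(roots)] <- seq_along(unique(roots))
  idx <- lab > 0L
  lab[idx] <- remap[roots[lab[idx]]]
  lab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
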