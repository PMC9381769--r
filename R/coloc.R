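#' Threshold an intensity image into a binary mask
#'
#' The mask keeps pixels strictly above the threshold. `threshold = "auto"`
#' uses Otsu's bimodal-histogram criterion ([otsu_threshold()]) for
#' unattended runs; the threshold actually used is recorded on the mask.
#'
#' @param img numeric intensity matrix.
#' @param threshold numeric cut (strict `>`), or `"auto"`.
#' @return logical matrix with attributes `threshold` and `min_area_um2`
#'   (`NA` until area-filtered).
#' @export
make_mask <- function(img, threshold = "auto") {
  stopifnot(is.matrix(img), length(img) > 0)
  thr <- if (identical(threshold, "auto")) {
    otsu_threshold(img)
  } else {
    as.numeric(threshold)
  }
  if (thr >= max(img)) {
    warning("threshold at or above maximum intensity: empty mask")
  }
  mask <- img > thr
  attr(mask, "threshold") <- thr
  attr(mask, "min_area_um2") <- NA_real_
  mask
}

#' Remove connected components below a surface-area cutoff
#'
#' Components (8-connectivity by default) whose area is strictly smaller
#' than `min_area_um2` are discarded. At 40-nm pixels the cutoff is
#' 0.1 um^2 / 0.0016 um^2 = 62.5 px, so components of <= 62 px are removed
#' and >= 63 px retained.
#'
#' @param mask logical matrix.
#' @param min_area_um2 area cutoff, um^2 (strict `<` removes).
#' @param pixel_size_nm pixel size, nm.
#' @param connectivity 8 (default) or 4.
#' @return filtered logical mask (attributes preserved, `min_area_um2`
#'   recorded).
#' @export
filter_small_components <- function(mask, min_area_um2 = 0.1, pixel_size_nm,
                                    connectivity = 8L) {
  stopifnot(is.matrix(mask), pixel_size_nm > 0)
  a <- attributes(mask)
  px_area_um2 <- (pixel_size_nm / 1000)^2
  lab <- label_components(mask, connectivity)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    small <- which(sizes * px_area_um2 < min_area_um2)
    if (length(small)) mask[lab %in% small] <- FALSE
  }
  attributes(mask) <- a
  attr(mask, "min_area_um2") <- min_area_um2
  mask
}

#' Signal density of a mask
#'
#' Fraction of the image covered: mask pixels / total pixels.
#'
#' @param mask logical matrix.
#' @return fraction in `[0, 1]`.
#' @export
signal_density <- function(mask) {
  stopifnot(is.matrix(mask))
  sum(mask) / length(mask)
}

#' Overlap mask of two channels
#'
#' Pixel-wise conjunction of two (already area-filtered) channel masks,
#' followed by another pass of the surface-area filter.
#'
#' @param mask_a,mask_b logical matrices of identical shape.
#' @param min_area_um2,pixel_size_nm,connectivity as in
#'   [filter_small_components()].
#' @return filtered overlap mask.
#' @export
overlap_mask <- function(mask_a, mask_b, min_area_um2 = 0.1, pixel_size_nm,
                         connectivity = 8L) {
  if (!all(dim(mask_a) == dim(mask_b))) stop("mask shapes differ")
  ov <- mask_a & mask_b
  filter_small_components(ov, min_area_um2, pixel_size_nm, connectivity)
}

#' Overlap area relative to a reference mask
#'
#' The statistic behind "fraction of all glutamatergic terminal area that is
#' also channel-A positive": `area(overlap) / area(reference)`.
#'
#' @param overlap overlap mask.
#' @param reference reference channel mask (non-empty).
#' @return fraction in `[0, 1]`, `NA` with a warning if the reference is
#'   empty.
#' @export
relative_density <- function(overlap, reference) {
  n_ref <- sum(reference)
  if (n_ref == 0L) {
    warning("empty reference mask: relative density undefined")
    return(NA_real_)
  }
  sum(overlap) / n_ref
}

#' Full two-channel densitometry
#'
#' Runs the whole procedure on a pair of intensity images: per-channel
#' thresholding, surface-area filtering, channel densities, overlap mask
#' (area-filtered again), overlap density, and the overlap density relative
#' to each channel.
#'
#' @param img_a,img_b intensity matrices (same shape).
#' @param pixel_size_nm pixel size, nm.
#' @param threshold_a,threshold_b numeric or `"auto"`.
#' @param min_area_um2 surface-area cutoff, um^2.
#' @param connectivity component connectivity.
#' @return a `coloc_result` list: `density_a`, `density_b`,
#'   `overlap_density`, `relative_to_a`, `relative_to_b`, `threshold_a`,
#'   `threshold_b`, `masks` (list a, b, overlap).
#' @export
coloc_densitometry <- function(img_a, img_b, pixel_size_nm,
                               threshold_a = "auto", threshold_b = "auto",
                               min_area_um2 = 0.1, connectivity = 8L) {
  if (!all(dim(img_a) == dim(img_b))) stop("image shapes differ")
  ma <- filter_small_components(
    make_mask(img_a, threshold_a), min_area_um2, pixel_size_nm, connectivity
  )
  mb <- filter_small_components(
    make_mask(img_b, threshold_b), min_area_um2, pixel_size_nm, connectivity
  )
  ov <- overlap_mask(ma, mb, min_area_um2, pixel_size_nm, connectivity)
  structure(
    list(
      density_a = signal_density(ma),
      density_b = signal_density(mb),
      overlap_density = signal_density(ov),
      relative_to_a = relative_density(ov, ma),
      relative_to_b = relative_density(ov, mb),
      threshold_a = attr(ma, "threshold"),
      threshold_b = attr(mb, "threshold"),
      masks = list(a = ma, b = mb, overlap = ov)
    ),
    class = "coloc_result"
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Two-channel densitometry\n",
      "  density A: %.4f  density B: %.4f  overlap: %.4f\n",
      "  overlap / A: %.4f  overlap / B: %.4f\n",
      "  thresholds: A %.3g, B %.3g\n"
    ),
    x$density_a, x$density_b, x$overlap_density,
    x$relative_to_a, x$relative_to_b, x$threshold_a, x$threshold_b
  ))
  invisible(x)
}

#' Centroid-distance colocalization by mutual nearest neighbors
#'
#' One-to-one matching of two point sets: a pair is matched iff each point
#' is the other's nearest neighbor and their distance is at most
#' `max_dist_um`. A greedy distance-sorted alternative is available.
#'
#' @param points_a,points_b two-column matrices or data.frames of (x, y) in
#'   um.
#' @param max_dist_um maximum pairing distance, um.
#' @param method `"mutual"` (default) or `"greedy"`.
#' @return list with `pairs` (data.frame `index_a`, `index_b`,
#'   `distance_um`), `matched_fraction_a`.
#' @export
centroid_colocalization <- function(points_a, points_b, max_dist_um = 2,
                                    method = c("mutual", "greedy")) {
  method <- match.arg(method)
  pa <- as.matrix(points_a)[, 1:2, drop = FALSE]
  pb <- as.matrix(points_b)[, 1:2, drop = FALSE]
  na <- nrow(pa)
  nb <- nrow(pb)
  empty <- data.frame(
    index_a = integer(0), index_b = integer(0), distance_um = numeric(0)
  )
  if (na == 0L || nb == 0L) {
    return(list(
      pairs = empty,
      matched_fraction_a = if (na == 0L) NA_real_ else 0
    ))
  }
  d <- sqrt(outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2)
  if (method == "mutual") {
    nn_a <- max.col(-d, ties.method = "first") # nearest B for each A
    nn_b <- max.col(-t(d), ties.method = "first") # nearest A for each B
    ia <- which(nn_b[nn_a] == seq_len(na) &
      d[cbind(seq_len(na), nn_a)] <= max_dist_um)
    pairs <- data.frame(
      index_a = ia, index_b = nn_a[ia],
      distance_um = d[cbind(ia, nn_a[ia])]
    )
  } else {
    ok <- which(d <= max_dist_um, arr.ind = TRUE)
    ord <- order(d[ok])
    ok <- ok[ord, , drop = FALSE]
    used_a <- logical(na)
    used_b <- logical(nb)
    keep <- logical(nrow(ok))
    for (r in seq_len(nrow(ok))) {
      i <- ok[r, 1]
      j <- ok[r, 2]
      if (!used_a[i] && !used_b[j]) {
        used_a[i] <- TRUE
        used_b[j] <- TRUE
        keep[r] <- TRUE
      }
    }
    ok <- ok[keep, , drop = FALSE]
    pairs <- data.frame(
      index_a = ok[, 1], index_b = ok[, 2],
      distance_um = d[ok]
    )
  }
  rownames(pairs) <- NULL
  list(pairs = pairs, matched_fraction_a = nrow(pairs) / na)
}
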