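#' Parameters for a synthetic two-channel punctum field
#'
#' Describes a pair of super-resolution images of punctate synaptic labelling
#' (channel A, e.g. CPLX3; channel B, e.g. VGluT1). Puncta are rendered as
#' isotropic 2-D Gaussians; a stated fraction of A puncta is placed within
#' `coloc_radius_nm` of a B punctum (colocalized), the rest are kept well away
#' from all B puncta so the ground-truth labels stay unambiguous.
#'
#' @param image_size_px image side in pixels (square).
#' @param pixel_size_nm pixel size, nm.
#' @param density_A,density_B puncta per um^2 (>= 0).
#' @param coloc_fraction fraction of A puncta colocalized with B, in `[0, 1]`.
#' @param coloc_radius_nm maximum center-to-center distance of a colocalized
#'   pair, nm; pairs are placed at distance ~ U(0, coloc_radius_nm) and a
#'   uniformly random angle. A radius below one pixel warns (sub-pixel
#'   placement).
#' @param punctum_sigma_nm Gaussian SD of a rendered punctum, nm.
#' @param amplitude peak intensity of a punctum (arbitrary units).
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @return a `punctum_field_params` list.
#' @export
punctum_field_params <- function(image_size_px = 512L, pixel_size_nm = 40,
                                 density_A = 0.3, density_B = 0.3,
                                 coloc_fraction = 0.15, coloc_radius_nm = 40,
                                 punctum_sigma_nm = 200, amplitude = 1000,
                                 noise_sd = 50) {
  stopifnot(
    image_size_px >= 8, pixel_size_nm > 0, density_A >= 0, density_B >= 0,
    coloc_fraction >= 0, coloc_fraction <= 1, punctum_sigma_nm > 0,
    noise_sd >= 0
  )
  if (coloc_radius_nm < pixel_size_nm) {
    warning("coloc_radius_nm below one pixel: sub-pixel pair placement")
  }
  structure(
    list(
      image_size_px = as.integer(image_size_px), pixel_size_nm = pixel_size_nm,
      density_A = density_A, density_B = density_B,
      coloc_fraction = coloc_fraction, coloc_radius_nm = coloc_radius_nm,
      punctum_sigma_nm = punctum_sigma_nm, amplitude = amplitude,
      noise_sd = noise_sd
    ),
    class = "punctum_field_params"
  )
}

# add one Gaussian punctum to an image matrix, in place-ish (returns matrix)
render_punctum <- function(img, cx_px, cy_px, sigma_px, amplitude) {
  n <- nrow(img)
  r <- ceiling(4 * sigma_px)
  i0 <- max(1L, floor(cx_px - r))
  i1 <- min(n, ceiling(cx_px + r))
  j0 <- max(1L, floor(cy_px - r))
  j1 <- min(n, ceiling(cy_px + r))
  if (i0 > i1 || j0 > j1) {
    return(img)
  }
  ii <- i0:i1
  jj <- j0:j1
  gx <- exp(-(ii - cx_px)^2 / (2 * sigma_px^2))
  gy <- exp(-(jj - cy_px)^2 / (2 * sigma_px^2))
  img[ii, jj] <- img[ii, jj] + amplitude * outer(gx, gy)
  img
}

#' Generate a synthetic two-channel punctum image pair with ground truth
#'
#' B puncta are placed uniformly (rejection keeps centers >= 2 sigma from the
#' borders). Exactly `round(coloc_fraction * N_A)` A puncta are placed within
#' `coloc_radius_nm` of a randomly chosen B punctum; the remaining A puncta
#' are placed with rejection at least `coloc_radius_nm + 2 * punctum_sigma_nm`
#' from every B center, so chance overlap cannot blur the ground-truth
#' labels. Both channels get independent additive Gaussian noise (clamped at
#' zero).
#'
#' @param params a [punctum_field_params()].
#' @param seed integer seed.
#' @return list with `image_A`, `image_B` (matrices, intensity units),
#'   `truth` (data.frame: `channel`, `x_um`, `y_um`, `colocalized`), and
#'   `params`.
#' @export
generate_punctum_image_pair <- function(params = punctum_field_params(),
                                        seed = 1L) {
  p <- params
  n <- p$image_size_px
  px_um <- p$pixel_size_nm / 1000
  side_um <- n * px_um
  area_um2 <- side_um^2
  n_A <- round(p$density_A * area_um2)
  n_B <- round(p$density_B * area_um2)
  if (p$density_A > 0 && n_A < 1) {
    stop("image too small to hold one A punctum at the stated density")
  }
  sigma_um <- p$punctum_sigma_nm / 1000
  margin <- 2 * sigma_um
  if (2 * margin >= side_um) stop("image too small for the punctum size")
  r_um <- p$coloc_radius_nm / 1000
  excl_um <- r_um + 2 * sigma_um

  placed <- with_seed(split_seed(seed, 0L), {
    bx <- stats::runif(n_B, margin, side_um - margin)
    by <- stats::runif(n_B, margin, side_um - margin)
    n_coloc <- round(p$coloc_fraction * n_A)
    ax <- numeric(n_A)
    ay <- numeric(n_A)
    is_coloc <- rep(FALSE, n_A)
    if (n_coloc > 0 && n_B == 0) {
      stop("cannot colocalize A puncta: no B puncta at this density")
    }
    # one-to-one host assignment: a colocalized A punctum IS one B punctum
    # with A-channel labelling, so distinct hosts until B is exhausted
    hosts <- if (n_coloc > 0) {
      sample.int(n_B, n_coloc, replace = n_coloc > n_B)
    } else {
      integer(0)
    }
    k <- 0L
    while (k < n_coloc) {
      host <- hosts[k + 1L]
      d <- stats::runif(1, 0, r_um)
      th <- stats::runif(1, 0, 2 * pi)
      x <- bx[host] + d * cos(th)
      y <- by[host] + d * sin(th)
      if (x >= margin && x <= side_um - margin &&
        y >= margin && y <= side_um - margin) {
        k <- k + 1L
        ax[k] <- x
        ay[k] <- y
        is_coloc[k] <- TRUE
      }
    }
    while (k < n_A) {
      x <- stats::runif(1, margin, side_um - margin)
      y <- stats::runif(1, margin, side_um - margin)
      if (n_B == 0 ||
        min((x - bx)^2 + (y - by)^2) > excl_um^2) {
        k <- k + 1L
        ax[k] <- x
        ay[k] <- y
      }
    }
    list(bx = bx, by = by, ax = ax, ay = ay, is_coloc = is_coloc)
  })

  img_A <- matrix(0, n, n)
  img_B <- matrix(0, n, n)
  sigma_px <- p$punctum_sigma_nm / p$pixel_size_nm
  # pixel (i, j) center is at ((i - 0.5) * px, (j - 0.5) * px)
  for (q in seq_len(n_B)) {
    img_B <- render_punctum(
      img_B, placed$bx[q] / px_um + 0.5, placed$by[q] / px_um + 0.5,
      sigma_px, p$amplitude
    )
  }
  for (q in seq_len(n_A)) {
    img_A <- render_punctum(
      img_A, placed$ax[q] / px_um + 0.5, placed$ay[q] / px_um + 0.5,
      sigma_px, p$amplitude
    )
  }
  if (p$noise_sd > 0) {
    noise <- with_seed(split_seed(seed, 1L), {
      list(
        a = matrix(stats::rnorm(n * n, 0, p$noise_sd), n, n),
        b = matrix(stats::rnorm(n * n, 0, p$noise_sd), n, n)
      )
    })
    img_A <- pmax(img_A + noise$a, 0)
    img_B <- pmax(img_B + noise$b, 0)
  }
  truth <- rbind(
    if (n_A > 0) {
      data.frame(
        channel = "A", x_um = placed$ax, y_um = placed$ay,
        colocalized = placed$is_coloc
      )
    },
    if (n_B > 0) {
      data.frame(
        channel = "B", x_um = placed$bx, y_um = placed$by,
        colocalized = NA
      )
    }
  )
  if (is.null(truth)) {
    truth <- data.frame(
      channel = character(0), x_um = numeric(0), y_um = numeric(0),
      colocalized = logical(0)
    )
  }
  list(image_A = img_A, image_B = img_B, truth = truth, params = p)
}
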