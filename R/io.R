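#' Read and write the pipeline's plain-text data formats
#'
#' Trajectories (`t_s`, `x_cm`, `y_cm`), spike trains (`unit_id`,
#' `spike_time_s`), EPSC traces (`t_ms`, `current_pA`) and nosepoke logs
#' (`animal_id`, `timestamp_s`, `port`, `assigned_port`, `group`) are
#' plain CSV; punctum images are 16-bit TIFF with a JSON sidecar carrying
#' the pixel size and, for synthetic images, the ground truth.
#'
#' @param x object to write.
#' @param path file path (for TIFF pairs, a path prefix).
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_trajectory_csv <- function(x, path) {
  utils::write.csv(x[, c("t_s", "x_cm", "y_cm")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @param arena an [arena_config()] to attach on read.
#' @export
read_trajectory_csv <- function(path, arena = arena_config()) {
  out <- utils::read.csv(path)
  stopifnot(all(c("t_s", "x_cm", "y_cm") %in% names(out)))
  class(out) <- c("trajectory", "data.frame")
  attr(out, "arena") <- arena
  out
}

#' @rdname pipeline_io
#' @export
write_spikes_csv <- function(x, path) {
  utils::write.csv(x[, c("unit_id", "spike_time_s")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_spikes_csv <- function(path) {
  out <- utils::read.csv(path)
  stopifnot(all(c("unit_id", "spike_time_s") %in% names(out)))
  class(out) <- c("spike_train", "data.frame")
  out
}

#' @rdname pipeline_io
#' @param pair a [generate_punctum_image_pair()] result.
#' @param max_intensity intensity mapped to the 16-bit maximum.
#' @export
write_punctum_tiff <- function(pair, path, max_intensity = NULL) {
  mx <- max_intensity %||% max(pair$image_A, pair$image_B, 1)
  to16 <- function(img) pmin(pmax(img / mx, 0), 1)
  tiff::writeTIFF(to16(pair$image_A), paste0(path, "_A.tif"),
    bits.per.sample = 16L
  )
  tiff::writeTIFF(to16(pair$image_B), paste0(path, "_B.tif"),
    bits.per.sample = 16L
  )
  sidecar <- list(
    pixel_size_nm = pair$params$pixel_size_nm,
    max_intensity = mx,
    truth = pair$truth
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_punctum_tiff <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  mx <- side$max_intensity
  list(
    image_A = tiff::readTIFF(paste0(path, "_A.tif")) * mx,
    image_B = tiff::readTIFF(paste0(path, "_B.tif")) * mx,
    truth = side$truth,
    pixel_size_nm = side$pixel_size_nm
  )
}

#' @rdname pipeline_io
#' @export
write_epsc_csv <- function(x, path) {
  utils::write.csv(x[, c("t_ms", "current_pA")], path, row.names = FALSE)
  jsonlite::write_json(
    list(stim_times_ms = attr(x, "stim_times_ms")),
    paste0(path, ".json"),
    digits = NA
  )
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_epsc_csv <- function(path) {
  out <- utils::read.csv(path)
  stopifnot(all(c("t_ms", "current_pA") %in% names(out)))
  class(out) <- c("epsc_trace", "data.frame")
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    attr(out, "stim_times_ms") <-
      unlist(jsonlite::read_json(sidecar, simplifyVector = TRUE)$stim_times_ms)
  }
  out
}

#' @rdname pipeline_io
#' @export
write_nosepoke_csv <- function(x, path) {
  utils::write.csv(
    x[, c("animal_id", "timestamp_s", "port", "assigned_port", "group")],
    path,
    row.names = FALSE
  )
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_nosepoke_csv <- function(path) {
  out <- utils::read.csv(path)
  stopifnot(all(
    c("animal_id", "timestamp_s", "port", "assigned_port") %in% names(out)
  ))
  out
}
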