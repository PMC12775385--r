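#' Display window for 8-bit conversion
#'
#' Conventional lung window by default (level -650 HU, width 1500 HU);
#' air maps darker than sponge matrix.
#'
#' @param level_hu window level (HU).
#' @param width_hu window width (HU, > 0).
#' @return an object of class `display_window`.
#' @export
display_window <- function(level_hu = -650, width_hu = 1500) {
    stop_if_not_scalar_pos(width_hu, "width_hu")
    structure(list(level_hu = level_hu, width_hu = width_hu),
              class = "display_window")
}

#' Convert a CT image to 8-bit grayscale under a display window
#'
#' Linear map of `[level - width/2, level + width/2]` onto `[0, 255]` with
#' clipping outside and round-half-up quantization.
#'
#' @param img a [ct_image()] or a numeric HU matrix.
#' @param win a [display_window()].
#' @return an object of class `spas_image8`: integer pixel matrix in
#'   0..255 plus carried metadata (`pixel_mm`, `mode`, `compression_pct`).
#' @export
window_to_8bit <- function(img, win = display_window()) {
    stopifnot(inherits(win, "display_window"))
    if (inherits(img, "ct_image")) {
        px <- img$pixels; pixel_mm <- img$pixel_mm
        mode <- img$mode; cp <- img$compression_pct
    } else {
        px <- img; pixel_mm <- NA_real_; mode <- NA_character_; cp <- NA_real_
    }
    lo <- win$level_hu - win$width_hu / 2
    g <- round_half_up(255 * (px - lo) / win$width_hu)
    g[g < 0] <- 0L
    g[g > 255] <- 255L
    structure(list(pixels = matrix(as.integer(g), nrow(px), ncol(px)),
                   pixel_mm = pixel_mm, mode = mode, compression_pct = cp,
                   window = win),
              class = "spas_image8")
}

#' @export
print.spas_image8 <- function(x, ...) {
    cat(sprintf("spas_image8 [%s]: %d x %d px, gray range [%d, %d]\n",
                x$mode, nrow(x$pixels), ncol(x$pixels),
                min(x$pixels), max(x$pixels)))
    invisible(x)
}

#' Physical parameters of the compression/acquisition setup
#'
#' @param stroke_mm maximal compression length of the plunger (mm).
#' @param rotation_s CT tube rotation time (s).
#' @param recon `"half"` or `"full"` reconstruction; the temporal window
#'   of one image is `rotation_s/2` or `rotation_s` respectively.
#' @param camera_fps reference-camera frame rate (frames/s).
#' @param dose_factor dose-length-product to effective-dose factor.
#' @return an object of class `physics_params`.
#' @export
physics_params <- function(stroke_mm = 15, rotation_s = 0.35,
                           recon = c("half", "full"), camera_fps = 30,
                           dose_factor = 0.014) {
    recon <- match.arg(recon)
    stop_if_not_scalar_pos(stroke_mm, "stroke_mm", allow_zero = TRUE)
    stop_if_not_scalar_pos(rotation_s, "rotation_s", allow_zero = TRUE)
    stop_if_not_scalar_pos(camera_fps, "camera_fps")
    stop_if_not_scalar_pos(dose_factor, "dose_factor")
    structure(list(stroke_mm = stroke_mm, rotation_s = rotation_s,
                   recon = recon, camera_fps = camera_fps,
                   dose_factor = dose_factor),
              class = "physics_params")
}

#' Compression percentage from section lengths
#'
#' `(1 - length_mm / length0_mm) * 100`, the plunger-axis length ratio.
#'
#' @param length_mm current longitudinal extent (mm).
#' @param length0_mm uncompressed extent (mm).
#' @return percentage in `[0, 100)`.
#' @export
compression_percentage <- function(length_mm, length0_mm) {
    if (any(length_mm <= 0) || any(length0_mm <= 0) ||
        any(length_mm > length0_mm))
        stop("lengths must satisfy 0 < length_mm <= length0_mm", call. = FALSE)
    (1 - length_mm / length0_mm) * 100
}

#' Compression velocity of the plunger
#'
#' The full stroke is traversed during the compression half of the cycle:
#' `stroke_mm / (cycle_s / 2)`.
#'
#' @param params a [physics_params()].
#' @param cycle_s compression-cycle duration (s).
#' @return velocity in mm/s.
#' @export
compression_velocity <- function(params = physics_params(), cycle_s) {
    stop_if_not_scalar_pos(cycle_s, "cycle_s")
    params$stroke_mm / (cycle_s / 2)
}

#' Estimated per-image motion blur on CT
#'
#' Compression velocity times the temporal window of one reconstructed
#' image (`rotation_s/2` for half reconstruction, `rotation_s` for full).
#'
#' @inheritParams compression_velocity
#' @return blur length in mm per image.
#' @export
motion_blur_ct <- function(params = physics_params(), cycle_s) {
    win <- if (params$recon == "half") params$rotation_s / 2 else params$rotation_s
    compression_velocity(params, cycle_s) * win
}

#' Estimated per-frame motion blur on the reference camera
#'
#' @inheritParams compression_velocity
#' @return blur length in mm per frame.
#' @export
motion_blur_camera <- function(params = physics_params(), cycle_s) {
    compression_velocity(params, cycle_s) / params$camera_fps
}

#' Circle-equivalent diameter of an area
#'
#' @param area_mm2 area (mm^2, >= 0).
#' @return `2 * sqrt(area / pi)` in mm.
#' @export
circle_equivalent_diameter <- function(area_mm2) {
    if (any(area_mm2 < 0)) stop("`area_mm2` must be >= 0", call. = FALSE)
    2 * sqrt(area_mm2 / pi)
}

#' Effective dose from a dose-length product
#'
#' @param dlp dose-length product (>= 0).
#' @param params a [physics_params()] supplying the conversion factor.
#' @return `dlp * dose_factor`.
#' @export
effective_dose <- function(dlp, params = physics_params()) {
    if (any(dlp < 0)) stop("`dlp` must be >= 0", call. = FALSE)
    dlp * params$dose_factor
}
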