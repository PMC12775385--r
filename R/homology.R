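#' Betti numbers of a binary image
#'
#' `b0` is the number of foreground (air/white) connected components
#' under 8-connectivity; `b1` is the number of background components
#' under 4-connectivity that do not touch the image border (holes).  The
#' complementary connectivity pair (8 for foreground, 4 for background)
#' gives a consistent digital topology.
#'
#' @param bin a [binary_image()].
#' @param min_area_mm2 optional component-size floor applied to `b0`
#'   (components smaller than this are ignored); `NULL` counts all,
#'   including isolated pixels.
#' @return named integer vector `c(b0, b1)`.
#' @export
betti_numbers <- function(bin, min_area_mm2 = NULL) {
    stopifnot(inherits(bin, "binary_image"))
    min_px <- min_area_px(min_area_mm2, bin$pixel_mm)
    .betti_cpp(bin$pixels, min_px)
}

min_area_px <- function(min_area_mm2, pixel_mm) {
    if (is.null(min_area_mm2) || is.na(min_area_mm2) || min_area_mm2 <= 0)
        return(1L)
    if (!is.finite(pixel_mm) || pixel_mm <= 0)
        stop("a pixel spacing is required to apply `min_area_mm2`",
             call. = FALSE)
    as.integer(ceiling(min_area_mm2 / pixel_mm^2 - 1e-9))
}

#' Multi-threshold Betti-number curve of an 8-bit image
#'
#' Sweeps every threshold `t` in 0..255, binarizing with air as
#' foreground (`gray < t`), and records `(b0, b1)` at each level.  The
#' sweep is a filtration: the foreground at a lower threshold is nested
#' in the foreground at any higher one.  `peak_b0`, the maximum of `b0`
#' over the sweep, summarizes the total air-space count independently of
#' any single display threshold.
#'
#' @param img8 a [window_to_8bit()] result (or integer matrix 0..255, in
#'   which case `pixel_mm` must be given when `min_area_mm2` is used).
#' @param min_area_mm2 optional component-size floor for `b0`.
#' @param pixel_mm pixel spacing override.
#' @return an object of class `homology_curve`: `thresholds` (0..255),
#'   `b0`, `b1`, `peak_b0`, `peak_threshold` (smallest threshold
#'   attaining the maximum).
#' @export
homology_curve <- function(img8, min_area_mm2 = NULL, pixel_mm = NULL) {
    if (inherits(img8, "spas_image8")) {
        px <- img8$pixels
        if (is.null(pixel_mm)) pixel_mm <- img8$pixel_mm
    } else {
        px <- img8
    }
    if (length(px) == 0L) stop("image is empty", call. = FALSE)
    min_px <- min_area_px(min_area_mm2, if (is.null(pixel_mm)) NA_real_ else pixel_mm)
    sw <- .betti_sweep_cpp(matrix(as.integer(px), nrow(px), ncol(px)), min_px)
    b0 <- sw$b0
    structure(list(thresholds = 0:255, b0 = b0, b1 = sw$b1,
                   peak_b0 = max(b0),
                   peak_threshold = (0:255)[which.max(b0)],
                   min_area_mm2 = min_area_mm2),
              class = "homology_curve")
}

#' @export
print.homology_curve <- function(x, ...) {
    cat(sprintf("homology_curve: peak b0 = %d at threshold %d (b1 max %d)\n",
                x$peak_b0, x$peak_threshold, max(x$b1)))
    invisible(x)
}

#' @export
plot.homology_curve <- function(x, ...) {
    graphics::plot(x$thresholds, x$b0, type = "l", xlab = "threshold",
                   ylab = "count", ...)
    graphics::lines(x$thresholds, x$b1, lty = 2)
    graphics::abline(v = x$peak_threshold, col = "grey")
    graphics::legend("topright", legend = c("b0", "b1"), lty = c(1, 2),
                     bty = "n")
    invisible(x)
}

#' Peak-b0 values across a phase series
#'
#' @param images list of [ct_image()]s (>= 2 phases).
#' @param win a [display_window()] applied before the sweep.
#' @param min_area_mm2 optional component-size floor for `b0`.
#' @return data frame with one row per image: `compression_pct`, `mode`,
#'   `peak_b0`, `peak_threshold`.
#' @export
peak_b0_series <- function(images, win = display_window(),
                           min_area_mm2 = NULL) {
    rows <- lapply(images, function(img) {
        hc <- homology_curve(window_to_8bit(img, win),
                             min_area_mm2 = min_area_mm2)
        data.frame(compression_pct = img$compression_pct, mode = img$mode,
                   peak_b0 = hc$peak_b0, peak_threshold = hc$peak_threshold)
    })
    do.call(rbind, rows)
}
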