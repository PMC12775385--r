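#' Imaging mode parameterization
#'
#' Bundles the acquisition parameters of one rendering pathway.  Built-in
#' defaults follow the two CT protocols sharing a 256 mm field of view
#' (NR: 512 matrix, 0.5 mm pixels; UHR: 1024 matrix, 0.25 mm pixels) and a
#' near-ideal reference rendering on a 0.05 mm grid.  The point-spread
#' function is an isotropic Gaussian whose sigma is fixed by the 5%
#' modulation-transfer frequency through `MTF(f) = exp(-2 pi^2 sigma^2 f^2)`;
#' the default noise levels are the 20 mA noise magnitudes (HU) of the two
#' protocols.
#'
#' @param name one of `"UHR"`, `"NR"`, `"REFERENCE"`.
#' @param pixel_mm pixel spacing override (mm).
#' @param mtf5_cyc_per_mm 5% MTF frequency override (cycles/mm).
#' @param noise_sd_hu additive Gaussian noise standard deviation (HU).
#' @param blur_mm per-image motion-blur length along the longitudinal axis.
#' @param slice_label free-text label.
#' @return an object of class `imaging_mode`.
#' @export
imaging_mode <- function(name = c("UHR", "NR", "REFERENCE"),
                         pixel_mm = NULL, mtf5_cyc_per_mm = NULL,
                         noise_sd_hu = NULL, blur_mm = 0,
                         slice_label = "") {
    name <- match.arg(name)
    defaults <- switch(name,
        UHR       = list(pixel_mm = 0.25, mtf5 = 1.26, noise = 14.6),
        NR        = list(pixel_mm = 0.5,  mtf5 = 0.61, noise = 17.8),
        REFERENCE = list(pixel_mm = 0.05, mtf5 = 40,   noise = 0))
    if (is.null(pixel_mm)) pixel_mm <- defaults$pixel_mm
    if (is.null(mtf5_cyc_per_mm)) mtf5_cyc_per_mm <- defaults$mtf5
    if (is.null(noise_sd_hu)) noise_sd_hu <- defaults$noise
    stop_if_not_scalar_pos(pixel_mm, "pixel_mm")
    stop_if_not_scalar_pos(mtf5_cyc_per_mm, "mtf5_cyc_per_mm")
    stop_if_not_scalar_pos(noise_sd_hu, "noise_sd_hu", allow_zero = TRUE)
    stop_if_not_scalar_pos(blur_mm, "blur_mm", allow_zero = TRUE)
    if (name == "REFERENCE") {
        if (noise_sd_hu != 0)
            stop("REFERENCE mode must be noiseless", call. = FALSE)
        if (psf_sigma_mm(mtf5_cyc_per_mm) >= pixel_mm)
            stop("REFERENCE mode requires a PSF narrower than one pixel",
                 call. = FALSE)
    }
    structure(list(name = name, pixel_mm = pixel_mm,
                   mtf5_cyc_per_mm = mtf5_cyc_per_mm,
                   noise_sd_hu = noise_sd_hu, blur_mm = blur_mm,
                   slice_label = slice_label),
              class = "imaging_mode")
}

#' Gaussian PSF sigma from the 5% MTF frequency
#'
#' Solves `exp(-2 pi^2 sigma^2 f^2) = 0.05` for sigma at `f = mtf5`.
#'
#' @param mtf5_cyc_per_mm frequency (cycles/mm) at which the MTF is 5%.
#' @return sigma in mm.
#' @export
psf_sigma_mm <- function(mtf5_cyc_per_mm) {
    sqrt(log(20) / (2 * pi^2)) / mtf5_cyc_per_mm
}

#' Construct a CT image container
#'
#' The first array axis is the longitudinal (compression) direction; pixel
#' `[i, j]` is centred at `((i - 0.5) * pixel_mm, (j - 0.5) * pixel_mm)`.
#'
#' @param pixels numeric matrix of CT numbers (HU), both dimensions >= 16.
#' @param pixel_mm pixel spacing (mm).
#' @param mode mode name tag.
#' @param compression_pct compression percentage of the imaged phase.
#' @param truth_id optional provenance link.
#' @param seed noise seed used at render time, if any.
#' @return an object of class `ct_image`.
#' @export
ct_image <- function(pixels, pixel_mm, mode = "UHR", compression_pct = 0,
                     truth_id = NULL, seed = NULL) {
    if (!is.matrix(pixels) || any(dim(pixels) < 16L))
        stop("`pixels` must be a matrix with both dimensions >= 16", call. = FALSE)
    if (!all(is.finite(pixels)))
        stop("`pixels` must be finite", call. = FALSE)
    stop_if_not_scalar_pos(pixel_mm, "pixel_mm")
    structure(list(pixels = pixels, pixel_mm = pixel_mm, mode = mode,
                   compression_pct = compression_pct, truth_id = truth_id,
                   seed = seed),
              class = "ct_image")
}

#' @export
print.ct_image <- function(x, ...) {
    cat(sprintf("ct_image [%s]: %d x %d px @ %.3g mm, compression %.1f%%, HU range [%.0f, %.0f]\n",
                x$mode, nrow(x$pixels), ncol(x$pixels), x$pixel_mm,
                x$compression_pct, min(x$pixels), max(x$pixels)))
    invisible(x)
}

# area-weighted rasterization of the two-level HU field on a pixel grid;
# supersampling is applied per-ellipse over its bounding box only
rasterize_truth <- function(truth, pixel_mm, supersample = 4L) {
    spec <- truth$spec
    n1 <- max(16L, as.integer(round(truth$section_length_mm / pixel_mm)))
    n2 <- max(16L, as.integer(round(truth$width_mm / pixel_mm)))
    cover <- matrix(0, n1, n2)
    s <- as.integer(supersample)
    offs <- ((seq_len(s) - 0.5) / s - 0.5) * pixel_mm
    open <- truth$spas[!truth$spas$closed, , drop = FALSE]
    if (nrow(open)) {
        for (k in seq_len(nrow(open))) {
            rl <- open$d_long_mm[k] / 2
            rt <- open$d_trans_mm[k] / 2
            cy <- open$cy_mm[k]; cx <- open$cx_mm[k]
            i1 <- max(1L, floor((cy - rl) / pixel_mm - 1) + 1L)
            i2 <- min(n1, ceiling((cy + rl) / pixel_mm + 1))
            j1 <- max(1L, floor((cx - rt) / pixel_mm - 1) + 1L)
            j2 <- min(n2, ceiling((cx + rt) / pixel_mm + 1))
            if (i1 > i2 || j1 > j2) next
            yc <- (seq(i1, i2) - 0.5) * pixel_mm
            xc <- (seq(j1, j2) - 0.5) * pixel_mm
            acc <- matrix(0, length(yc), length(xc))
            for (oy in offs) {
                u2 <- ((yc + oy - cy) / rl)^2
                for (ox in offs) {
                    v2 <- ((xc + ox - cx) / rt)^2
                    acc <- acc + (outer(u2, v2, `+`) <= 1)
                }
            }
            cover[i1:i2, j1:j2] <- cover[i1:i2, j1:j2] + acc / (s * s)
        }
        cover[cover > 1] <- 1
    }
    spec$matrix_hu + cover * (spec$air_hu - spec$matrix_hu)
}

gaussian_kernel <- function(sigma_px) {
    r <- max(1L, ceiling(4 * sigma_px))
    w <- dnorm(seq(-r, r), sd = sigma_px)
    w / sum(w)
}

# symmetric discrete box of continuous length len_px (pixel units); tap i
# weights the overlap of [i - 1/2, i + 1/2] with [-len/2, len/2]
box_kernel <- function(len_px) {
    if (len_px <= 1) return(1)
    r <- ceiling((len_px - 1) / 2)
    i <- seq(-r, r)
    w <- pmax(0, pmin(i + 0.5, len_px / 2) - pmax(i - 0.5, -len_px / 2))
    w / sum(w)
}

# 1-D convolution along the given axis with replicate (edge-clamp) padding
convolve_axis <- function(m, k, axis = 1L) {
    L <- length(k)
    if (L == 1L) return(m * k)
    r <- (L - 1L) %/% 2L
    if (axis == 2L) return(t(convolve_axis(t(m), k, 1L)))
    nr <- nrow(m)
    pad <- rbind(m[rep(1L, r), , drop = FALSE], m,
                 m[rep(nr, r), , drop = FALSE])
    out <- matrix(0, nr, ncol(m))
    for (j in seq_len(L)) out <- out + k[j] * pad[j:(j + nr - 1L), , drop = FALSE]
    out
}

#' Render a phantom truth through an imaging mode
#'
#' The two-level HU field (air inside open SPAS, matrix elsewhere) is
#' rasterized by area-weighted supersampling, convolved with the mode's
#' Gaussian PSF, convolved with a 1-D box kernel of length `blur_mm` along
#' the longitudinal axis (motion blur), and finally degraded with white
#' Gaussian noise of standard deviation `noise_sd_hu`.  A PSF sigma below
#' a quarter pixel is applied as the identity (a notice is emitted).
#'
#' @param truth a [phantom_truth][generate_phantom()] object.
#' @param mode an [imaging_mode()].
#' @param seed integer noise seed; rendering is deterministic given
#'   `(truth, mode, seed)`.
#' @param supersample supersampling factor per axis (>= 4 recommended).
#' @return a [ct_image()].
#' @export
render_image <- function(truth, mode, seed = 0L, supersample = 4L) {
    stopifnot(inherits(truth, "phantom_truth"), inherits(mode, "imaging_mode"))
    img <- rasterize_truth(truth, mode$pixel_mm, supersample)
    sigma_px <- psf_sigma_mm(mode$mtf5_cyc_per_mm) / mode$pixel_mm
    if (sigma_px >= 0.25) {
        k <- gaussian_kernel(sigma_px)
        img <- convolve_axis(convolve_axis(img, k, 1L), k, 2L)
    } else {
        message(sprintf(
            "PSF sigma (%.3g px) below 1/4 pixel; applied as identity",
            sigma_px))
    }
    if (mode$blur_mm > 0) {
        kb <- box_kernel(mode$blur_mm / mode$pixel_mm)
        img <- convolve_axis(img, kb, 1L)
    }
    if (mode$noise_sd_hu > 0) {
        noise <- with_seed(seed,
            matrix(rnorm(length(img), 0, mode$noise_sd_hu),
                   nrow(img), ncol(img)))
        img <- img + noise
    }
    ct_image(img, mode$pixel_mm, mode = mode$name,
             compression_pct = truth$compression_pct, seed = seed)
}
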