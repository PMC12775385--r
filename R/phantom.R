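#' Specification of a synthetic sponge cross-section
#'
#' Describes a rectangular sponge cross-section containing elliptical
#' simulated peripheral air spaces (SPAS).  The section is oriented with
#' its longitudinal (compression) axis first: `height_mm` is the extent
#' along the plunger direction, `width_mm` the transverse extent.
#'
#' Air-space areas are sampled log-uniformly over `area_range_mm2` and
#' shaped as axis-aligned ellipses with the long axis transverse
#' (`aspect = d_trans / d_long` drawn uniformly from `aspect_range`).
#' When `matrix_hu` is `NULL` it is calibrated analytically so that the
#' whole-section mean CT number equals `target_mean_hu` given the sampled
#' air fraction.
#'
#' @param width_mm transverse extent of the section (mm).
#' @param height_mm longitudinal (compression-axis) extent (mm).
#' @param n_spas number of air spaces to place.
#' @param area_range_mm2 length-2 sampling range for SPAS areas (mm^2).
#' @param aspect_range length-2 range of the transverse/longitudinal
#'   diameter ratio (>= 1: long axis transverse).
#' @param min_gap_mm minimum wall thickness between neighbouring SPAS (mm).
#' @param matrix_hu CT number of the sponge matrix, or `NULL` to calibrate
#'   against `target_mean_hu`.
#' @param air_hu CT number inside an air space.
#' @param target_mean_hu calibration target for the whole-section mean HU.
#' @param seed integer random seed; the phantom is deterministic given it.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(width_mm = 60, height_mm = 35, n_spas = 60,
                         area_range_mm2 = c(0.2, 10),
                         aspect_range = c(1, 3),
                         min_gap_mm = 0.5,
                         matrix_hu = NULL, air_hu = -1000,
                         target_mean_hu = -776, seed = 1L) {
    stop_if_not_scalar_pos(width_mm, "width_mm")
    stop_if_not_scalar_pos(height_mm, "height_mm")
    if (!is.numeric(n_spas) || length(n_spas) != 1L || n_spas < 0)
        stop("`n_spas` must be a non-negative count", call. = FALSE)
    if (length(area_range_mm2) != 2L || area_range_mm2[1] <= 0 ||
        diff(area_range_mm2) < 0)
        stop("`area_range_mm2` must be an increasing range with positive lower bound",
             call. = FALSE)
    if (length(aspect_range) != 2L || aspect_range[1] < 1 ||
        diff(aspect_range) < 0)
        stop("`aspect_range` must be an increasing range with lower bound >= 1",
             call. = FALSE)
    stop_if_not_scalar_pos(min_gap_mm, "min_gap_mm", allow_zero = TRUE)
    if (!is.null(matrix_hu) && air_hu >= matrix_hu)
        stop("`air_hu` must be below `matrix_hu`", call. = FALSE)
    structure(list(width_mm = width_mm, height_mm = height_mm,
                   n_spas = as.integer(n_spas),
                   area_range_mm2 = as.numeric(area_range_mm2),
                   aspect_range = as.numeric(aspect_range),
                   min_gap_mm = min_gap_mm, matrix_hu = matrix_hu,
                   air_hu = air_hu, target_mean_hu = target_mean_hu,
                   seed = as.integer(seed)),
              class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
    cat(sprintf("phantom_spec: %.0f x %.0f mm section, %d SPAS, areas %.2g-%.2g mm^2, seed %d\n",
                x$width_mm, x$height_mm, x$n_spas,
                x$area_range_mm2[1], x$area_range_mm2[2], x$seed))
    invisible(x)
}

#' Generate an uncompressed phantom ground truth
#'
#' Places `n_spas` elliptical air spaces by rejection sampling so that the
#' wall thickness between any two SPAS is at least `min_gap_mm` (checked
#' conservatively on the bounding circles) and every ellipse lies inside
#' the section.  If `matrix_hu` is unset it is solved from the sampled air
#' fraction so the rendered whole-section mean equals `target_mean_hu`.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom_truth` with a `spas` data frame
#'   (id, cx_mm transverse centre, cy_mm longitudinal centre, d_long_mm,
#'   d_trans_mm, area_mm2, closed), section geometry and the resolved spec.
#' @export
generate_phantom <- function(spec) {
    stopifnot(inherits(spec, "phantom_spec"))
    n <- spec$n_spas
    spas <- with_seed(spec$seed, {
        if (n == 0L) {
            data.frame(id = integer(), cx_mm = numeric(), cy_mm = numeric(),
                       d_long_mm = numeric(), d_trans_mm = numeric(),
                       area_mm2 = numeric(), closed = logical())
        } else {
            area <- exp(stats::runif(n, log(spec$area_range_mm2[1]),
                                     log(spec$area_range_mm2[2])))
            aspect <- stats::runif(n, spec$aspect_range[1], spec$aspect_range[2])
            d_trans <- sqrt(4 * area * aspect / pi)
            d_long <- d_trans / aspect
            # place large SPAS first: packing succeeds with fewer rejections
            ord <- order(area, decreasing = TRUE)
            area <- area[ord]; aspect <- aspect[ord]
            d_trans <- d_trans[ord]; d_long <- d_long[ord]
            cx <- cy <- numeric(n)
            placed <- 0L
            attempts <- 0L
            budget <- 10L * n
            edge <- spec$min_gap_mm / 2
            while (placed < n && attempts < budget) {
                attempts <- attempts + 1L
                k <- placed + 1L
                px <- stats::runif(1, d_trans[k] / 2 + edge,
                                   spec$width_mm - d_trans[k] / 2 - edge)
                py <- stats::runif(1, d_long[k] / 2 + edge,
                                   spec$height_mm - d_long[k] / 2 - edge)
                ok <- TRUE
                if (placed > 0L) {
                    dd <- sqrt((cx[seq_len(placed)] - px)^2 +
                               (cy[seq_len(placed)] - py)^2)
                    lim <- (d_trans[seq_len(placed)] + d_trans[k]) / 2 +
                        spec$min_gap_mm
                    ok <- all(dd >= lim)
                }
                if (ok) {
                    cx[k] <- px; cy[k] <- py
                    placed <- k
                }
            }
            if (placed < n)
                stop(sprintf(
                    "could not place %d SPAS within %d rejection attempts; reduce n_spas or min_gap_mm",
                    n, budget), call. = FALSE)
            data.frame(id = seq_len(n), cx_mm = cx, cy_mm = cy,
                       d_long_mm = d_long, d_trans_mm = d_trans,
                       area_mm2 = pi / 4 * d_long * d_trans,
                       closed = FALSE)
        }
    })
    spec_out <- spec
    if (is.null(spec_out$matrix_hu)) {
        phi <- sum(spas$area_mm2) / (spec$width_mm * spec$height_mm)
        spec_out$matrix_hu <- (spec$target_mean_hu - phi * spec$air_hu) / (1 - phi)
    }
    structure(list(spas = spas,
                   section_length_mm = spec$height_mm,
                   width_mm = spec$width_mm,
                   uncompressed_length_mm = spec$height_mm,
                   compression_pct = 0,
                   spec = spec_out),
              class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
    cat(sprintf(
        "phantom_truth: %.1f x %.1f mm, %d SPAS (%d open), compression %.1f%%\n",
        x$width_mm, x$section_length_mm, nrow(x$spas), sum(!x$spas$closed),
        x$compression_pct))
    invisible(x)
}

#' Apply uniaxial compression to a phantom truth
#'
#' The section length and every longitudinal centre coordinate scale by
#' `1 - compression_pct/100`; each SPAS's longitudinal diameter scales by
#' `1 - kappa * compression_pct/100` with `kappa >= 1`, so air spaces close
#' faster than the bulk.  Transverse diameters are unchanged.  SPAS whose
#' longitudinal diameter falls below `closure_mm` are flagged closed; they
#' stay in the truth table but are excluded from rendering.
#'
#' @param truth an uncompressed [generate_phantom()] result.
#' @param compression_pct requested compression in percent (0-45).
#' @param kappa air-space compression amplification (>= 1).
#' @param closure_mm longitudinal diameter below which a SPAS is closed.
#' @return a new `phantom_truth` at the requested compression.
#' @export
compress_phantom <- function(truth, compression_pct, kappa = 1.5,
                             closure_mm = 0.3) {
    stopifnot(inherits(truth, "phantom_truth"))
    if (!is.numeric(compression_pct) || length(compression_pct) != 1L ||
        compression_pct < 0 || compression_pct > 45)
        stop("`compression_pct` must lie in [0, 45]", call. = FALSE)
    if (truth$compression_pct != 0)
        stop("compression is applied to the uncompressed truth", call. = FALSE)
    if (kappa < 1) stop("`kappa` must be >= 1", call. = FALSE)
    f_bulk <- 1 - compression_pct / 100
    f_air <- max(0, 1 - kappa * compression_pct / 100)
    out <- truth
    out$section_length_mm <- truth$uncompressed_length_mm * f_bulk
    out$compression_pct <- compression_pct
    s <- truth$spas
    if (nrow(s)) {
        s$cy_mm <- s$cy_mm * f_bulk
        s$d_long_mm <- s$d_long_mm * f_air
        s$area_mm2 <- pi / 4 * s$d_long_mm * s$d_trans_mm
        s$closed <- s$d_long_mm < closure_mm
    }
    out$spas <- s
    out
}

#' Generate a compression phase series with rendered images
#'
#' One shared geometry (from `spec$seed`) is compressed to each requested
#' phase and rendered through every imaging mode.  Noise seeds are derived
#' deterministically per (phase, mode).
#'
#' @param spec a [phantom_spec()].
#' @param phases compression percentages; must start at 0, strictly
#'   increasing, maximum 45.  Default `c(0, 12, 24, 35)` emulates peak
#'   inspiration through late expiration.
#' @param modes list of [imaging_mode()] objects.
#' @param kappa,closure_mm passed to [compress_phantom()].
#' @return list with `truths` (one per phase) and `images` (one
#'   [render_image()] result per phase x mode, phase-major order).
#' @export
make_phase_series <- function(spec, phases = c(0, 12, 24, 35),
                              modes = list(imaging_mode("UHR"),
                                           imaging_mode("NR"),
                                           imaging_mode("REFERENCE")),
                              kappa = 1.5, closure_mm = 0.3) {
    stopifnot(inherits(spec, "phantom_spec"))
    if (phases[1] != 0 || any(diff(phases) <= 0) || max(phases) > 45)
        stop("`phases` must start at 0, be strictly increasing, and not exceed 45",
             call. = FALSE)
    truth0 <- generate_phantom(spec)
    truths <- lapply(phases, function(p)
        compress_phantom(truth0, p, kappa = kappa, closure_mm = closure_mm))
    images <- list()
    for (i in seq_along(phases)) {
        for (j in seq_along(modes)) {
            img <- render_image(truths[[i]], modes[[j]],
                                seed = derive_seed(spec$seed, i, j))
            images[[length(images) + 1L]] <- img
        }
    }
    list(truths = truths, images = images, phases = phases)
}

#' Flatten a list of phase truths to a long data frame
#'
#' @param truths list of `phantom_truth` objects (one per phase).
#' @return data frame with one row per SPAS per phase.
#' @export
truths_to_df <- function(truths) {
    do.call(rbind, lapply(seq_along(truths), function(i) {
        t <- truths[[i]]
        if (!nrow(t$spas)) return(NULL)
        cbind(data.frame(phase = i, compression_pct = t$compression_pct),
              t$spas)
    }))
}
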