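#' Extract an intensity profile through a point
#'
#' Samples the image by bilinear interpolation along the longitudinal
#' (compression, first array axis) or transverse direction, centred on
#' `center`, with an odd sample count and the central sample exactly at
#' the centre.
#'
#' @param img a [ct_image()].
#' @param center length-2 physical coordinates `c(y_mm, x_mm)` =
#'   (longitudinal, transverse).
#' @param direction `"longitudinal"` or `"transverse"`.
#' @param half_length_mm extent of the line on each side of the centre.
#' @param sampling_mm sample spacing; default a quarter pixel.
#' @return an object of class `profile_line` with `offsets_mm` and
#'   `values`.
#' @export
extract_profile <- function(img, center,
                            direction = c("longitudinal", "transverse"),
                            half_length_mm, sampling_mm = NULL) {
    stopifnot(inherits(img, "ct_image"), length(center) == 2L)
    direction <- match.arg(direction)
    if (is.null(sampling_mm)) sampling_mm <- img$pixel_mm / 4
    if (sampling_mm > img$pixel_mm / 2)
        stop("`sampling_mm` must be at most half the pixel spacing", call. = FALSE)
    stop_if_not_scalar_pos(half_length_mm, "half_length_mm")
    nh <- ceiling(half_length_mm / sampling_mm)
    offs <- seq(-nh, nh) * sampling_mm
    if (direction == "longitudinal") {
        ys <- center[1] + offs; xs <- rep(center[2], length(offs))
    } else {
        ys <- rep(center[1], length(offs)); xs <- center[2] + offs
    }
    ext_y <- nrow(img$pixels) * img$pixel_mm
    ext_x <- ncol(img$pixels) * img$pixel_mm
    if (any(ys < 0 | ys > ext_y | xs < 0 | xs > ext_x))
        stop("profile line leaves the image", call. = FALSE)
    vals <- bilinear_sample(img$pixels, img$pixel_mm, ys, xs)
    structure(list(center = center, direction = direction,
                   half_length_mm = half_length_mm,
                   sampling_mm = sampling_mm,
                   offsets_mm = offs, values = vals),
              class = "profile_line")
}

# bilinear interpolation at physical coordinates; pixel i is centred at
# (i - 0.5) * pixel_mm, edges are clamped
bilinear_sample <- function(px, pixel_mm, y_mm, x_mm) {
    nr <- nrow(px); nc <- ncol(px)
    fy <- y_mm / pixel_mm + 0.5
    fx <- x_mm / pixel_mm + 0.5
    i0 <- pmin(pmax(floor(fy), 1), nr)
    j0 <- pmin(pmax(floor(fx), 1), nc)
    i1 <- pmin(i0 + 1, nr)
    j1 <- pmin(j0 + 1, nc)
    wy <- pmin(pmax(fy - i0, 0), 1)
    wx <- pmin(pmax(fx - j0, 0), 1)
    v00 <- px[cbind(i0, j0)]; v10 <- px[cbind(i1, j0)]
    v01 <- px[cbind(i0, j1)]; v11 <- px[cbind(i1, j1)]
    (1 - wy) * (1 - wx) * v00 + wy * (1 - wx) * v10 +
        (1 - wy) * wx * v01 + wy * wx * v11
}

#' Full width at half maximum of an intensity trough
#'
#' The air space appears as a trough.  The baseline is the mean of the
#' medians of the outer 25% of samples on each side; the depth is
#' baseline minus the profile minimum.  Walking outward from the
#' minimum, the first crossings of `baseline - depth/2` on each side are
#' located by linear interpolation and their distance is the width.
#' Returns `NA` (not measurable) when the depth is below
#' `contrast_floor` or a crossing is missing - mirroring air spaces that
#' cannot be measured on low-resolution images.
#'
#' The minimum is sought within the central part of the line (fraction
#' `center_window` of the half-length on each side of the centre), so a
#' neighbouring air space crossed by a long profile cannot capture the
#' trough that belongs to the measured one; the line is always drawn
#' through the centre of the target.
#'
#' @param profile a [extract_profile()] result.
#' @param contrast_floor minimum trough depth (same units as the profile;
#'   50 HU by default).
#' @param center_window fraction of the half-length, centred on the
#'   middle sample, searched for the trough minimum.
#' @return width in mm, or `NA_real_` when not measurable.
#' @export
fwhm_width <- function(profile, contrast_floor = 50, center_window = 0.5) {
    stopifnot(inherits(profile, "profile_line"))
    v <- profile$values
    x <- profile$offsets_mm
    n <- length(v)
    nq <- max(1L, floor(n * 0.25))
    baseline <- (median(v[seq_len(nq)]) + median(v[seq(n - nq + 1L, n)])) / 2
    central <- which(abs(x) <= center_window * profile$half_length_mm + 1e-12)
    imin <- central[which.min(v[central])]
    depth <- baseline - v[imin]
    if (!is.finite(depth) || depth < contrast_floor) return(NA_real_)
    half <- baseline - depth / 2
    cross <- function(side) {
        idx <- if (side < 0) seq(imin, 1L) else seq(imin, n)
        vv <- v[idx]
        up <- which(vv >= half)
        if (!length(up)) return(NA_real_)
        k <- up[1]                      # first sample at/above half level
        if (k == 1L) return(x[idx[1]])  # minimum itself at half level
        a <- idx[k - 1L]; b <- idx[k]   # v[a] < half <= v[b]
        x[a] + (x[b] - x[a]) * (half - v[a]) / (v[b] - v[a])
    }
    xl <- cross(-1L)
    xr <- cross(+1L)
    if (is.na(xl) || is.na(xr)) return(NA_real_)
    xr - xl
}

#' Measure one SPAS on one image
#'
#' Longitudinal and transverse profiles through the (ground-truth)
#' centre, FWHM widths, and the elliptical area
#' `pi/4 * d_long * d_trans`.  A failed width propagates to a
#' non-measurable record with absent area.
#'
#' @param img a [ct_image()].
#' @param center length-2 `c(y_mm, x_mm)` SPAS centre.
#' @param half_long_mm profile half-length for the longitudinal line.
#' @param half_trans_mm profile half-length for the transverse line
#'   (defaults to `half_long_mm`).
#' @param contrast_floor passed to [fwhm_width()].
#' @param spas_id identifier carried into the output.
#' @return one-row data frame: `spas_id`, `mode`, `compression_pct`,
#'   `d_long_mm`, `d_trans_mm`, `area_mm2`, `measurable`.
#' @export
measure_spas <- function(img, center, half_long_mm,
                         half_trans_mm = half_long_mm,
                         contrast_floor = 50, spas_id = NA_integer_) {
    p_long <- extract_profile(img, center, "longitudinal", half_long_mm)
    p_trans <- extract_profile(img, center, "transverse", half_trans_mm)
    d_long <- fwhm_width(p_long, contrast_floor)
    d_trans <- fwhm_width(p_trans, contrast_floor)
    measurable <- !is.na(d_long) && !is.na(d_trans)
    data.frame(spas_id = spas_id, mode = img$mode,
               compression_pct = img$compression_pct,
               d_long_mm = d_long, d_trans_mm = d_trans,
               area_mm2 = if (measurable) pi / 4 * d_long * d_trans else NA_real_,
               measurable = measurable)
}

#' Deviation of CT measurements from the reference rendering
#'
#' Pairs CT and reference measurements by `(spas_id, phase)` and emits
#' one record per dimension (longitudinal, transverse, area) with
#' `deviation = ct - reference`, plus the CT-minus-reference
#' compression-percentage mismatch as a covariate.  Unpaired ids are
#' reported via a message and skipped.
#'
#' @param ct_meas,ref_meas data frames with columns `spas_id`, `phase`,
#'   `compression_pct`, `d_long_mm`, `d_trans_mm`, `area_mm2` (and
#'   `mode`, `cycle` on the CT side if available).
#' @return data frame of deviation records.
#' @export
deviation_table <- function(ct_meas, ref_meas) {
    key <- function(d) paste(d$spas_id, d$phase, sep = "/")
    ct_meas$..k <- key(ct_meas)
    ref_meas$..k <- key(ref_meas)
    unpaired <- setdiff(ct_meas$..k, ref_meas$..k)
    if (length(unpaired))
        message(sprintf("%d CT measurement(s) without a reference pair skipped",
                        length(unpaired)))
    m <- merge(ct_meas, ref_meas, by = "..k",
               suffixes = c("_ct", "_ref"))
    if (!nrow(m)) return(NULL)
    dims <- c(longitudinal = "d_long_mm", transverse = "d_trans_mm",
              area = "area_mm2")
    out <- do.call(rbind, lapply(names(dims), function(dm) {
        col <- dims[[dm]]
        data.frame(spas_id = m$spas_id_ct, phase = m$phase_ct,
                   mode = if ("mode_ct" %in% names(m)) m$mode_ct else NA,
                   cycle = if ("cycle_ct" %in% names(m)) m$cycle_ct else NA,
                   dimension = dm,
                   ct_value = m[[paste0(col, "_ct")]],
                   reference_value = m[[paste0(col, "_ref")]],
                   deviation = m[[paste0(col, "_ct")]] - m[[paste0(col, "_ref")]],
                   compression_pct_deviation =
                       m$compression_pct_ct - m$compression_pct_ref)
    }))
    rownames(out) <- NULL
    out
}

#' Long-format per-SPAS size trajectories
#'
#' Orders measurements of tracked SPAS by compression within each
#' (SPAS, mode) series, truncating a series at the first non-measurable
#' phase (closing air spaces) with a flag.
#'
#' @param meas data frame of [measure_spas()] rows with added `phase`
#'   (and optionally `cycle`, `section`) columns.
#' @return long-format data frame ready for the mixed-model stage, with
#'   a `truncated` flag per row.
#' @export
trajectory_table <- function(meas) {
    stopifnot(all(c("spas_id", "mode", "phase", "compression_pct") %in%
                  names(meas)))
    sk <- interaction(meas$spas_id, meas$mode,
                      if ("cycle" %in% names(meas)) meas$cycle else 0,
                      if ("section" %in% names(meas)) meas$section else 0,
                      drop = TRUE)
    parts <- lapply(split(meas, sk), function(d) {
        d <- d[order(d$phase), , drop = FALSE]
        if (nrow(d) < 2L) return(NULL)
        first_bad <- which(!d$measurable)[1]
        d$truncated <- FALSE
        if (!is.na(first_bad)) {
            if (first_bad == 1L) return(NULL)
            d <- d[seq_len(first_bad - 1L), , drop = FALSE]
            d$truncated <- TRUE
        }
        d
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
}
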