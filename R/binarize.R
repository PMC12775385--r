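#' Gray-level histogram of an 8-bit image
#'
#' @param img8 a [window_to_8bit()] result or an integer matrix in 0..255.
#' @return an object of class `histogram256`: `counts` (length 256, gray
#'   levels 0..255) and `total`.
#' @export
build_histogram <- function(img8) {
    px <- if (inherits(img8, "spas_image8")) img8$pixels else img8
    if (length(px) == 0L) stop("image is empty", call. = FALSE)
    if (any(px < 0 | px > 255)) stop("gray levels must lie in 0..255", call. = FALSE)
    counts <- tabulate(as.integer(px) + 1L, nbins = 256L)
    structure(list(counts = counts, total = sum(counts)),
              class = "histogram256")
}

# third central moment of the two-point distribution matching mean and
# variance of the data when the lower class holds mass q0
two_point_mu3 <- function(q0, cd) {
    q1 <- 1 - q0
    cd^1.5 * (q0 - q1) / sqrt(q0 * q1)
}

#' Moment-preserving (Tsai) threshold
#'
#' Selects the gray level that splits the histogram so that the resulting
#' two-level image preserves the first three statistical moments of the
#' original gray-level distribution.  From the normalized moments
#' `m1, m2, m3` the representative levels `z0 < z1` are the roots of
#' `z^2 + c1 z + c0 = 0` with `c0 = (-m2^2 + m1 m3)/cd`,
#' `c1 = (m1 m2 - m3)/cd`, `cd = m2 - m1^2`, and the target lower-class
#' fraction is `p0 = (z1 - m1)/(z1 - z0)`.  The returned threshold `t`
#' (largest gray level of the lower/dark class, i.e. the split is
#' `g <= t` vs `g > t`) is whichever of the two thresholds bracketing
#' `p0` on the cumulative histogram has the smaller third-moment
#' mismatch, ties going to the smaller level.  Degenerate histograms
#' (zero variance, complex roots, or `p0` outside (0, 1)) fall back to
#' the mean gray level.
#'
#' @param hist a [build_histogram()] result.
#' @return integer threshold in 0..255.
#' @export
moments_threshold <- function(hist) {
    stopifnot(inherits(hist, "histogram256"))
    if (hist$total <= 0) stop("empty histogram", call. = FALSE)
    p <- hist$counts / hist$total
    g <- 0:255
    m1 <- sum(p * g)
    m2 <- sum(p * g^2)
    m3 <- sum(p * g^3)
    cd <- m2 - m1^2
    fallback <- as.integer(round_half_up(m1))
    if (cd < 1e-9) return(fallback)
    c0 <- (-m2^2 + m1 * m3) / cd
    c1 <- (m1 * m2 - m3) / cd
    disc <- c1^2 - 4 * c0
    if (disc <= 0) return(fallback)
    z0 <- (-c1 - sqrt(disc)) / 2
    z1 <- (-c1 + sqrt(disc)) / 2
    p0 <- (z1 - m1) / (z1 - z0)
    if (!is.finite(p0) || p0 <= 0 || p0 >= 1) return(fallback)
    cum <- cumsum(p)
    t_up <- which(cum >= p0 - 1e-12)[1] - 1L
    cand <- unique(c(t_up - 1L, t_up))
    cand <- cand[cand >= 0L & cand <= 255L]
    mu3_target <- m3 - 3 * m1 * cd - m1^3
    best_q <- NA_real_
    best_err <- Inf
    for (t in cand) {
        q0 <- cum[t + 1L]
        if (q0 <= 0 || q0 >= 1) next
        err <- abs(two_point_mu3(q0, cd) - mu3_target)
        if (err < best_err - 1e-12) {
            best_err <- err
            best_q <- q0
        }
    }
    if (is.na(best_q)) return(fallback)
    # smallest gray level inducing the chosen split (ties in a flat run of
    # the cumulative histogram all yield the same two-level image)
    as.integer(which(cum >= best_q - 1e-12)[1] - 1L)
}

#' Binarize an 8-bit image at a threshold
#'
#' Air is dark under the lung window and becomes the white/foreground
#' phase: foreground pixels are those with gray level strictly below `t`.
#'
#' @param img8 a [window_to_8bit()] result or integer matrix in 0..255.
#' @param t threshold in 0..255.
#' @return an object of class `binary_image` (logical `pixels`,
#'   `pixel_mm`, `threshold_used`, fixed air-as-foreground polarity).
#' @export
binarize <- function(img8, t) {
    if (!is.numeric(t) || length(t) != 1L || t < 0 || t > 255)
        stop("`t` must lie in 0..255", call. = FALSE)
    px <- if (inherits(img8, "spas_image8")) img8$pixels else img8
    pixel_mm <- if (inherits(img8, "spas_image8")) img8$pixel_mm else NA_real_
    binary_image(px < t, pixel_mm, threshold_used = as.integer(t))
}

#' @rdname binarize
#' @param pixels logical matrix (TRUE = air/SPAS foreground).
#' @param pixel_mm pixel spacing (mm).
#' @param threshold_used threshold recorded for provenance.
#' @export
binary_image <- function(pixels, pixel_mm, threshold_used = NA_integer_) {
    stopifnot(is.logical(pixels), is.matrix(pixels))
    structure(list(pixels = pixels, pixel_mm = pixel_mm,
                   threshold_used = threshold_used,
                   polarity = "air-as-foreground"),
              class = "binary_image")
}

#' Label connected particles in a binary image
#'
#' Connected components of the foreground (default 8-connectivity,
#' matching common particle-analysis behaviour) with per-particle pixel
#' counts, physical areas, centroids and bounding boxes.  Holes are not
#' filled; the area is the foreground pixel count times `pixel_mm^2`.
#'
#' @param bin a [binary_image()].
#' @param connectivity 4 or 8.
#' @return an object of class `particle_set`: a data frame with one row
#'   per particle (label, pixel_count, area_mm2, centroid_y_mm
#'   longitudinal, centroid_x_mm transverse, rmin/rmax/cmin/cmax bounding
#'   box in pixels) with attributes `pixel_mm`, `source_threshold`,
#'   `connectivity` and `dim`.
#' @export
label_particles <- function(bin, connectivity = 8L) {
    stopifnot(inherits(bin, "binary_image"))
    if (!connectivity %in% c(4L, 8L))
        stop("`connectivity` must be 4 or 8", call. = FALSE)
    lab <- .cc_label_cpp(bin$pixels, as.integer(connectivity))
    n <- attr(lab, "n")
    nr <- nrow(lab)
    pm <- bin$pixel_mm
    if (n == 0L) {
        df <- data.frame(label = integer(), pixel_count = integer(),
                         area_mm2 = numeric(), centroid_y_mm = numeric(),
                         centroid_x_mm = numeric(), rmin = integer(),
                         rmax = integer(), cmin = integer(), cmax = integer())
    } else {
        idx <- which(lab > 0L)
        l <- lab[idx]
        rows <- (idx - 1L) %% nr + 1L
        cols <- (idx - 1L) %/% nr + 1L
        cnt <- tabulate(l, n)
        df <- data.frame(
            label = seq_len(n),
            pixel_count = cnt,
            area_mm2 = cnt * pm^2,
            centroid_y_mm = as.numeric(rowsum(rows - 0.5, l)) / cnt * pm,
            centroid_x_mm = as.numeric(rowsum(cols - 0.5, l)) / cnt * pm,
            rmin = as.integer(tapply(rows, l, min)),
            rmax = as.integer(tapply(rows, l, max)),
            cmin = as.integer(tapply(cols, l, min)),
            cmax = as.integer(tapply(cols, l, max)))
    }
    structure(df, pixel_mm = pm, source_threshold = bin$threshold_used,
              connectivity = as.integer(connectivity), dim_px = dim(lab),
              class = c("particle_set", "data.frame"))
}

#' Size gate for particle counting
#'
#' All bins, including the top one, are half-open `[lo, hi)`: particles
#' smaller than `min_area_mm2` or at least `max_area_mm2` are excluded.
#'
#' @param min_area_mm2 lower area bound (mm^2).
#' @param max_area_mm2 upper area bound (mm^2, excluded).
#' @param bins ordered bin edges; first and last must equal the bounds.
#' @return an object of class `size_gate`.
#' @export
size_gate <- function(min_area_mm2 = 0.5, max_area_mm2 = 7,
                      bins = c(0.5, 1, 2, 4, 7)) {
    if (any(diff(bins) <= 0)) stop("bin edges must be strictly increasing",
                                   call. = FALSE)
    if (bins[1] != min_area_mm2 || bins[length(bins)] != max_area_mm2)
        stop("bin edges must span [min_area_mm2, max_area_mm2]", call. = FALSE)
    structure(list(min_area_mm2 = min_area_mm2, max_area_mm2 = max_area_mm2,
                   bins = as.numeric(bins)),
              class = "size_gate")
}

#' Count gated particles overall and per size bin
#'
#' @param particles a [label_particles()] result.
#' @param gate a [size_gate()].
#' @return list with `total` (count in `[min, max)`) and `bin_counts`
#'   (named per half-open bin).
#' @export
count_spas <- function(particles, gate = size_gate()) {
    stopifnot(inherits(particles, "particle_set"), inherits(gate, "size_gate"))
    a <- particles$area_mm2
    edges <- gate$bins
    nb <- length(edges) - 1L
    bin_counts <- integer(nb)
    idx <- findInterval(a, edges)           # [lo, hi) semantics
    for (b in seq_len(nb)) bin_counts[b] <- sum(idx == b)
    names(bin_counts) <- paste0("[", edges[-length(edges)], ",", edges[-1], ")")
    list(total = sum(a >= gate$min_area_mm2 & a < gate$max_area_mm2),
         bin_counts = bin_counts, gate = gate)
}

#' Full counting pipeline for one CT image
#'
#' Windows the image to 8-bit, finds the moment-preserving threshold,
#' binarizes with air as foreground ([binarize()], `gray < t`), labels
#' particles and applies the size gate.
#'
#' @param img a [ct_image()].
#' @param win a [display_window()].
#' @param gate a [size_gate()].
#' @param connectivity foreground connectivity (default 8).
#' @return list with `threshold`, `total`, `bin_counts`, `particles`.
#' @export
count_spas_image <- function(img, win = display_window(),
                             gate = size_gate(), connectivity = 8L) {
    img8 <- window_to_8bit(img, win)
    t <- moments_threshold(build_histogram(img8))
    bin <- binarize(img8, t)
    parts <- label_particles(bin, connectivity)
    cnt <- count_spas(parts, gate)
    list(threshold = t, total = cnt$total, bin_counts = cnt$bin_counts,
         particles = parts)
}
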