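# fixtures built in code

# a small sparse phantom whose SPAS sit comfortably inside the size gate
sparse_spec <- function(n_spas = 8, seed = 11, area_range = c(1.2, 5),
                        width = 40, height = 30) {
    phantom_spec(width_mm = width, height_mm = height, n_spas = n_spas,
                 area_range_mm2 = area_range, aspect_range = c(1, 2),
                 min_gap_mm = 2, seed = seed)
}

# K well-separated dark disks on a bright background (8-bit)
disk_image8 <- function(k = 5, gray_bg = 200L, gray_disk = 30L,
                        radius_px = 4L, spacing_px = 14L) {
    side <- spacing_px * ceiling(sqrt(k)) + spacing_px
    img <- matrix(gray_bg, side, side)
    ctr <- expand.grid(
        i = seq(spacing_px, side - spacing_px, by = spacing_px),
        j = seq(spacing_px, side - spacing_px, by = spacing_px))[seq_len(k), ]
    for (r in seq_len(k)) {
        ii <- pmax(1, ctr$i[r] - radius_px):pmin(side, ctr$i[r] + radius_px)
        jj <- pmax(1, ctr$j[r] - radius_px):pmin(side, ctr$j[r] + radius_px)
        d2 <- outer((ii - ctr$i[r])^2, (jj - ctr$j[r])^2, `+`)
        img[ii, jj][d2 <= radius_px^2] <- gray_disk
    }
    img
}

as_image8 <- function(px, pixel_mm = 0.25) {
    structure(list(pixels = matrix(as.integer(px), nrow(px), ncol(px)),
                   pixel_mm = pixel_mm, mode = "TEST",
                   compression_pct = 0, window = display_window()),
              class = "spas_image8")
}

# synthetic profile line (for closed-form FWHM checks)
make_profile <- function(values, sampling_mm = 0.05) {
    n <- length(values)
    stopifnot(n %% 2 == 1)
    half <- (n - 1) / 2 * sampling_mm
    structure(list(center = c(0, 0), direction = "longitudinal",
                   half_length_mm = half, sampling_mm = sampling_mm,
                   offsets_mm = seq(-half, half, by = sampling_mm),
                   values = values),
              class = "profile_line")
}

# clustered two-mode design echoing the study scale: G sections, two CT
# modes x two cycles x four compression phases per section
make_lmm_data <- function(G = 14, beta = c(intercept = 30, mode = 10,
                                           comp = -2, interaction = -2.1),
                          sigma_b = 3, sigma_e = 2, seed = 1,
                          heteroscedastic = FALSE) {
    set.seed(seed)
    cells <- expand.grid(mode = c("NR", "UHR"), cycle = c(4, 5),
                         compression_pct = c(0, 12, 24, 35),
                         stringsAsFactors = FALSE)
    d <- do.call(rbind, lapply(seq_len(G), function(g) {
        x <- cells
        x$section <- g
        x
    }))
    u <- stats::rnorm(G, 0, sigma_b)
    sde <- if (heteroscedastic)
        sigma_e * (0.5 + (d$section %% 3)) else sigma_e
    is_uhr <- as.numeric(d$mode == "UHR")
    d$y <- beta[1] + beta[2] * is_uhr + beta[3] * d$compression_pct +
        beta[4] * is_uhr * d$compression_pct + u[d$section] +
        stats::rnorm(nrow(d), 0, sde)
    d$mode <- factor(d$mode, levels = c("NR", "UHR"))
    d
}

# single-SPAS truth at an arbitrary position
single_spas_truth <- function(d_long, d_trans, width = 24, height = 24,
                              matrix_hu = -756, air_hu = -1000) {
    spec <- phantom_spec(width_mm = width, height_mm = height, n_spas = 0,
                         matrix_hu = matrix_hu, air_hu = air_hu, seed = 1)
    truth <- generate_phantom(spec)
    truth$spas <- data.frame(id = 1L, cx_mm = width / 2, cy_mm = height / 2,
                             d_long_mm = d_long, d_trans_mm = d_trans,
                             area_mm2 = pi / 4 * d_long * d_trans,
                             closed = FALSE)
    truth
}
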