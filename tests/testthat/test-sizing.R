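test_that("profiles interpolate bilinearly with the centre sample on centre", {
    truth <- single_spas_truth(2, 2)
    img <- suppressMessages(render_image(truth, imaging_mode("REFERENCE")))
    p <- extract_profile(img, c(12, 12), "longitudinal", 3)
    expect_true(length(p$values) %% 2 == 1)
    expect_equal(p$offsets_mm[(length(p$offsets_mm) + 1) / 2], 0)
    # constant image -> constant profile
    flat <- ct_image(matrix(-500, 32, 32), 0.5)
    pf <- extract_profile(flat, c(8, 8), "transverse", 5)
    expect_true(all(pf$values == -500))
    # step edge: bilinear midpoint halfway between the two levels
    step <- ct_image(cbind(matrix(0, 32, 16), matrix(100, 32, 16)), 0.5)
    ps <- extract_profile(step, c(8, 8), "transverse", 4, sampling_mm = 0.25)
    expect_equal(ps$values[ps$offsets_mm == 0], 50)
    expect_error(extract_profile(flat, c(1, 8), "longitudinal", 5),
                 "leaves the image")
})

test_that("FWHM matches closed forms for rectangular and Gaussian troughs", {
    x <- seq(-5, 5, by = 0.05)
    rect <- ifelse(abs(x) <= 1.5, -1000, -750)     # width 3 mm
    expect_lt(abs(fwhm_width(make_profile(rect)) - 3), 0.05 + 1e-9)
    sigma <- 0.8
    gauss <- -750 - 250 * exp(-x^2 / (2 * sigma^2))
    expect_lt(abs(fwhm_width(make_profile(gauss)) -
                  2 * sqrt(2 * log(2)) * sigma) /
              (2 * sqrt(2 * log(2)) * sigma), 0.02)
})

test_that("FWHM is invariant to affine intensity rescaling", {
    x <- seq(-5, 5, by = 0.05)
    v <- -750 - 250 * exp(-x^2 / 1.3)
    w1 <- fwhm_width(make_profile(v))
    w2 <- fwhm_width(make_profile(0.37 * v + 120), contrast_floor = 10)
    expect_equal(w1, w2, tolerance = 1e-9)
})

test_that("shallow troughs are flagged not measurable", {
    x <- seq(-5, 5, by = 0.05)
    shallow <- -750 - 30 * exp(-x^2)                # depth 30 HU < 50
    expect_true(is.na(fwhm_width(make_profile(shallow))))
    expect_true(is.na(fwhm_width(make_profile(rep(-750, 201)))))
})

test_that("halving the sampling step changes the FWHM by less than one step", {
    truth <- single_spas_truth(2, 2.5)
    img <- suppressMessages(render_image(truth, imaging_mode("REFERENCE")))
    coarse <- fwhm_width(extract_profile(img, c(12, 12), "transverse", 5,
                                         sampling_mm = 0.025))
    fine <- fwhm_width(extract_profile(img, c(12, 12), "transverse", 5,
                                       sampling_mm = 0.0125))
    expect_lt(abs(coarse - fine), 0.025)
})

test_that("reference measurements agree with truth within 5% above 1 mm", {
    truth <- generate_phantom(sparse_spec(n_spas = 6, seed = 41))
    img <- suppressMessages(render_image(truth, imaging_mode("REFERENCE")))
    for (k in seq_len(nrow(truth$spas))) {
        s <- truth$spas[k, ]
        if (s$d_long_mm < 1) next
        hl <- min(6, 2 * s$d_long_mm, s$cy_mm - 0.1,
                  truth$section_length_mm - s$cy_mm - 0.1)
        ht <- min(6, 2 * s$d_trans_mm, s$cx_mm - 0.1,
                  truth$width_mm - s$cx_mm - 0.1)
        if (hl < s$d_long_mm || ht < s$d_trans_mm) next
        m <- measure_spas(img, c(s$cy_mm, s$cx_mm), hl, ht, spas_id = s$id)
        expect_true(m$measurable)
        expect_lt(abs(m$d_long_mm - s$d_long_mm) / s$d_long_mm, 0.05)
        expect_lt(abs(m$d_trans_mm - s$d_trans_mm) / s$d_trans_mm, 0.05)
        expect_equal(m$area_mm2, pi / 4 * m$d_long_mm * m$d_trans_mm,
                     tolerance = 1e-12)
    }
})

test_that("an ellipse measures close to its analytic elliptical area", {
    truth <- single_spas_truth(1.5, 3.0)
    img <- suppressMessages(render_image(truth, imaging_mode("REFERENCE")))
    m <- measure_spas(img, c(12, 12), min(6, 2 * 1.5), min(6, 2 * 3))
    expect_lt(abs(m$area_mm2 - pi / 4 * 1.5 * 3.0) / (pi / 4 * 1.5 * 3.0),
              0.07)
})

test_that("deviation records subtract reference from CT and skip unpaired ids", {
    ct <- data.frame(spas_id = c(1, 2), phase = 1, mode = "NR",
                     compression_pct = c(10, 10),
                     d_long_mm = c(1.8, 2.0), d_trans_mm = c(3, 3),
                     area_mm2 = c(4.2, 4.7), measurable = TRUE)
    ref <- data.frame(spas_id = 1, phase = 1, mode = "REFERENCE",
                      compression_pct = 8,
                      d_long_mm = 1.3, d_trans_mm = 3, area_mm2 = 3.1,
                      measurable = TRUE)
    expect_message(d <- deviation_table(ct, ref), "skipped")
    expect_equal(nrow(d), 3)    # one paired SPAS x three dimensions
    long <- d[d$dimension == "longitudinal", ]
    expect_equal(long$deviation, 0.5)
    expect_equal(long$compression_pct_deviation, 2)
    same <- suppressMessages(deviation_table(ct, transform(ct, phase = 1)))
    expect_true(all(same$deviation == 0))
})

test_that("trajectories keep ordered phases and truncate at closure", {
    m <- data.frame(spas_id = 1, mode = "UHR", phase = c(1, 2, 3, 4),
                    compression_pct = c(0, 12, 24, 35),
                    d_long_mm = c(2, 1.8, NA, NA),
                    d_trans_mm = 3, area_mm2 = 5,
                    measurable = c(TRUE, TRUE, FALSE, FALSE))
    tr <- trajectory_table(m)
    expect_equal(nrow(tr), 2)
    expect_true(all(tr$truncated))
    m2 <- data.frame(spas_id = 2, mode = "UHR", phase = 1:4,
                     compression_pct = c(0, 12, 24, 35),
                     d_long_mm = 2, d_trans_mm = 3, area_mm2 = 5,
                     measurable = TRUE)
    expect_equal(nrow(trajectory_table(m2)), 4)
})

test_that("reference-measured longitudinal diameters shrink under compression", {
    truth <- generate_phantom(sparse_spec(n_spas = 5, seed = 51))
    d_by_phase <- vapply(c(0, 20, 35), function(p) {
        t <- compress_phantom(truth, p)
        img <- suppressMessages(render_image(t, imaging_mode("REFERENCE")))
        s <- t$spas[1, ]
        measure_spas(img, c(s$cy_mm, s$cx_mm), min(6, 2 * s$d_long_mm),
                     min(6, 2 * s$d_trans_mm))$d_long_mm
    }, numeric(1))
    expect_true(all(diff(d_by_phase) < 0))
})
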