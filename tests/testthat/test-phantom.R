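test_that("empty phantom renders as pure matrix at the calibration target", {
    spec <- phantom_spec(n_spas = 0, seed = 3)
    truth <- generate_phantom(spec)
    expect_equal(nrow(truth$spas), 0)
    expect_equal(truth$spec$matrix_hu, spec$target_mean_hu)
    img <- suppressMessages(render_image(truth, imaging_mode("REFERENCE")))
    expect_true(all(img$pixels == truth$spec$matrix_hu))
})

test_that("calibrated whole-section mean HU lands in the reported sponge range", {
    for (seed in c(1, 2, 9)) {
        truth <- generate_phantom(phantom_spec(seed = seed))
        img <- suppressMessages(render_image(truth, imaging_mode("REFERENCE")))
        m <- mean(img$pixels)
        expect_gt(m, -816.5)
        expect_lt(m, -729.9)
        expect_lt(abs(m - truth$spec$target_mean_hu), 10)
    }
})

test_that("area, aspect and gap invariants hold (dense boundary-point oracle)", {
    truth <- generate_phantom(phantom_spec(n_spas = 50, seed = 21))
    s <- truth$spas
    expect_equal(s$area_mm2, pi / 4 * s$d_long_mm * s$d_trans_mm,
                 tolerance = 1e-12)
    expect_true(all(s$d_trans_mm >= s$d_long_mm))        # long axis transverse
    # inside section bounds
    expect_true(all(s$cx_mm - s$d_trans_mm / 2 >= 0 &
                    s$cx_mm + s$d_trans_mm / 2 <= truth$width_mm))
    expect_true(all(s$cy_mm - s$d_long_mm / 2 >= 0 &
                    s$cy_mm + s$d_long_mm / 2 <= truth$section_length_mm))
    # brute-force wall thickness between sampled ellipse boundaries
    th <- seq(0, 2 * pi, length.out = 72)
    bnd <- lapply(seq_len(nrow(s)), function(k)
        cbind(s$cx_mm[k] + s$d_trans_mm[k] / 2 * cos(th),
              s$cy_mm[k] + s$d_long_mm[k] / 2 * sin(th)))
    min_gap <- Inf
    for (a in seq_len(nrow(s) - 1)) for (b in seq((a + 1), nrow(s))) {
        dx <- outer(bnd[[a]][, 1], bnd[[b]][, 1], `-`)
        dy <- outer(bnd[[a]][, 2], bnd[[b]][, 2], `-`)
        min_gap <- min(min_gap, sqrt(min(dx^2 + dy^2)))
    }
    expect_gte(min_gap, truth$spec$min_gap_mm)
})

test_that("generation is deterministic and rejects impossible packings", {
    a <- generate_phantom(phantom_spec(seed = 5))
    b <- generate_phantom(phantom_spec(seed = 5))
    expect_identical(a, b)
    expect_error(generate_phantom(
        phantom_spec(width_mm = 10, height_mm = 10, n_spas = 200, seed = 1)),
        "rejection attempts")
})

test_that("compression scales lengths exactly and conserves SPAS identity", {
    truth <- generate_phantom(phantom_spec(seed = 7))
    expect_identical(compress_phantom(truth, 0)$spas, truth$spas)
    t20 <- compress_phantom(truth, 20, kappa = 1.5)
    expect_equal(t20$spas$d_long_mm / truth$spas$d_long_mm,
                 rep(0.70, nrow(truth$spas)), tolerance = 1e-12)
    expect_equal(t20$spas$d_trans_mm, truth$spas$d_trans_mm)
    expect_equal(t20$section_length_mm, truth$section_length_mm * 0.8)
    expect_identical(t20$spas$id, truth$spas$id)     # open + closed conserved
    expect_equal(compression_percentage(t20$section_length_mm,
                                        truth$uncompressed_length_mm), 20,
                 tolerance = 1e-9)
    expect_error(compress_phantom(truth, 50), "0, 45")
    expect_error(compress_phantom(t20, 10), "uncompressed")
})

test_that("ground-truth in-gate count does not increase at 35% compression", {
    truth <- generate_phantom(phantom_spec(seed = 1))
    ingate <- function(t) {
        s <- t$spas
        sum(!s$closed & s$area_mm2 >= 0.5 & s$area_mm2 < 7)
    }
    expect_lte(ingate(compress_phantom(truth, 35)), ingate(truth))
})

test_that("phase series has one truth per phase and one image per phase-mode", {
    spec <- sparse_spec()
    ser <- suppressMessages(make_phase_series(
        spec, phases = c(0, 12, 24, 35),
        modes = list(imaging_mode("UHR"), imaging_mode("NR"),
                     imaging_mode("REFERENCE"))))
    expect_length(ser$truths, 4)
    expect_length(ser$images, 12)
    single <- suppressMessages(make_phase_series(
        spec, phases = 0, modes = list(imaging_mode("REFERENCE"))))
    expect_length(single$images, 1)
    expect_equal(single$truths[[1]]$compression_pct, 0)
    expect_error(make_phase_series(spec, phases = c(5, 10)), "start at 0")
})
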