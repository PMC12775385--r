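test_that("histogram counts gray levels and conserves totals", {
    img <- matrix(c(0L, 0L, 255L, 255L), 2, 2)
    h <- build_histogram(img)
    expect_equal(h$counts[1], 2)
    expect_equal(h$counts[256], 2)
    expect_equal(sum(h$counts), 4)
    hc <- build_histogram(matrix(7L, 5, 5))
    expect_equal(sum(hc$counts > 0), 1)
    set.seed(4)
    rnd <- matrix(sample(0:255, 900, TRUE), 30, 30)
    expect_equal(build_histogram(rnd)$total, 900)
})

test_that("moments threshold separates a two-delta histogram and preserves moments", {
    img <- matrix(rep(c(50L, 200L), each = 128), 16, 16)
    h <- build_histogram(img)
    t <- moments_threshold(h)
    expect_gte(t, 50)
    expect_lt(t, 200)
    # the induced two-level image (dark class g <= t at level z0, rest at
    # z1, masses matching the split) preserves the first three moments
    p <- h$counts / h$total
    g <- 0:255
    m <- vapply(1:3, function(r) sum(p * g^r), numeric(1))
    q0 <- sum(p[seq_len(t + 1)])
    cd <- m[2] - m[1]^2
    z0 <- m[1] - sqrt(cd * (1 - q0) / q0)
    z1 <- m[1] + sqrt(cd * q0 / (1 - q0))
    for (r in 1:3)
        expect_equal(q0 * z0^r + (1 - q0) * z1^r, m[r], tolerance = 1e-9)
})

test_that("degenerate histograms fall back to the mean gray level", {
    expect_equal(moments_threshold(build_histogram(matrix(93L, 8, 8))), 93)
})

test_that("moments threshold equals the brute-force moment-mismatch minimizer", {
    set.seed(2026)
    for (r in 1:300) {
        h <- random_histogram()
        expect_identical(as.integer(moments_threshold(h)),
                         as.integer(oracle_moments_brute(h$counts)))
    }
})

test_that("binarize uses strict air-as-foreground polarity", {
    img <- as_image8(matrix(c(10L, 100L, 254L, 255L), 16, 16))
    expect_true(!any(binarize(img, 0)$pixels))
    b255 <- binarize(img, 255)
    expect_identical(b255$pixels, img$pixels < 255)
    expect_error(binarize(img, 256))
})

test_that("moments binarization recovers a single SPAS with Dice >= 0.8", {
    truth <- single_spas_truth(2, 3)
    img <- render_image(truth, imaging_mode("UHR", noise_sd_hu = 0))
    img8 <- window_to_8bit(img)
    t <- moments_threshold(build_histogram(img8))
    mask <- binarize(img8, t)$pixels
    pm <- img$pixel_mm
    yc <- (seq_len(nrow(mask)) - 0.5) * pm
    xc <- (seq_len(ncol(mask)) - 0.5) * pm
    s <- truth$spas
    truemask <- outer(((yc - s$cy_mm) / (s$d_long_mm / 2))^2,
                      ((xc - s$cx_mm) / (s$d_trans_mm / 2))^2, `+`) <= 1
    dice <- 2 * sum(mask & truemask) / (sum(mask) + sum(truemask))
    expect_gte(dice, 0.8)
})

test_that("particle labeling matches definitions and the flood-fill oracle", {
    px <- matrix(FALSE, 10, 10)
    px[4:6, 4:6] <- TRUE
    ps <- label_particles(binary_image(px, 0.5))
    expect_equal(nrow(ps), 1)
    expect_equal(ps$pixel_count, 9)
    expect_equal(ps$area_mm2, 9 * 0.25)
    diagpx <- matrix(FALSE, 8, 8)
    diagpx[3, 3] <- TRUE; diagpx[4, 4] <- TRUE
    expect_equal(nrow(label_particles(binary_image(diagpx, 1), 8L)), 1)
    expect_equal(nrow(label_particles(binary_image(diagpx, 1), 4L)), 2)
    set.seed(8)
    for (r in 1:20) {
        m <- matrix(stats::runif(32 * 32) < 0.4, 32, 32)
        for (conn in c(4L, 8L)) {
            expect_equal(nrow(label_particles(binary_image(m, 1), conn)),
                         oracle_flood_label(m, conn)$n)
        }
    }
})

test_that("size gating uses half-open bins including the top one", {
    areas <- c(0.4, 0.5, 6.99, 7.0)
    ps <- structure(data.frame(label = 1:4, pixel_count = 1L,
                               area_mm2 = areas),
                    pixel_mm = 1, class = c("particle_set", "data.frame"))
    cnt <- count_spas(ps)
    expect_equal(cnt$total, 2)
    ps2 <- structure(data.frame(label = 1:4, pixel_count = 1L,
                                area_mm2 = c(0.7, 1.5, 3.0, 5.0)),
                     pixel_mm = 1, class = c("particle_set", "data.frame"))
    cnt2 <- count_spas(ps2)
    expect_equal(unname(cnt2$bin_counts), c(1, 1, 1, 1))
    # widening the gate never decreases the total
    wide <- count_spas(ps, size_gate(0.25, 8, bins = c(0.25, 1, 8)))
    expect_gte(wide$total, cnt$total)
    expect_error(size_gate(1, 7, bins = c(0.5, 7)), "span")
})

test_that("noiseless UHR counting recovers the exact in-gate truth count", {
    truth <- generate_phantom(sparse_spec(n_spas = 8, seed = 31))
    expect_equal(sum(truth$spas$area_mm2 >= 0.5 & truth$spas$area_mm2 < 7), 8)
    img <- render_image(truth, imaging_mode("UHR", noise_sd_hu = 0))
    res <- count_spas_image(img)
    expect_equal(res$total, 8)
})
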