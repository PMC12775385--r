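test_that("the default design enumerates 224 CT images", {
    d <- experiment_design(experiment_config())
    expect_equal(nrow(d), 224)           # 14 x 4 x 2 x 2
    expect_equal(length(unique(d$section)), 14)
    expect_setequal(unique(d$mode), c("UHR", "NR"))
    expect_setequal(unique(d$cycle), c(4, 5))
    expect_equal(sort(unique(d$compression_pct)), c(0, 12, 24, 35))
})

test_that("a small experiment produces coherent, deterministic tables", {
    cfg <- experiment_config(n_sections = 2, phases = c(0, 24), cycles = 4,
                             master_seed = 6, n_spas = 20)
    b1 <- suppressMessages(run_experiment(cfg))
    b2 <- suppressMessages(run_experiment(cfg))
    expect_identical(b1$counts, b2$counts)
    expect_identical(b1$trajectories, b2$trajectories)
    expect_equal(nrow(b1$counts), nrow(b1$design))   # one row per CT image
    expect_equal(nrow(b1$peaks), nrow(b1$design))
    # one truth row per (section, phase, SPAS)
    expect_equal(nrow(b1$truths), 2 * 2 * 20)
    expect_true(all(b1$counts$threshold >= 0 & b1$counts$threshold <= 255))
    expect_true(!is.null(b1$fits$counts))
    expect_s3_class(b1$fits$counts, "lmm_fit")
    expect_true(all(c("NR", "UHR") %in% b1$slopes$counts$group))
})

test_that("a reference-only single-phase run skips the statistical stage", {
    cfg <- experiment_config(n_sections = 1, phases = 0,
                             modes = "REFERENCE", cycles = 4, n_spas = 10,
                             master_seed = 2)
    expect_message(b <- run_experiment(cfg), "skipped")
    expect_equal(nrow(b$design), 0)
    expect_null(b$counts)
    expect_length(b$fits, 0)
    expect_gte(nrow(b$ref_measurements), 1)
})

test_that("experiment outputs are written when an output directory is set", {
    out <- file.path(tempdir(), "spasim-exp-test")
    on.exit(unlink(out, recursive = TRUE))
    cfg <- experiment_config(n_sections = 1, phases = c(0, 35), cycles = 4,
                             master_seed = 4, n_spas = 15, output_dir = out)
    b <- suppressMessages(run_experiment(cfg))
    expect_equal(b$n_images_written, nrow(b$design))
    expect_true(file.exists(file.path(out, "counts.csv")))
    expect_true(file.exists(file.path(out, "truths.csv")))
    expect_true(file.exists(file.path(out, "summary.json")))
    tifs <- list.files(out, pattern = "\\.tif$")
    expect_length(tifs, nrow(b$design))
})

test_that("CT images round-trip through 16-bit TIFF with sidecar metadata", {
    truth <- generate_phantom(sparse_spec())
    img <- render_image(truth, imaging_mode("UHR"), seed = 3)
    img$pixels <- round(img$pixels)
    path <- tempfile(fileext = ".tif")
    on.exit(unlink(c(path, paste0(path, ".json"))))
    write_ct_image(img, path)
    back <- read_ct_image(path)
    expect_identical(back$pixels, img$pixels)
    expect_equal(back$pixel_mm, img$pixel_mm)
    expect_equal(back$mode, img$mode)
    expect_equal(back$compression_pct, img$compression_pct)
    # corrupted sidecar is rejected with the offending field named
    side <- jsonlite::read_json(paste0(path, ".json"))
    side$pixel_mm <- -1
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         null = "null")
    expect_error(read_ct_image(path), "pixel_mm")
    unlink(paste0(path, ".json"))
    expect_error(read_ct_image(path), "sidecar")
})

test_that("windowed 8-bit images round-trip through PNG", {
    truth <- generate_phantom(sparse_spec())
    img8 <- window_to_8bit(render_image(truth, imaging_mode("NR"), seed = 1))
    path <- tempfile(fileext = ".png")
    on.exit(unlink(path))
    write_image8(img8, path)
    expect_identical(read_image8(path), img8$pixels)
})

test_that("YAML configuration files populate the experiment config", {
    path <- tempfile(fileext = ".yaml")
    on.exit(unlink(path))
    writeLines(c("n_sections: 3", "cycles: [4]", "master_seed: 11",
                 "n_spas: 12", "phases: [0, 12, 24]"), path)
    cfg <- read_experiment_config(path)
    expect_equal(cfg$n_sections, 3)
    expect_equal(cfg$cycles, 4)
    expect_equal(cfg$phases, c(0, 12, 24))
    expect_equal(cfg$n_spas, 12)
    expect_equal(cfg$master_seed, 11L)
})

test_that("per-cell seeds are stable and fit in an R integer", {
    s1 <- derive_seed(1, 3, 2, 1, 1)
    expect_identical(s1, derive_seed(1, 3, 2, 1, 1))
    expect_false(s1 == derive_seed(1, 3, 2, 1, 2))
    expect_true(s1 >= 0 && s1 < 2^31)
    expect_type(s1, "integer")
})
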