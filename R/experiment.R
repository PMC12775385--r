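#' Configuration of the full phantom experiment
#'
#' Mirrors the study design: `n_sections` cross-sections, four
#' compression phases, two CT modes and two compression-cycle durations
#' (the cycles differ only through their motion-blur length), plus the
#' reference rendering.  Sections are labelled upper/median/lateral
#' cyclically.
#'
#' @param n_sections number of cross-sections.
#' @param phases compression percentages (start at 0, increasing).
#' @param modes imaging-mode names; `"REFERENCE"` drives the sizing
#'   reference and is not counted as a CT image.
#' @param cycles compression-cycle durations in seconds.
#' @param master_seed integer; all per-cell seeds derive from it.
#' @param window a [display_window()].
#' @param gate a [size_gate()].
#' @param homology_min_area optional component-size floor for peak b0.
#' @param n_spas air spaces per section.
#' @param kappa,closure_mm compression law parameters
#'   ([compress_phantom()]).
#' @param matched_noise if `TRUE` both CT modes use the UHR noise level,
#'   isolating resolution effects in sizing comparisons.
#' @param contrast_floor FWHM trough-depth floor in HU.
#' @param n_tracked maximum tracked SPAS per section entering the sizing
#'   and deviation analysis.
#' @param n_trajectory number of SPAS selected across the whole
#'   experiment for the compression-trajectory analysis (the study
#'   design follows a small fixed panel of air spaces).
#' @param output_dir directory for images/CSV output, or `NULL` to keep
#'   everything in memory.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(n_sections = 14, phases = c(0, 12, 24, 35),
                              modes = c("UHR", "NR", "REFERENCE"),
                              cycles = c(4, 5), master_seed = 1L,
                              window = display_window(),
                              gate = size_gate(),
                              homology_min_area = NULL,
                              n_spas = 60, kappa = 1.5, closure_mm = 0.3,
                              matched_noise = FALSE, contrast_floor = 50,
                              n_tracked = 10, n_trajectory = 10,
                              output_dir = NULL) {
    if (n_sections < 1) stop("`n_sections` must be >= 1", call. = FALSE)
    if (phases[1] != 0 || any(diff(phases) <= 0))
        stop("`phases` must start at 0 and increase", call. = FALSE)
    modes <- match.arg(modes, c("UHR", "NR", "REFERENCE"), several.ok = TRUE)
    structure(list(n_sections = as.integer(n_sections), phases = phases,
                   modes = modes, cycles = cycles,
                   master_seed = as.integer(master_seed), window = window,
                   gate = gate, homology_min_area = homology_min_area,
                   n_spas = n_spas, kappa = kappa, closure_mm = closure_mm,
                   matched_noise = matched_noise,
                   contrast_floor = contrast_floor,
                   n_tracked = n_tracked, n_trajectory = n_trajectory,
                   output_dir = output_dir),
              class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' Scalar fields of [experiment_config()] can be given in a YAML mapping;
#' unspecified fields keep their defaults.
#'
#' @param path YAML file path.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
    cfg <- yaml::read_yaml(path)
    keep <- intersect(names(cfg), names(formals(experiment_config)))
    do.call(experiment_config, cfg[keep])
}

#' Enumerate the CT design cells of an experiment
#'
#' One row per CT image to be acquired: section x phase x CT mode x
#' cycle (the reference rendering is excluded).
#'
#' @param cfg an [experiment_config()].
#' @return data frame with columns `section`, `position`, `phase`,
#'   `compression_pct`, `mode`, `cycle`.
#' @export
experiment_design <- function(cfg) {
    positions <- rep(c("upper", "median", "lateral"),
                     length.out = cfg$n_sections)
    ct_modes <- setdiff(cfg$modes, "REFERENCE")
    d <- expand.grid(cycle = cfg$cycles, mode = ct_modes,
                     phase = seq_along(cfg$phases),
                     section = seq_len(cfg$n_sections),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    d <- d[, c("section", "phase", "mode", "cycle")]
    d$position <- positions[d$section]
    d$compression_pct <- cfg$phases[d$phase]
    d[order(d$section, d$phase, d$mode, d$cycle),
      c("section", "position", "phase", "compression_pct", "mode", "cycle")]
}

# tracked SPAS: open at all phases, in the size gate at phase 0, up to
# n_tracked ids spread evenly across the in-gate size range
select_tracked <- function(truths, gate, n_tracked) {
    first <- truths[[1]]$spas
    last <- truths[[length(truths)]]$spas
    ok <- !last$closed &
        first$area_mm2 >= gate$min_area_mm2 &
        first$area_mm2 < gate$max_area_mm2
    ids <- first$id[ok]
    if (!length(ids)) return(integer())
    ids <- ids[order(first$area_mm2[match(ids, first$id)])]
    take <- unique(round(seq(1, length(ids),
                             length.out = min(n_tracked, length(ids)))))
    ids[take]
}

measure_tracked_one <- function(img, trow, contrast_floor) {
    ext_y <- nrow(img$pixels) * img$pixel_mm
    ext_x <- ncol(img$pixels) * img$pixel_mm
    hl_long <- min(6, 2 * trow$d_long_mm,
                   trow$cy_mm - img$pixel_mm, ext_y - trow$cy_mm - img$pixel_mm)
    hl_trans <- min(6, 2 * trow$d_trans_mm,
                    trow$cx_mm - img$pixel_mm, ext_x - trow$cx_mm - img$pixel_mm)
    if (hl_long < trow$d_long_mm * 0.75 || hl_trans < trow$d_trans_mm * 0.75 ||
        hl_long <= 0 || hl_trans <= 0)
        return(data.frame(spas_id = trow$id, mode = img$mode,
                          compression_pct = img$compression_pct,
                          d_long_mm = NA_real_, d_trans_mm = NA_real_,
                          area_mm2 = NA_real_, measurable = FALSE))
    measure_spas(img, c(trow$cy_mm, trow$cx_mm), hl_long, hl_trans,
                 contrast_floor = contrast_floor, spas_id = trow$id)
}

#' Run the end-to-end phantom experiment
#'
#' For every design cell: generate the section geometry, compress it to
#' each phase, render the CT modes (with per-cycle motion blur from
#' [motion_blur_ct()]) and the reference, then count gated particles
#' (moment-preserving threshold), compute the peak-b0 homology summary,
#' measure tracked SPAS by FWHM on CT and reference, and finally fit the
#' mixed models and descriptive regression lines.  Any stage failure is
#' reported with its design-cell coordinates and the run continues.
#' Fully deterministic given `cfg$master_seed`.
#'
#' @param cfg an [experiment_config()].
#' @return an object of class `spasim_experiment`: list with `design`,
#'   `truths` (data frame), `counts`, `peaks`, `measurements`,
#'   `ref_measurements`, `deviations`, `trajectories`, `fits`, `slopes`,
#'   `config`, `n_images_written`.
#' @export
run_experiment <- function(cfg) {
    stopifnot(inherits(cfg, "experiment_config"))
    design <- experiment_design(cfg)
    ct_modes <- setdiff(cfg$modes, "REFERENCE")
    has_ref <- "REFERENCE" %in% cfg$modes
    params <- physics_params()
    blur <- setNames(vapply(cfg$cycles, function(cy)
        motion_blur_ct(params, cy), numeric(1)), as.character(cfg$cycles))
    out_dir <- cfg$output_dir
    if (!is.null(out_dir) && !dir.exists(out_dir))
        dir.create(out_dir, recursive = TRUE)
    n_written <- 0L

    counts <- list(); peaks <- list(); meas <- list(); ref_meas <- list()
    truth_rows <- list(); tracked_pool <- list()
    positions <- rep(c("upper", "median", "lateral"),
                     length.out = cfg$n_sections)

    for (s in seq_len(cfg$n_sections)) {
        spec_s <- phantom_spec(n_spas = cfg$n_spas,
                               seed = derive_seed(cfg$master_seed, 101L, s))
        truth0 <- generate_phantom(spec_s)
        truths <- lapply(cfg$phases, function(p)
            compress_phantom(truth0, p, kappa = cfg$kappa,
                             closure_mm = cfg$closure_mm))
        tdf <- truths_to_df(truths)
        if (!is.null(tdf)) {
            tdf$section <- s
            truth_rows[[s]] <- tdf
        }
        tracked <- select_tracked(truths, cfg$gate, cfg$n_tracked)
        if (length(tracked))
            tracked_pool[[s]] <- data.frame(
                section = s, id = tracked,
                area0 = truths[[1]]$spas$area_mm2[match(tracked,
                                                        truths[[1]]$spas$id)])

        for (pi in seq_along(cfg$phases)) {
            truth <- truths[[pi]]
            if (has_ref) {
                ref_img <- suppressMessages(
                    render_image(truth, imaging_mode("REFERENCE"),
                                 seed = derive_seed(cfg$master_seed, s, pi, 0L)))
                for (id in tracked) {
                    trow <- truth$spas[truth$spas$id == id, ]
                    r <- tryCatch(
                        measure_tracked_one(ref_img, trow, cfg$contrast_floor),
                        error = function(e) {
                            message(sprintf(
                                "[section %d phase %d REFERENCE] sizing failed: %s",
                                s, pi, conditionMessage(e)))
                            NULL
                        })
                    if (!is.null(r)) {
                        r$phase <- pi; r$section <- s
                        ref_meas[[length(ref_meas) + 1L]] <- r
                    }
                }
            }
            for (mi in seq_along(ct_modes)) {
                for (ci in seq_along(cfg$cycles)) {
                    cy <- cfg$cycles[ci]
                    mode_obj <- imaging_mode(
                        ct_modes[mi], blur_mm = blur[[as.character(cy)]],
                        noise_sd_hu = if (cfg$matched_noise)
                            imaging_mode("UHR")$noise_sd_hu else NULL)
                    img <- render_image(
                        truth, mode_obj,
                        seed = derive_seed(cfg$master_seed, s, pi, mi, ci))
                    cell <- sprintf("[section %d phase %d %s %gs]",
                                    s, pi, ct_modes[mi], cy)
                    res <- tryCatch({
                        cs <- count_spas_image(img, cfg$window, cfg$gate)
                        hc <- homology_curve(window_to_8bit(img, cfg$window),
                                             min_area_mm2 = cfg$homology_min_area)
                        list(cs = cs, hc = hc)
                    }, error = function(e) {
                        message(sprintf("%s quantification failed: %s",
                                        cell, conditionMessage(e)))
                        NULL
                    })
                    if (!is.null(res)) {
                        counts[[length(counts) + 1L]] <- cbind(
                            data.frame(section = s, position = positions[s],
                                       phase = pi,
                                       compression_pct = cfg$phases[pi],
                                       mode = ct_modes[mi], cycle = cy,
                                       threshold = res$cs$threshold,
                                       total = res$cs$total),
                            as.data.frame(as.list(res$cs$bin_counts),
                                          check.names = FALSE))
                        peaks[[length(peaks) + 1L]] <- data.frame(
                            section = s, position = positions[s], phase = pi,
                            compression_pct = cfg$phases[pi],
                            mode = ct_modes[mi], cycle = cy,
                            peak_b0 = res$hc$peak_b0,
                            peak_threshold = res$hc$peak_threshold)
                    }
                    for (id in tracked) {
                        trow <- truth$spas[truth$spas$id == id, ]
                        r <- tryCatch(
                            measure_tracked_one(img, trow, cfg$contrast_floor),
                            error = function(e) {
                                message(sprintf("%s sizing failed: %s",
                                                cell, conditionMessage(e)))
                                NULL
                            })
                        if (!is.null(r)) {
                            r$phase <- pi; r$section <- s; r$cycle <- cy
                            meas[[length(meas) + 1L]] <- r
                        }
                    }
                    if (!is.null(out_dir)) {
                        fn <- file.path(out_dir, sprintf(
                            "sec%02d_ph%d_%s_c%gs.tif", s, pi, ct_modes[mi], cy))
                        write_ct_image(img, fn)
                        n_written <- n_written + 1L
                    }
                }
            }
        }
    }

    counts <- do.call(rbind, counts)
    peaks <- do.call(rbind, peaks)
    meas <- if (length(meas)) do.call(rbind, meas) else NULL
    ref_meas <- if (length(ref_meas)) do.call(rbind, ref_meas) else NULL
    truths_df <- do.call(rbind, truth_rows)

    deviations <- NULL
    if (!is.null(meas) && !is.null(ref_meas)) {
        deviations <- do.call(rbind, lapply(cfg$cycles, function(cy) {
            m <- meas[meas$cycle == cy, , drop = FALSE]
            m$spas_id <- paste(m$section, m$spas_id, sep = ":")
            r <- ref_meas
            r$spas_id <- paste(r$section, r$spas_id, sep = ":")
            d <- deviation_table(m, r)
            if (!is.null(d)) d$cycle <- cy
            d
        }))
    }
    # the trajectory analysis follows a small fixed panel of SPAS,
    # recognizable at the uncompressed phase on every modality (as the
    # study's readers required), spread evenly across the size range
    trajectories <- NULL
    if (!is.null(meas) && length(tracked_pool)) {
        pool <- do.call(rbind, tracked_pool)
        m0 <- meas[meas$phase == 1L, , drop = FALSE]
        ok_ct <- stats::aggregate(measurable ~ section + spas_id, m0, all)
        keep <- ok_ct[ok_ct$measurable, c("section", "spas_id")]
        if (!is.null(ref_meas)) {
            r0 <- ref_meas[ref_meas$phase == 1L & ref_meas$measurable,
                           c("section", "spas_id")]
            keep <- merge(keep, r0, by = c("section", "spas_id"))
        }
        pool <- pool[paste(pool$section, pool$id) %in%
                     paste(keep$section, keep$spas_id), , drop = FALSE]
        pool <- pool[order(pool$area0), , drop = FALSE]
        if (nrow(pool)) {
            take <- unique(round(seq(1, nrow(pool),
                                     length.out = min(cfg$n_trajectory,
                                                      nrow(pool)))))
            panel <- pool[take, c("section", "id")]
            sel <- paste(meas$section, meas$spas_id) %in%
                paste(panel$section, panel$id)
            if (any(sel))
                trajectories <- trajectory_table(meas[sel, , drop = FALSE])
        }
    }
    ref_trajectories <- if (!is.null(ref_meas)) {
        rm2 <- ref_meas
        rm2$cycle <- 0
        trajectory_table(rm2)
    } else NULL

    fits <- list()
    slopes <- list()
    enough <- length(ct_modes) == 2L && cfg$n_sections >= 2L &&
        length(cfg$phases) >= 2L && !is.null(counts)
    if (enough) {
        rhs <- c("mode",
                 if (length(unique(counts$position)) > 1L) "position",
                 if (length(cfg$cycles) > 1L) "factor(cycle)",
                 "compression_pct", "mode:compression_pct")
        fml <- stats::reformulate(rhs, response = "total")
        counts$mode <- factor(counts$mode, levels = c("NR", "UHR"))
        fits$counts <- tryCatch(fit_lmm(fml, counts, "section"),
                                error = function(e) {
                                    message("count model failed: ",
                                            conditionMessage(e)); NULL
                                })
        peaks$mode <- factor(peaks$mode, levels = c("NR", "UHR"))
        fml_b <- stats::reformulate(rhs, response = "peak_b0")
        fits$peak_b0 <- tryCatch(fit_lmm(fml_b, peaks, "section"),
                                 error = function(e) {
                                     message("peak-b0 model failed: ",
                                             conditionMessage(e)); NULL
                                 })
        slopes$counts <- group_regression_lines(counts, "compression_pct",
                                                "total", "mode")
        slopes$peak_b0 <- group_regression_lines(peaks, "compression_pct",
                                                 "peak_b0", "mode")
        if (!is.null(trajectories)) {
            tr <- trajectories[trajectories$measurable, , drop = FALSE]
            for (m in ct_modes) {
                dm <- tr[tr$mode == m, , drop = FALSE]
                if (nrow(dm) >= 8L && length(unique(dm$section)) >= 2L) {
                    fits[[paste0("trajectory_", m)]] <- tryCatch(
                        fit_lmm(d_long_mm ~ compression_pct, dm, "section"),
                        error = function(e) NULL)
                }
            }
            if (nrow(tr) >= 16L) {
                tr$mode <- factor(tr$mode, levels = c("NR", "UHR"))
                fits$trajectory_interaction <- tryCatch(
                    fit_lmm(d_long_mm ~ mode * compression_pct, tr, "section"),
                    error = function(e) NULL)
            }
        }
    } else if (length(cfg$phases) < 2L) {
        message("fewer than 2 phases: statistical stage skipped")
    }

    bundle <- structure(list(design = design, truths = truths_df,
                             counts = counts, peaks = peaks,
                             measurements = meas,
                             ref_measurements = ref_meas,
                             deviations = deviations,
                             trajectories = trajectories,
                             ref_trajectories = ref_trajectories,
                             fits = fits, slopes = slopes, config = cfg,
                             n_images_written = n_written),
                        class = "spasim_experiment")
    if (!is.null(out_dir)) write_experiment_outputs(bundle, out_dir)
    bundle
}

#' @export
print.spasim_experiment <- function(x, ...) {
    cat(sprintf("spasim_experiment: %d sections x %d phases x %s x %d cycle(s) = %d CT images\n",
                x$config$n_sections, length(x$config$phases),
                paste(setdiff(x$config$modes, "REFERENCE"), collapse = "/"),
                length(x$config$cycles), nrow(x$design)))
    if (!is.null(x$slopes$counts)) {
        cat("count slopes vs compression:\n")
        print(x$slopes$counts)
    }
    if (!is.null(x$fits$counts)) {
        ia <- grep(":compression_pct", names(x$fits$counts$beta), value = TRUE)
        if (length(ia)) {
            sc <- slope_contrast(x$fits$counts, ia[1])
            cat(sprintf("mode x compression contrast: %.3f [%.3f, %.3f], p = %.4g\n",
                        sc$difference, sc$ci95[1], sc$ci95[2], sc$p_value))
        }
    }
    invisible(x)
}

write_experiment_outputs <- function(bundle, out_dir) {
    wr <- function(obj, name) {
        if (!is.null(obj))
            write.csv(obj, file.path(out_dir, name), row.names = FALSE)
    }
    wr(bundle$truths, "truths.csv")
    wr(bundle$counts, "counts.csv")
    wr(bundle$peaks, "homology_peaks.csv")
    wr(bundle$measurements, "measurements.csv")
    wr(bundle$ref_measurements, "reference_measurements.csv")
    wr(bundle$deviations, "deviations.csv")
    wr(bundle$trajectories, "trajectories.csv")
    summary <- list(
        n_ct_images = nrow(bundle$design),
        count_slopes = bundle$slopes$counts,
        peak_b0_slopes = bundle$slopes$peak_b0)
    if (!is.null(bundle$fits$counts)) {
        ia <- grep(":compression_pct", names(bundle$fits$counts$beta),
                   value = TRUE)
        if (length(ia))
            summary$count_mode_compression_contrast <-
                slope_contrast(bundle$fits$counts, ia[1])
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    invisible(NULL)
}
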