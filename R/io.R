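#' Write and read CT images as 16-bit TIFF with a JSON sidecar
#'
#' HU values are rounded to integers and stored offset by +32768 in a
#' 16-bit TIFF; the sidecar `<path>.json` records `pixel_mm`, `mode`,
#' `compression_pct`, `seed` and `truth_id`.  The round trip preserves
#' the (integer-rounded) pixel values exactly.
#'
#' @param img a [ct_image()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_ct_image <- function(img, path) {
    stopifnot(inherits(img, "ct_image"))
    stored <- round(img$pixels) + 32768
    if (any(stored < 0 | stored > 65535))
        stop("HU values outside the representable range [-32768, 32767]",
             call. = FALSE)
    tiff::writeTIFF(stored / 65535, path, bits.per.sample = 16L,
                    compression = "none")
    side <- list(pixel_mm = img$pixel_mm, mode = img$mode,
                 compression_pct = img$compression_pct,
                 seed = img$seed, truth_id = img$truth_id)
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
    invisible(path)
}

#' @rdname write_ct_image
#' @export
read_ct_image <- function(path) {
    side_path <- paste0(path, ".json")
    if (!file.exists(side_path))
        stop("sidecar JSON missing: ", side_path, call. = FALSE)
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    for (f in c("pixel_mm", "mode", "compression_pct")) {
        if (is.null(side[[f]]))
            stop("sidecar field missing: ", f, call. = FALSE)
    }
    if (!is.numeric(side$pixel_mm) || side$pixel_mm <= 0)
        stop("sidecar field invalid: pixel_mm must be > 0", call. = FALSE)
    raw <- tiff::readTIFF(path)
    px <- round(raw * 65535) - 32768
    ct_image(px, side$pixel_mm, mode = side$mode,
             compression_pct = side$compression_pct,
             truth_id = side$truth_id, seed = side$seed)
}

#' Write and read windowed 8-bit images as PNG
#'
#' @param img8 a [window_to_8bit()] result.
#' @param path output PNG path.
#' @return `path` invisibly; `read_image8` returns the integer pixel
#'   matrix (0..255).
#' @export
write_image8 <- function(img8, path) {
    px <- if (inherits(img8, "spas_image8")) img8$pixels else img8
    png::writePNG(px / 255, path)
    invisible(path)
}

#' @rdname write_image8
#' @export
read_image8 <- function(path) {
    raw <- png::readPNG(path)
    if (length(dim(raw)) == 3L) raw <- raw[, , 1]
    matrix(as.integer(round(raw * 255)), nrow(raw), ncol(raw))
}
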