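#' AFM-like height image
#'
#' A physical-unit 2D height raster: a numeric matrix of surface heights in
#' nm (rows = y, columns = x) with a lateral pixel size and free-form
#' provenance metadata.
#'
#' @param heights Numeric matrix of heights (nm), finite everywhere.
#' @param pixel_nm Lateral pixel size (nm), > 0.
#' @param metadata Named list of provenance metadata (seed, preset, noise).
#' @return An `afm_image`.
#' @export
afm_image <- function(heights, pixel_nm, metadata = list()) {
  if (!is.matrix(heights) || !is.numeric(heights) ||
      any(!is.finite(heights))) {
    stop_invalid("`heights` must be a finite numeric matrix.")
  }
  check_number(pixel_nm, "pixel_nm")
  if (pixel_nm <= 0) stop_invalid("`pixel_nm` must be > 0.")
  structure(list(heights = heights, pixel_nm = pixel_nm,
                 metadata = metadata),
            class = "afm_image")
}

#' @export
print.afm_image <- function(x, ...) {
  d <- dim(x$heights)
  cat(sprintf(
    "<afm_image> %d x %d px (%.1f x %.1f nm), pixel %.3g nm\n",
    d[2], d[1], d[2] * x$pixel_nm, d[1] * x$pixel_nm, x$pixel_nm))
  cat(sprintf("  height range %.2f .. %.2f nm\n",
              min(x$heights), max(x$heights)))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.afm_image <- function(object, ...) {
  d <- dim(object$heights)
  df <- expand_grid(y_nm = (seq_len(d[1]) - 0.5) * object$pixel_nm,
                    x_nm = (seq_len(d[2]) - 0.5) * object$pixel_nm)
  df$height_nm <- as.vector(t(object$heights))
  ggplot(df, aes(.data$x_nm, .data$y_nm, fill = .data$height_nm)) +
    geom_raster() +
    scale_fill_viridis_c() +
    coord_equal() +
    labs(x = "x (nm)", y = "y (nm)", fill = "height (nm)") +
    theme_minimal()
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write an AFM height image as float TIFF plus JSON sidecar
#'
#' The raster is stored as a 32-bit float TIFF (min-max normalized to
#' [0, 1]; the normalization offset and scale are recorded in the sidecar so
#' heights are recovered in nm at float32 precision) with a JSON sidecar at
#' `<path>.json` holding `pixel_nm`, `height_offset_nm`, `height_scale_nm`
#' and the image metadata.
#'
#' @param image An [afm_image()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_afm_image <- function(image, path) {
  stopifnot(inherits(image, "afm_image"))
  off <- min(image$heights)
  scale <- max(image$heights) - off
  if (scale == 0) scale <- 1
  tiff::writeTIFF((image$heights - off) / scale, path,
                  bits.per.sample = 32, reduce = FALSE)
  side <- c(list(pixel_nm = image$pixel_nm, height_offset_nm = off,
                 height_scale_nm = scale),
            image$metadata)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an AFM height image written by [write_afm_image()]
#'
#' @param path TIFF path; the JSON sidecar `<path>.json` must exist and
#'   contain `pixel_nm`. Unknown sidecar keys are preserved in the image
#'   metadata.
#' @return An [afm_image()] with heights in nm.
#' @export
read_afm_image <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("no such file: %s", path))
  sp <- sidecar_path(path)
  if (!file.exists(sp)) {
    abort(sprintf("missing JSON sidecar: expected %s", sp),
          class = "vippgeom_format_error")
  }
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (is.null(side$pixel_nm)) {
    abort("sidecar lacks required key `pixel_nm`.",
          class = "vippgeom_format_error")
  }
  raw <- tiff::readTIFF(path, info = TRUE)
  bits <- attr(raw, "bits.per.sample")
  if (!identical(as.integer(bits), 32L) || length(dim(raw)) != 2) {
    abort("expected a single-channel 32-bit float TIFF.",
          class = "vippgeom_format_error")
  }
  attributes(raw) <- list(dim = dim(raw))
  off <- side$height_offset_nm %||% 0
  scale <- side$height_scale_nm %||% 1
  meta <- side[setdiff(names(side),
                       c("pixel_nm", "height_offset_nm",
                         "height_scale_nm"))]
  afm_image(raw * scale + off, side$pixel_nm, metadata = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
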