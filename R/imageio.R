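## Image I/O: multi-page 16-bit TIFF per field with a JSON sidecar
## carrying channel names and calibration metadata.

#' Write an image set to a multi-page 16-bit TIFF
#'
#' One page per channel, in the sidecar's channel order; a JSON sidecar
#' (\code{<path>.json}) records channel names, pixel scale, stretching
#' constant, field id, seed and configuration hash. The round trip
#' through [read_imageset()] is lossless for 16-bit counts.
#'
#' @param imageset A \code{fiber_imageset}.
#' @param path Output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_imageset <- function(imageset, path) {
  if (!inherits(imageset, "fiber_imageset"))
    stop("format error: not a fiber_imageset", call. = FALSE)
  pages <- lapply(imageset$channels, function(m) m / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "none", reduce = FALSE)
  meta <- list(channels = names(imageset$channels),
               pixel_um = imageset$pixel_um,
               kb_per_um = imageset$kb_per_um,
               field = imageset$field,
               seed = imageset$seed,
               config_hash = imageset$config_hash,
               bits = 16L)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image set written by [write_imageset()]
#'
#' 8-bit TIFF input is accepted and up-converted to the 16-bit count
#' scale with a warning. A missing required channel is an explicit
#' format error naming the channel.
#'
#' @param path TIFF path (sidecar \code{<path>.json} must exist).
#' @param require_channels Channels that must be present.
#' @return A \code{fiber_imageset}.
#' @export
read_imageset <- function(path, require_channels = c("cldU", "idU", "qdot")) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("format error: metadata sidecar not found: ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(meta$channels))
    stop("format error: ", length(pages), " TIFF page(s) but ",
         length(meta$channels), " channel name(s) in sidecar", call. = FALSE)
  missing_ch <- setdiff(require_channels, meta$channels)
  if (length(missing_ch))
    stop("format error: missing channel(s): ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  bits <- if (!is.null(meta$bits)) meta$bits else 16L
  depth_in <- if (max(vapply(pages, max, numeric(1))) > 255 || bits == 16L)
    16L else 8L
  channels <- lapply(pages, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    if (depth_in == 8L) m * 257 else m
  })
  if (depth_in == 8L)
    warning("8-bit TIFF input up-converted to the 16-bit count scale")
  names(channels) <- meta$channels
  shp <- dim(channels[[1]])
  if (!all(vapply(channels, function(m) identical(dim(m), shp), logical(1))))
    stop("format error: TIFF pages have mismatched shapes", call. = FALSE)
  rc <- render_config(pixel_um = meta$pixel_um, kb_per_um = meta$kb_per_um,
                      image_shape = shp)
  new_imageset(channels, rc,
               field = if (!is.null(meta$field)) meta$field else 1L,
               seed = if (!is.null(meta$seed)) meta$seed else NA_integer_,
               config_hash = if (!is.null(meta$config_hash))
                 meta$config_hash else NA_character_)
}
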