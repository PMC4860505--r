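## Rendering: lay ground-truth fibers out as smooth curvilinear paths and
## draw them into three-channel (CldU / IdU / quantum-dot) images with a
## Gaussian PSF, background and noise, emitting pixel ground truth.

# arc-length-parameterized smooth path, mostly horizontal within a lane.
# Heading evolves as a mean-reverting random walk with a pull back toward
# the lane center, giving bounded curvature and bounded vertical wander.
make_path <- function(len_px, x0, y0, ds = 0.5, wiggle_sd = 0.02,
                      y_pull = 0.015, theta_max = 0.45) {
  n <- max(2L, ceiling(len_px / ds) + 1L)
  x <- y <- theta <- numeric(n)
  x[1] <- x0; y[1] <- y0; theta[1] <- 0
  dth <- rnorm(n, 0, wiggle_sd)
  for (i in 2:n) {
    th <- 0.95 * theta[i - 1] + dth[i] - y_pull * (y[i - 1] - y0)
    th <- max(min(th, theta_max), -theta_max)
    theta[i] <- th
    x[i] <- x[i - 1] + ds * cos(th)
    y[i] <- y[i - 1] + ds * sin(th)
  }
  arc <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  keep <- arc <= len_px
  keep[max(2L, sum(keep))] <- TRUE
  data.frame(arc_px = arc[keep], x = x[keep], y = y[keep])
}

# bilinear deposit of weighted point masses into a matrix (rows x cols);
# x is the column coordinate, y the row coordinate (1-based, continuous)
deposit <- function(mat, x, y, w) {
  nr <- nrow(mat); nc <- ncol(mat)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  px <- c(x0, x0 + 1, x0, x0 + 1)
  py <- c(y0, y0, y0 + 1, y0 + 1)
  pw <- c(w * (1 - fx) * (1 - fy), w * fx * (1 - fy),
          w * (1 - fx) * fy, w * fx * fy)
  ok <- px >= 1 & px <= nc & py >= 1 & py <= nr & pw > 0
  if (!any(ok)) return(mat)
  idx <- (px[ok] - 1L) * nr + py[ok]
  acc <- rowsum(pw[ok], idx)
  ii <- as.integer(rownames(acc))
  mat[ii] <- mat[ii] + acc[, 1]
  mat
}

# interpolate (x, y) on a path at given arc positions
path_at <- function(path, arc_px) {
  a <- pmin(pmax(arc_px, 0), max(path$arc_px))
  cbind(x = approx(path$arc_px, path$x, a, rule = 2)$y,
        y = approx(path$arc_px, path$y, a, rule = 2)$y)
}

# greedy lane layout; returns per-fiber field / lane-center / x-offset
layout_fibers <- function(len_px, rc) {
  nr <- rc$image_shape[1]; nc <- rc$image_shape[2]
  usable_w <- nc - 2 * rc$margin_px
  if (any(len_px > usable_w))
    stop("fiber of ", round(max(len_px)), " px exceeds the usable image ",
         "width (", usable_w, " px); enlarge image_shape or truncate ",
         "fiber lengths", call. = FALSE)
  n_lanes <- floor((nr - 2 * rc$margin_px) / rc$lane_height_px)
  if (n_lanes < 1L)
    stop("image too small for one fiber lane; enlarge image_shape",
         call. = FALSE)
  field <- lane <- integer(length(len_px))
  x0 <- y0 <- numeric(length(len_px))
  cur_f <- 1L; cur_l <- 1L; cur_x <- rc$margin_px
  for (i in seq_along(len_px)) {
    if (cur_x + len_px[i] > nc - rc$margin_px) {
      cur_l <- cur_l + 1L; cur_x <- rc$margin_px
      if (cur_l > n_lanes) { cur_f <- cur_f + 1L; cur_l <- 1L }
    }
    field[i] <- cur_f; lane[i] <- cur_l
    x0[i] <- cur_x
    y0[i] <- rc$margin_px + (cur_l - 0.5) * rc$lane_height_px
    cur_x <- cur_x + len_px[i] + rc$lane_gap_px
  }
  data.frame(field = field, lane = lane, x0 = x0, y0 = y0)
}

apply_noise <- function(signal, rc) {
  img <- signal + rc$background_level
  if (rc$shot_noise)
    img <- rpois(length(img), pmax(img, 0) * rc$photon_gain) / rc$photon_gain
  if (rc$read_noise_sd > 0)
    img <- img + rnorm(length(img), 0, rc$read_noise_sd)
  m <- matrix(pmin(pmax(round(img), 0), 65535), nrow(signal), ncol(signal))
  m
}

#' Render a fiber population as multi-channel images
#'
#' Fibers are laid out as smooth curvilinear paths (bounded curvature,
#' minimum separation via lanes) across as many image fields as needed.
#' The CldU channel carries every fiber over its full length, the IdU
#' channel only the replication-tract arc segments, and the quantum-dot
#' channel a diffraction-limited spot per adduct at its mapped arc
#' position. All channels are blurred with a Gaussian PSF, then
#' background, Poisson shot noise and Gaussian read noise are added and
#' intensities quantized to 16-bit counts. Pixel ground truth (fiber
#' paths and spot coordinates) is emitted alongside.
#'
#' @param pop A [simulate_fibers()] population.
#' @param rc A [render_config()]; defaults to the population's.
#' @return An object of class \code{fiber_fields}: list of
#'   \code{fiber_imageset} objects (one per field) plus ground-truth
#'   \code{layout} (fiber_id, field, path polylines) and \code{spots}
#'   (fiber_id, field, position_kb, x, y) tables.
#' @export
#' @examples
#' pop <- simulate_fibers(simulation_config(
#'   n_fibers = 4, seed = 2,
#'   fiber_length_dist = length_dist(kind = "fixed", value_kb = 120),
#'   render = render_config(image_shape = c(256L, 512L))))
#' flds <- render_images(pop)
#' flds
render_images <- function(pop, rc = pop$config$render) {
  rc <- validate_render_config(rc)
  kbpx <- kb_per_px(rc)
  n <- nrow(pop$fibers)
  len_px <- pop$fibers$length_kb / kbpx
  lay <- if (n > 0) layout_fibers(len_px, rc) else
    data.frame(field = integer(0), lane = integer(0),
               x0 = numeric(0), y0 = numeric(0))
  n_fields <- if (n > 0) max(lay$field) else 1L
  nr <- rc$image_shape[1]; nc <- rc$image_shape[2]
  paths <- vector("list", n)
  spot_l <- list()
  fields <- vector("list", n_fields)
  for (f in seq_len(n_fields)) {
    ch <- list(cldU = matrix(0, nr, nc), idU = matrix(0, nr, nc),
               qdot = matrix(0, nr, nc))
    idx <- which(lay$field == f)
    for (i in idx) {
      p <- make_path(len_px[i], lay$x0[i], lay$y0[i])
      paths[[i]] <- p
      ds <- diff(p$arc_px)
      mid <- cbind(x = (p$x[-1] + p$x[-nrow(p)]) / 2,
                   y = (p$y[-1] + p$y[-nrow(p)]) / 2)
      ch$cldU <- deposit(ch$cldU, mid[, "x"], mid[, "y"],
                         rc$channel_gains[["cldU"]] * ds)
      tr <- pop$tracts[pop$tracts$fiber_id == pop$fibers$fiber_id[i] &
                         pop$tracts$label == "IdU", , drop = FALSE]
      if (nrow(tr)) {
        arc_mid_kb <- (p$arc_px[-1] + p$arc_px[-nrow(p)]) / 2 * kbpx
        inside <- rep(FALSE, length(arc_mid_kb))
        for (k in seq_len(nrow(tr)))
          inside <- inside | (arc_mid_kb >= tr$start_kb[k] &
                              arc_mid_kb < tr$end_kb[k])
        if (any(inside))
          ch$idU <- deposit(ch$idU, mid[inside, "x"], mid[inside, "y"],
                            rc$channel_gains[["idU"]] * ds[inside])
      }
      ad <- pop$adducts[pop$adducts$fiber_id == pop$fibers$fiber_id[i], ,
                        drop = FALSE]
      if (nrow(ad)) {
        xy <- path_at(p, ad$position_kb / kbpx)
        ch$qdot <- deposit(ch$qdot, xy[, "x"], xy[, "y"],
                           rep(rc$channel_gains[["qdot"]], nrow(ad)))
        spot_l[[length(spot_l) + 1L]] <-
          data.frame(fiber_id = pop$fibers$fiber_id[i], field = f,
                     position_kb = ad$position_kb,
                     x = xy[, "x"], y = xy[, "y"])
      }
    }
    if (rc$psf_sigma_px > 0)
      ch <- lapply(ch, function(m)
        as.matrix(EBImage::gblur(m, sigma = rc$psf_sigma_px)))
    ch <- lapply(ch, apply_noise, rc = rc)
    fields[[f]] <- new_imageset(ch, rc, field = f,
                                seed = pop$config$seed,
                                config_hash = config_hash(pop$config))
  }
  spots <- if (length(spot_l)) do.call(rbind, spot_l) else
    data.frame(fiber_id = integer(0), field = integer(0),
               position_kb = numeric(0), x = numeric(0), y = numeric(0))
  rownames(spots) <- NULL
  structure(list(fields = fields,
                 layout = cbind(fiber_id = pop$fibers$fiber_id, lay),
                 paths = paths, spots = spots, render = rc),
            class = "fiber_fields")
}

new_imageset <- function(channels, rc, field = 1L, seed = NA_integer_,
                         config_hash = NA_character_) {
  shp <- dim(channels[[1]])
  if (!all(vapply(channels, function(m) identical(dim(m), shp), logical(1))))
    stop("format error: all channels must have identical shape", call. = FALSE)
  if (any(vapply(channels, function(m) any(m < 0), logical(1))))
    stop("format error: channel intensities must be non-negative",
         call. = FALSE)
  structure(list(channels = channels, pixel_um = rc$pixel_um,
                 kb_per_um = rc$kb_per_um, field = field,
                 seed = seed, config_hash = config_hash),
            class = "fiber_imageset")
}

#' @export
print.fiber_imageset <- function(x, ...) {
  cat(sprintf("Fiber image set (field %s): %d x %d px, %.3g um/px\n",
              x$field, nrow(x$channels[[1]]), ncol(x$channels[[1]]),
              x$pixel_um))
  for (nm in names(x$channels))
    cat(sprintf("  %-5s mean %.1f  max %.0f\n", nm,
                mean(x$channels[[nm]]), max(x$channels[[nm]])))
  invisible(x)
}

#' @export
print.fiber_fields <- function(x, ...) {
  cat(sprintf("Rendered fiber fields: %d field(s), %d fibers, %d spots\n",
              length(x$fields), nrow(x$layout), nrow(x$spots)))
  invisible(x)
}

#' Display one rendered field as an RGB composite
#'
#' CldU in green, IdU in blue, quantum-dot signal in red, each channel
#' scaled to its own maximum.
#'
#' @param x A \code{fiber_imageset}.
#' @param ... Unused.
#' @export
plot.fiber_imageset <- function(x, ...) {
  sc <- function(m) {
    m <- m - min(m)
    if (max(m) > 0) m / max(m) else m
  }
  rgb_arr <- array(0, c(nrow(x$channels[[1]]), ncol(x$channels[[1]]), 3))
  rgb_arr[, , 1] <- sc(x$channels$qdot)
  rgb_arr[, , 2] <- sc(x$channels$cldU)
  rgb_arr[, , 3] <- sc(x$channels$idU)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::rasterImage(rgb_arr, 0, 0, 1, 1)
  invisible(x)
}
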