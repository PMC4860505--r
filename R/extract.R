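## Signal extraction: quantum-dot spot detection, spot-to-fiber
## assignment by perpendicular projection, and IdU tract segmentation
## along each fiber's arc.

#' Spot-detection parameters
#'
#' @param threshold_k Acceptance threshold: local maxima must exceed the
#'   background median by \code{threshold_k} robust SDs (SD multiples
#'   rather than absolute counts, so the rule is invariant to channel
#'   gain).
#' @param min_separation_px Maxima closer than this are merged, keeping
#'   the brighter one.
#' @param centroid_radius_px Half-width of the window used for the
#'   intensity-weighted sub-pixel centroid.
#' @return A \code{spot_params} list.
#' @export
spot_params <- function(threshold_k = 5, min_separation_px = 3,
                        centroid_radius_px = 2L) {
  structure(list(threshold_k = threshold_k,
                 min_separation_px = min_separation_px,
                 centroid_radius_px = as.integer(centroid_radius_px)),
            class = "spot_params")
}

#' Detect quantum-dot spots in one channel
#'
#' Pixels that are 3 x 3 local maxima and exceed background median +
#' \code{threshold_k} robust SDs are accepted; nearby maxima are merged
#' to the brighter one; centroids are refined to sub-pixel precision by
#' an intensity-weighted centroid of the background-subtracted window.
#' Zero detections is a valid outcome.
#'
#' @param channel A 2-D intensity matrix (e.g. the qdot channel).
#' @param params A [spot_params()].
#' @return Data frame with \code{x}, \code{y} (sub-pixel, column/row
#'   pixel coordinates), \code{peak_intensity} and \code{snr}.
#' @export
detect_spots <- function(channel, params = spot_params()) {
  bg <- robust_bg(channel)
  thr <- bg$median + params$threshold_k * bg$sd
  dil <- as.matrix(EBImage::dilate(EBImage::Image(channel / 65535),
                                   EBImage::makeBrush(3, "box"))) * 65535
  cand <- which(channel >= dil - 1e-6 & channel > thr)
  out <- data.frame(x = numeric(0), y = numeric(0),
                    peak_intensity = numeric(0), snr = numeric(0))
  if (!length(cand)) return(out)
  nr <- nrow(channel); nc <- ncol(channel)
  yy <- (cand - 1L) %% nr + 1L
  xx <- (cand - 1L) %/% nr + 1L
  peak <- channel[cand]
  # merge candidates closer than min_separation_px, brightest first
  ord <- order(peak, decreasing = TRUE)
  keep <- logical(length(ord))
  for (i in ord) {
    if (any(keep & (xx - xx[i])^2 + (yy - yy[i])^2 <
              params$min_separation_px^2)) next
    keep[i] <- TRUE
  }
  xx <- xx[keep]; yy <- yy[keep]; peak <- peak[keep]
  r <- params$centroid_radius_px
  cx <- cy <- numeric(length(xx))
  for (i in seq_along(xx)) {
    rs <- max(1, yy[i] - r):min(nr, yy[i] + r)
    cs <- max(1, xx[i] - r):min(nc, xx[i] + r)
    w <- pmax(channel[rs, cs, drop = FALSE] - bg$median, 0)
    if (sum(w) == 0) { cx[i] <- xx[i]; cy[i] <- yy[i]; next }
    cx[i] <- sum(w %*% cbind(cs)) / sum(w)
    cy[i] <- sum(rs %*% w) / sum(w)
  }
  data.frame(x = cx, y = cy, peak_intensity = peak,
             snr = (peak - bg$median) / bg$sd)
}

# min distance from point to each polyline, with projection arc position
point_to_polyline <- function(px, py, poly) {
  x1 <- poly$x[-nrow(poly)]; y1 <- poly$y[-nrow(poly)]
  x2 <- poly$x[-1];          y2 <- poly$y[-1]
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  t <- ((px - x1) * dx + (py - y1) * dy) / pmax(len2, 1e-12)
  t <- pmin(pmax(t, 0), 1)
  qx <- x1 + t * dx; qy <- y1 + t * dy
  d2 <- (px - qx)^2 + (py - qy)^2
  i <- which.min(d2)
  arc <- poly$arc_px[i] + t[i] * sqrt(len2[i])
  list(dist = sqrt(d2[i]), arc_px = arc)
}

#' Assign detected spots to traced fibers
#'
#' Each spot goes to the trace minimizing perpendicular distance,
#' provided that distance is at most \code{max_dist_px}; its position
#' along the fiber (\code{arc_kb}) is the calibrated arc length of the
#' projection point. Spots beyond the cutoff, or exactly equidistant
#' between two traces, are left unassigned (ties are counted, not
#' guessed).
#'
#' @param spots Data frame from [detect_spots()].
#' @param traces A \code{fiber_traces} object.
#' @param max_dist_px Assignment cutoff in pixels.
#' @return List with \code{signals} (data frame: \code{trace_id},
#'   \code{arc_kb}, \code{x}, \code{y}, \code{peak_intensity},
#'   \code{snr}), \code{unassigned} count and \code{ties} count.
#' @export
assign_spots_to_fibers <- function(spots, traces, max_dist_px = 3) {
  kbpx <- traces$pixel_um * traces$kb_per_um
  sig <- data.frame(trace_id = integer(0), arc_kb = numeric(0),
                    x = numeric(0), y = numeric(0),
                    peak_intensity = numeric(0), snr = numeric(0))
  ties <- 0L; unassigned <- 0L
  if (!nrow(spots) || !nrow(traces$traces))
    return(list(signals = sig, unassigned = nrow(spots), ties = 0L))
  # bounding boxes pre-filter
  bbs <- t(vapply(traces$polylines, function(p)
    c(min(p$x), max(p$x), min(p$y), max(p$y)), numeric(4)))
  pad <- max_dist_px + 2
  rows <- list()
  for (i in seq_len(nrow(spots))) {
    px <- spots$x[i]; py <- spots$y[i]
    cand <- which(px >= bbs[, 1] - pad & px <= bbs[, 2] + pad &
                    py >= bbs[, 3] - pad & py <= bbs[, 4] + pad)
    if (!length(cand)) { unassigned <- unassigned + 1L; next }
    hits <- lapply(cand, function(k)
      point_to_polyline(px, py, traces$polylines[[k]]))
    d <- vapply(hits, `[[`, numeric(1), "dist")
    o <- order(d)
    if (d[o[1]] > max_dist_px) { unassigned <- unassigned + 1L; next }
    if (length(d) > 1L && abs(d[o[1]] - d[o[2]]) < 1e-9) {
      ties <- ties + 1L; unassigned <- unassigned + 1L
      next
    }
    k <- cand[o[1]]
    arc_kb <- min(hits[[o[1]]]$arc_px * kbpx, traces$traces$length_kb[k])
    rows[[length(rows) + 1L]] <-
      data.frame(trace_id = traces$traces$trace_id[k], arc_kb = arc_kb,
                 x = px, y = py, peak_intensity = spots$peak_intensity[i],
                 snr = spots$snr[i])
  }
  if (length(rows)) sig <- do.call(rbind, rows)
  rownames(sig) <- NULL
  list(signals = sig, unassigned = unassigned, ties = ties)
}

#' Tract-segmentation parameters
#'
#' @param threshold Absolute intensity threshold, or \code{NULL} to use
#'   Otsu's threshold on the per-fiber profile floored at background
#'   median + 3 robust SDs (raw Otsu on a tract-free profile would split
#'   noise).
#' @param gap_close_kb Sub-threshold gaps shorter than this are closed.
#' @param min_tract_kb Merged runs shorter than this are dropped.
#' @return A \code{tract_params} list.
#' @export
tract_params <- function(threshold = NULL, gap_close_kb = 1,
                         min_tract_kb = 5) {
  structure(list(threshold = threshold, gap_close_kb = gap_close_kb,
                 min_tract_kb = min_tract_kb), class = "tract_params")
}

otsu_threshold <- function(v) {
  rng <- range(v)
  if (diff(rng) <= 0) return(Inf)
  x <- array((v - rng[1]) / diff(rng), dim = c(length(v), 1L))
  EBImage::otsu(x, range = c(0, 1)) * diff(rng) + rng[1]
}

merge_intervals <- function(iv, gap_close, min_len) {
  if (!nrow(iv)) return(iv)
  iv <- iv[order(iv$start_kb), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
    j <- nrow(out)
    if (iv$start_kb[i] - out$end_kb[j] < gap_close) {
      out$end_kb[j] <- max(out$end_kb[j], iv$end_kb[i])
    } else out <- rbind(out, iv[i, , drop = FALSE])
  }
  out <- out[out$end_kb - out$start_kb >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Segment replication tracts along one fiber's IdU profile
#'
#' Supra-threshold runs of the arc-sampled IdU profile become intervals;
#' runs separated by sub-threshold gaps shorter than
#' \code{gap_close_kb} are merged; merged runs shorter than
#' \code{min_tract_kb} are dropped. Idempotent: re-running on intervals
#' already produced changes nothing.
#'
#' @param profile Data frame with \code{arc_kb} and the channel column.
#' @param params A [tract_params()].
#' @param channel Profile column to segment.
#' @param bg Optional background stats (list with \code{median},
#'   \code{sd}) used to floor the Otsu threshold.
#' @return Data frame of intervals: \code{start_kb}, \code{end_kb}
#'   (half-open), \code{mean_intensity}.
#' @export
segment_tracts <- function(profile, params = tract_params(),
                           channel = "idU", bg = NULL) {
  v <- profile[[channel]]
  arc <- profile$arc_kb
  empty <- data.frame(start_kb = numeric(0), end_kb = numeric(0),
                      mean_intensity = numeric(0))
  if (!length(v)) return(empty)
  thr <- params$threshold
  if (is.null(thr)) {
    thr <- otsu_threshold(v)
    if (!is.null(bg)) thr <- max(thr, bg$median + 3 * bg$sd)
  }
  above <- v > thr
  if (!any(above)) return(empty)
  step <- if (length(arc) > 1) median(diff(arc)) else 1
  r <- rle(above)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  runs <- which(r$values)
  iv <- data.frame(start_kb = pmax(arc[starts_i[runs]] - step / 2, 0),
                   end_kb = arc[ends_i[runs]] + step / 2)
  iv <- merge_intervals(iv, params$gap_close_kb, params$min_tract_kb)
  if (!nrow(iv)) return(empty)
  iv$mean_intensity <- vapply(seq_len(nrow(iv)), function(i)
    mean(v[arc >= iv$start_kb[i] & arc < iv$end_kb[i]]), numeric(1))
  iv
}

#' Extract signals and tracts from one traced field
#'
#' Convenience wrapper running [detect_spots()],
#' [assign_spots_to_fibers()] and [segment_tracts()] over all traces of
#' a field.
#'
#' @param imageset A \code{fiber_imageset}.
#' @param traces Matching \code{fiber_traces}.
#' @param spot_par,tract_par,max_dist_px Stage parameters.
#' @return List with \code{signals}, \code{tracts} (both keyed by
#'   \code{trace_id}), \code{unassigned}, \code{ties}.
#' @export
extract_field <- function(imageset, traces, spot_par = spot_params(),
                          tract_par = tract_params(), max_dist_px = 3) {
  spots <- detect_spots(imageset$channels$qdot, spot_par)
  asg <- assign_spots_to_fibers(spots, traces, max_dist_px)
  tr_l <- lapply(seq_len(nrow(traces$traces)), function(k) {
    iv <- segment_tracts(traces$profiles[[k]], tract_par,
                         bg = traces$bg_stats$idU)
    if (nrow(iv)) cbind(trace_id = traces$traces$trace_id[k], iv)
    else NULL
  })
  tr_l <- tr_l[!vapply(tr_l, is.null, logical(1))]
  tracts <- if (length(tr_l)) do.call(rbind, tr_l) else
    data.frame(trace_id = integer(0), start_kb = numeric(0),
               end_kb = numeric(0), mean_intensity = numeric(0))
  rownames(tracts) <- NULL
  list(signals = asg$signals, tracts = tracts,
       unassigned = asg$unassigned, ties = asg$ties)
}
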