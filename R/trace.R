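## Fiber tracing: threshold and skeletonize the CldU channel, link
## skeleton pixels into simple paths, discard crossings (branch points),
## and calibrate arc lengths into kb.

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Zhang-Suen thinning of a binary matrix (TRUE = foreground) to a
# one-pixel-wide 8-connected skeleton, with three amendments the pure
# parallel algorithm needs on curvilinear strokes:
#   - deletion candidates are found in parallel per subiteration but
#     confirmed sequentially against the current state (pure parallel
#     deletion disconnects two-pixel diagonal staircases);
#   - each iteration ends with a Hilditch-simple-point cleanup that
#     reduces two-pixel-wide diagonal bands, which Zhang-Suen cannot
#     thin and would instead erode from the ends one pixel per pass,
#     to unit width. Every deleted pixel is simple at deletion time,
#     so connectivity is preserved throughout.
skeletonize <- function(mask, max_iter = 100L) {
  nr0 <- nrow(mask); nc0 <- ncol(mask)
  m <- matrix(0L, nr0 + 2L, nc0 + 2L)   # zero border
  m[2:(nr0 + 1L), 2:(nc0 + 1L)] <- as.integer(mask)
  nr <- nrow(m)
  # neighbor order P2..P9: N, NE, E, SE, S, SW, W, NW (row -1 is "north")
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  lin_offs <- vapply(offs, function(o) o[1] + o[2] * nr, numeric(1))
  # a pixel whose only two neighbors are themselves adjacent is a line
  # tip; deleting tips erodes staircase ends indefinitely, so both the
  # thinning steps and the cleanup leave them alone
  ring_adj <- outer(seq_len(8), seq_len(8), Vectorize(function(i, j)
    i != j && max(abs(offs[[i]] - offs[[j]])) <= 1L))
  is_tip <- function(p) {
    w <- which(p == 1L)
    length(w) == 2L && ring_adj[w[1], w[2]]
  }
  xh_of <- function(p) {
    sum(vapply(c(1L, 3L, 5L, 7L), function(k)
      p[k] == 0L && (p[k %% 8L + 1L] == 1L ||
                     p[(k + 1L) %% 8L + 1L] == 1L), logical(1)))
  }
  check_del <- function(i, step) {
    p <- m[i + lin_offs]
    B <- sum(p)
    if (B < 2L || B > 6L) return(FALSE)
    if (is_tip(p)) return(FALSE)
    if (sum(p == 0L & c(p[-1], p[1]) == 1L) != 1L) return(FALSE)
    if (step == 1)
      p[1] * p[3] * p[5] == 0L && p[3] * p[5] * p[7] == 0L
    else
      p[1] * p[3] * p[7] == 0L && p[1] * p[5] * p[7] == 0L
  }
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    for (step in 1:2) {
      nb <- lapply(offs, function(o) shift_mat(m, -o[1], -o[2]))
      B <- Reduce(`+`, nb)
      A <- matrix(0L, nrow(m), ncol(m))
      for (k in 1:8) {
        nxt <- nb[[if (k == 8) 1 else k + 1]]
        A <- A + (nb[[k]] == 0L & nxt == 1L)
      }
      if (step == 1) {
        c1 <- nb[[1]] * nb[[3]] * nb[[5]] == 0L   # P2*P4*P6
        c2 <- nb[[3]] * nb[[5]] * nb[[7]] == 0L   # P4*P6*P8
      } else {
        c1 <- nb[[1]] * nb[[3]] * nb[[7]] == 0L   # P2*P4*P8
        c2 <- nb[[1]] * nb[[5]] * nb[[7]] == 0L   # P2*P6*P8
      }
      cand <- which(m == 1L & B >= 2L & B <= 6L & A == 1L & c1 & c2)
      for (i in cand) {
        if (check_del(i, step)) {
          m[i] <- 0L
          changed <- TRUE
        }
      }
    }
    # unit-width cleanup: delete non-endpoint pixels with Hilditch
    # crossing number 1 (their removal cannot disconnect the
    # neighborhood)
    nb <- lapply(offs, function(o) shift_mat(m, -o[1], -o[2]))
    B <- Reduce(`+`, nb)
    cand <- which(m == 1L & B >= 2L)
    for (i in cand) {
      p <- m[i + lin_offs]
      if (sum(p) < 2L || is_tip(p)) next
      if (xh_of(p) == 1L) {
        m[i] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m[2:(nr0 + 1L), 2:(nc0 + 1L)] == 1L
}

# Hilditch crossing number of each pixel: 1 at endpoints, 2 along a
# simple path, >= 3 at a junction (fiber crossing)
crossing_number <- function(skel) {
  s <- matrix(as.integer(skel), nrow(skel), ncol(skel))
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  nb <- lapply(offs, function(o) shift_mat(s, -o[1], -o[2]))
  xh <- matrix(0L, nrow(s), ncol(s))
  for (k in c(1L, 3L, 5L, 7L))
    xh <- xh + ((nb[[k]] == 0L) &
                  (nb[[k %% 8L + 1L]] == 1L |
                     nb[[(k + 1L) %% 8L + 1L]] == 1L))
  xh
}

# remove short skeleton spurs: endpoint branches shorter than
# max_spur_px that terminate at a branch point are boundary-noise
# artifacts of thinning, not fiber crossings
prune_spurs <- function(skel, max_spur_px = 8L, max_rounds = 5L) {
  nr <- nrow(skel)
  offs <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  for (round in seq_len(max_rounds)) {
    nbc <- neighbor_counts(skel)
    xh <- crossing_number(skel)
    ends <- which(skel & nbc == 1L)
    if (!length(ends)) break
    removed <- FALSE
    for (e in ends) {
      path <- integer(0)
      cur <- e
      prev <- -1L
      hit_branch <- FALSE
      for (k in seq_len(max_spur_px)) {
        path <- c(path, cur)
        nxt <- cur + offs
        nxt <- nxt[nxt >= 1L & nxt <= length(skel)]
        nxt <- nxt[skel[nxt] & nxt != prev & !(nxt %in% path)]
        if (!length(nxt)) break
        if (any(xh[nxt] >= 3L)) { hit_branch <- TRUE; break }
        prev <- cur
        cur <- nxt[1]
      }
      if (hit_branch) {
        skel[path] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  skel
}

# 8-connected component labels of a binary skeleton. EBImage::bwlabel
# is 4-connected, which would split diagonal skeleton links; labelling
# the 3x3 dilation and masking back gives 8-connectivity (fibers are
# laid out and retained with separations well above one pixel).
label8 <- function(skel) {
  d <- EBImage::dilate(EBImage::Image(skel * 1), EBImage::makeBrush(3, "box"))
  labs <- as.matrix(EBImage::bwlabel(d))
  labs * skel
}

# 8-neighbor count of each skeleton pixel
neighbor_counts <- function(skel) {
  s <- matrix(as.integer(skel), nrow(skel), ncol(skel))
  acc <- matrix(0L, nrow(s), ncol(s))
  for (dr in -1:1) for (dc in -1:1)
    if (dr != 0 || dc != 0) acc <- acc + shift_mat(s, dr, dc)
  acc
}

# order the pixels of a near-simple 8-connected path by its graph
# diameter: BFS from an arbitrary pixel finds one true end, BFS from
# there finds the other, and the parent chain between them is the
# ordered path. Robust to residual "triangle" corner pixels left by
# thinning (they are skipped, not mis-walked).
order_path <- function(idx, nr) {
  offs <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  pos <- new.env(hash = TRUE, size = length(idx))
  for (i in idx) assign(as.character(i), TRUE, envir = pos)
  bfs <- function(start) {
    seen <- new.env(hash = TRUE, size = length(idx))
    parent <- new.env(hash = TRUE, size = length(idx))
    assign(as.character(start), TRUE, envir = seen)
    queue <- integer(length(idx))
    queue[1] <- start
    qh <- 1L; qt <- 1L
    last <- start
    while (qh <= qt) {
      cur <- queue[qh]
      qh <- qh + 1L
      last <- cur
      for (nb in cur + offs) {
        key <- as.character(nb)
        if (exists(key, envir = pos, inherits = FALSE) &&
            !exists(key, envir = seen, inherits = FALSE)) {
          assign(key, TRUE, envir = seen)
          assign(key, cur, envir = parent)
          qt <- qt + 1L
          queue[qt] <- nb
        }
      }
    }
    list(far = last, parent = parent, n_reached = qt)
  }
  b1 <- bfs(idx[1])
  if (b1$n_reached != length(idx)) return(integer(0))  # not connected
  b2 <- bfs(b1$far)
  # walk parents from the far end back to b1$far
  path <- b2$far
  while (exists(as.character(path[1]), envir = b2$parent,
                inherits = FALSE)) {
    path <- c(get(as.character(path[1]), envir = b2$parent), path)
  }
  path
}

# extend a polyline past both endpoints along the local tangent while
# the smoothed image stays above half the local ridge height: thinning
# retracts skeleton tips by roughly the stroke half-width, and the
# blurred profile of a line end crosses 50% of the ridge intensity at
# the true endpoint, so the half-height crossing recovers it
extend_endpoints <- function(xy, img, bg_level, max_px = 8, ds = 0.5) {
  nr <- nrow(img); nc <- ncol(img)
  one_end <- function(tip, inner) {
    v <- tip - inner
    n <- sqrt(sum(v^2))
    if (n < 1e-9) return(NULL)
    v <- v / n
    ridge <- bilinear_sample(img, inner[1], inner[2])
    thr <- bg_level + 0.5 * (ridge - bg_level)
    if (ridge <= bg_level) return(NULL)
    added <- NULL
    for (k in seq_len(ceiling(max_px / ds))) {
      p <- tip + v * ds * k
      if (p[1] < 2 || p[1] > nc - 1 || p[2] < 2 || p[2] > nr - 1) break
      if (bilinear_sample(img, p[1], p[2]) < thr) break
      added <- rbind(added, p)
    }
    added
  }
  m <- nrow(xy)
  ref <- min(5L, m)
  head_ext <- one_end(xy[1, ], xy[ref, ])
  tail_ext <- one_end(xy[m, ], xy[m - ref + 1L, ])
  if (!is.null(head_ext))
    xy <- rbind(head_ext[rev(seq_len(nrow(head_ext))), , drop = FALSE], xy)
  if (!is.null(tail_ext)) xy <- rbind(xy, tail_ext)
  xy
}

smooth_polyline <- function(xy, window = 5L) {
  n <- nrow(xy)
  if (n < window) return(xy)
  half <- window %/% 2L
  sm <- apply(xy, 2, function(v) {
    s <- stats::filter(v, rep(1 / window, window), sides = 2)
    s[seq_len(half)] <- v[seq_len(half)]
    s[(n - half + 1):n] <- v[(n - half + 1):n]
    as.numeric(s)
  })
  sm
}

bilinear_sample <- function(mat, x, y) {
  nr <- nrow(mat); nc <- ncol(mat)
  x <- pmin(pmax(x, 1), nc - 1e-9)
  y <- pmin(pmax(y, 1), nr - 1e-9)
  x0 <- pmin(floor(x), nc - 1); y0 <- pmin(floor(y), nr - 1)
  fx <- x - x0; fy <- y - y0
  v00 <- mat[cbind(y0, x0)];     v10 <- mat[cbind(y0, x0 + 1)]
  v01 <- mat[cbind(y0 + 1, x0)]; v11 <- mat[cbind(y0 + 1, x0 + 1)]
  v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
    v01 * (1 - fx) * fy + v11 * fx * fy
}

robust_bg <- function(m) {
  med <- median(m)
  s <- mad(m, center = med)
  if (s == 0) s <- sd(m) * 0.5
  list(median = med, sd = s)
}

#' Tracing parameters
#'
#' @param threshold_k Foreground threshold in robust background SDs
#'   above the background median of the smoothed CldU channel.
#' @param smooth_sigma_px Pre-threshold Gaussian smoothing sigma.
#' @param min_fiber_kb Traces shorter than this are discarded as debris.
#' @param step_kb Arc step at which per-channel profiles are sampled.
#' @param polyline_window Running-mean window (pixels) smoothing the
#'   skeleton polyline before arc-length summation, which removes the
#'   digitization staircase bias.
#' @param edge_margin_px Traces coming within this many pixels of the
#'   border are flagged \code{edge_touching} (field-of-view truncation).
#' @return A \code{trace_params} list.
#' @export
trace_params <- function(threshold_k = 4, smooth_sigma_px = 1,
                         min_fiber_kb = 30, step_kb = 0.5,
                         polyline_window = 5L, edge_margin_px = 2L) {
  structure(list(threshold_k = threshold_k,
                 smooth_sigma_px = smooth_sigma_px,
                 min_fiber_kb = min_fiber_kb, step_kb = step_kb,
                 polyline_window = as.integer(polyline_window),
                 edge_margin_px = as.integer(edge_margin_px)),
            class = "trace_params")
}

#' Trace DNA fibers in the CldU channel
#'
#' The CldU channel is lightly smoothed, thresholded at
#' \code{threshold_k} robust SDs above background, morphologically
#' closed, and skeletonized. Skeleton components containing a branch
#' point (fiber crossings) are discarded entirely and counted; simple
#' paths are ordered endpoint-to-endpoint, their polylines smoothed, and
#' arc length calibrated to kb. Per-channel intensity profiles are
#' sampled along each retained trace at a fixed kb step.
#'
#' @param imageset A \code{fiber_imageset}.
#' @param params A [trace_params()].
#' @return An object of class \code{fiber_traces}: \code{traces} data
#'   frame (\code{trace_id}, \code{field}, \code{length_px},
#'   \code{length_kb}, \code{edge_touching}, \code{n_points}),
#'   \code{polylines} and \code{profiles} lists, \code{crossing_count},
#'   \code{bg_stats} per channel, and the calibration used. An empty or
#'   flat image yields zero traces with a warning, not an error.
#' @export
segment_fibers <- function(imageset, params = trace_params()) {
  ch <- imageset$channels$cldU
  if (is.null(ch)) stop("format error: CldU channel missing", call. = FALSE)
  bg_stats <- lapply(imageset$channels, robust_bg)
  sm <- if (params$smooth_sigma_px > 0)
    as.matrix(EBImage::gblur(ch, sigma = params$smooth_sigma_px)) else ch
  # background statistics from the raw (quantized) channel: smoothing
  # spreads vanishing tails over an exactly-zero background and would
  # wreck the MAD estimate on noise-free input
  bg <- robust_bg(ch)
  empty <- function(msg) {
    warning(msg)
    new_traces(list(), list(), list(), 0L, bg_stats, imageset, params)
  }
  if (max(sm) - bg$median < max(4 * bg$sd, 1e-9))
    return(empty("flat image: no fibers traced"))
  mask <- sm > bg$median + params$threshold_k * bg$sd
  mask <- EBImage::closing(EBImage::Image(mask * 1),
                           EBImage::makeBrush(3, "box")) > 0.5
  mask <- as.matrix(mask)
  if (!any(mask)) return(empty("no foreground pixels: no fibers traced"))
  skel <- prune_spurs(skeletonize(mask))
  labs <- label8(skel)
  xh <- crossing_number(skel)
  nr <- nrow(skel); ncol_ <- ncol(skel)
  kbpx <- imageset$pixel_um * imageset$kb_per_um
  polylines <- list(); profiles <- list(); rows <- list()
  crossing_count <- 0L
  for (lab in seq_len(max(labs))) {
    idx <- which(labs == lab)
    if (length(idx) < 3L) next
    if (max(xh[idx]) >= 3L) {           # branch point: fiber crossing
      crossing_count <- crossing_count + 1L
      next
    }
    path <- order_path(idx, nr)
    # the diameter path may skip residual triangle-corner pixels, but a
    # large shortfall means a tangled component, not a fiber
    if (length(path) < 0.9 * length(idx)) next
    cc <- (path - 1L) %/% nr + 1L
    rr <- (path - 1L) %% nr + 1L
    xy <- smooth_polyline(cbind(x = cc, y = rr), params$polyline_window)
    xy <- extend_endpoints(xy, sm, bg$median)
    seg <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
    arc_px <- c(0, cumsum(seg))
    length_px <- arc_px[length(arc_px)]
    length_kb <- calibrate_length(length_px, imageset$pixel_um,
                                  imageset$kb_per_um)
    if (length_kb < params$min_fiber_kb) next
    edge <- any(rr <= params$edge_margin_px | cc <= params$edge_margin_px |
                  rr > nr - params$edge_margin_px |
                  cc > ncol_ - params$edge_margin_px)
    k <- length(rows) + 1L
    poly <- data.frame(arc_px = arc_px, x = xy[, 1], y = xy[, 2])
    n_samp <- ceiling(length_kb / params$step_kb)
    arc_kb <- (seq_len(n_samp) - 0.5) * params$step_kb
    arc_kb <- pmin(arc_kb, length_kb)
    pts <- path_at(poly, arc_kb / kbpx)
    prof <- data.frame(arc_kb = arc_kb)
    for (nm in names(imageset$channels))
      prof[[nm]] <- bilinear_sample(imageset$channels[[nm]],
                                    pts[, "x"], pts[, "y"])
    polylines[[k]] <- poly
    profiles[[k]] <- prof
    rows[[k]] <- data.frame(trace_id = k, field = imageset$field,
                            length_px = length_px, length_kb = length_kb,
                            edge_touching = edge,
                            n_points = length(path))
  }
  new_traces(rows, polylines, profiles, crossing_count, bg_stats,
             imageset, params)
}

new_traces <- function(rows, polylines, profiles, crossing_count,
                       bg_stats, imageset, params) {
  traces <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trace_id = integer(0), field = integer(0),
               length_px = numeric(0), length_kb = numeric(0),
               edge_touching = logical(0), n_points = integer(0))
  rownames(traces) <- NULL
  structure(list(traces = traces, polylines = polylines,
                 profiles = profiles, crossing_count = crossing_count,
                 bg_stats = bg_stats,
                 pixel_um = imageset$pixel_um,
                 kb_per_um = imageset$kb_per_um,
                 field = imageset$field, params = params),
            class = "fiber_traces")
}

#' @export
print.fiber_traces <- function(x, ...) {
  cat(sprintf("Fiber traces (field %s): %d retained, %d crossing component(s) discarded\n",
              x$field, nrow(x$traces), x$crossing_count))
  if (nrow(x$traces))
    cat(sprintf("  length: %.0f-%.0f kb (median %.0f kb); %d edge-touching\n",
                min(x$traces$length_kb), max(x$traces$length_kb),
                median(x$traces$length_kb), sum(x$traces$edge_touching)))
  invisible(x)
}

#' Calibrate a trace length from pixels to kilobases
#'
#' Arc length (the summed segment lengths of the polyline, not the
#' endpoint-to-endpoint distance) times \code{pixel_um} times
#' \code{kb_per_um}.
#'
#' @param trace A \code{fiber_traces} row length in pixels (numeric), or
#'   an n x 2 polyline matrix of pixel coordinates.
#' @param pixel_um Micrometres per pixel (> 0).
#' @param kb_per_um Kilobases per micrometre (> 0).
#' @return Length in kb.
#' @export
#' @examples
#' calibrate_length(100, 0.16, 2.59)  # 41.44 kb
calibrate_length <- function(trace, pixel_um, kb_per_um) {
  if (!is.numeric(pixel_um) || pixel_um <= 0 ||
      !is.numeric(kb_per_um) || kb_per_um <= 0)
    stop("configuration error: calibration constants must be > 0",
         call. = FALSE)
  length_px <- if (is.matrix(trace) || is.data.frame(trace)) {
    xy <- as.matrix(trace)
    if (nrow(xy) < 2L) 0 else sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))
  } else as.numeric(trace)
  length_px * pixel_um * kb_per_um
}
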