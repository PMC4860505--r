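test_that("spot detection on a blank channel returns nothing", {
  expect_identical(nrow(detect_spots(matrix(0, 64, 64))), 0L)
})

test_that("well-separated synthetic spots are each detected once", {
  set.seed(2)
  bg <- matrix(rpois(256 * 256, 120), 256, 256)
  sp <- matrix(0, 256, 256)
  sp[100, 80] <- 2500
  sp[100, 80 + 8] <- 2500   # > 3 PSF sigmas away
  sp <- as.matrix(EBImage::gblur(sp, 1.2))
  d <- detect_spots(bg + sp)
  expect_identical(nrow(d), 2L)
  expect_lt(min(abs(d$x - 80)), 1)
  expect_lt(min(abs(d$x - 88)), 1)
  expect_true(all(abs(d$y - 100) < 1))
  expect_true(all(d$snr > 5))
})

test_that("spot counts are monotone non-increasing in the threshold", {
  fx <- fixture_noisy()
  q <- fx$flds$fields[[1]]$channels$qdot
  n <- vapply(c(3, 5, 8, 12), function(k)
    nrow(detect_spots(q, spot_params(threshold_k = k))), integer(1))
  expect_true(all(diff(n) <= 0))
})

test_that("rendered spots are recalled and localized against ground truth", {
  fx <- fixture_noisy()
  truth <- fx$flds$spots
  d <- detect_spots(fx$flds$fields[[1]]$channels$qdot)
  t1 <- truth[truth$field == 1, ]
  hit <- vapply(seq_len(nrow(t1)), function(i)
    any((d$x - t1$x[i])^2 + (d$y - t1$y[i])^2 <= 1), logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("spot assignment respects the distance cutoff and tie rule", {
  mk_poly <- function(y) data.frame(arc_px = 0:100,
                                    x = 10 + 0:100, y = y)
  traces <- structure(list(
    traces = data.frame(trace_id = 1:2, field = 1L,
                        length_px = c(100, 100),
                        length_kb = c(41.44, 41.44),
                        edge_touching = FALSE, n_points = 101L),
    polylines = list(mk_poly(40), mk_poly(60)),
    pixel_um = 0.16, kb_per_um = 2.59), class = "fiber_traces")

  far <- data.frame(x = 50, y = 30, peak_intensity = 500, snr = 10)
  out <- assign_spots_to_fibers(far, traces, max_dist_px = 3)
  expect_identical(nrow(out$signals), 0L)
  expect_identical(out$unassigned, 1L)

  near <- data.frame(x = 50, y = 41, peak_intensity = 500, snr = 10)
  out2 <- assign_spots_to_fibers(near, traces, max_dist_px = 3)
  expect_identical(out2$signals$trace_id, 1L)
  expect_lt(abs(out2$signals$arc_kb - 40 * 0.16 * 2.59), 0.16 * 2.59)

  tie <- data.frame(x = 50, y = 50, peak_intensity = 500, snr = 10)
  out3 <- assign_spots_to_fibers(tie, traces, max_dist_px = 20)
  expect_identical(nrow(out3$signals), 0L)
  expect_identical(out3$ties, 1L)
})

test_that("assigned spots land on the correct fiber at the correct arc", {
  fx <- fixture_noisy()
  kbpx <- 0.16 * 2.59
  is <- fx$flds$fields[[1]]
  tr <- segment_fibers(is)
  ex <- extract_field(is, tr)
  sig <- ex$signals
  truth <- fx$flds$spots[fx$flds$spots$field == 1, ]
  expect_gt(nrow(truth), 5)
  expect_gte(nrow(sig), 0.95 * nrow(truth))
  # at most a couple of noise false positives per field
  expect_lte(nrow(sig), nrow(truth) + 3)
  ok_fiber <- ok_arc <- logical(nrow(truth))
  for (j in seq_len(nrow(truth))) {
    # detected signal matching this ground-truth spot
    d2 <- (sig$x - truth$x[j])^2 + (sig$y - truth$y[j])^2
    i <- which.min(d2)
    if (sqrt(d2[i]) > 1.5) next
    poly <- tr$polylines[[match(sig$trace_id[i], tr$traces$trace_id)]]
    prj <- fiberglow:::point_to_polyline(truth$x[j], truth$y[j], poly)
    # correct fiber: the assigned trace passes through the truth spot
    ok_fiber[j] <- prj$dist <= 2
    # correct arc: assigned position matches the truth projection
    ok_arc[j] <- abs(prj$arc_px * kbpx - sig$arc_kb[i]) <= 1.5 * kbpx
  }
  expect_gte(mean(ok_fiber), 0.95)
  expect_gte(mean(ok_arc), 0.95)
})

test_that("tract segmentation extracts, merges and filters runs", {
  arc <- seq(0.25, 59.75, by = 0.5)
  hi <- 400; lo <- 0
  v <- ifelse((arc < 20) | (arc > 21 & arc < 41), hi, lo)
  prof <- data.frame(arc_kb = arc, idU = v)
  # all below threshold: nothing
  none <- segment_tracts(data.frame(arc_kb = arc, idU = rep(0, length(arc))),
                         tract_params(threshold = 100))
  expect_identical(nrow(none), 0L)
  # two 20-kb runs separated by a 1-kb gap, gap_close 2: one ~41-kb tract
  one <- segment_tracts(prof, tract_params(threshold = 100,
                                           gap_close_kb = 2))
  expect_identical(nrow(one), 1L)
  expect_lt(abs((one$end_kb - one$start_kb) - 41), 0.75)
  # short runs are dropped: a 0.8-kb run against min_tract_kb = 1
  arc_f <- seq(0.05, 59.95, by = 0.1)
  v2 <- ifelse(arc_f > 30 & arc_f < 30.8, hi, lo)
  short <- segment_tracts(data.frame(arc_kb = arc_f, idU = v2),
                          tract_params(threshold = 100, min_tract_kb = 1))
  expect_identical(nrow(short), 0L)
})

test_that("tract segmentation is idempotent on its own output", {
  arc <- seq(0.25, 99.75, by = 0.5)
  set.seed(4)
  v <- ifelse((arc > 10 & arc < 35) | (arc > 36 & arc < 60) |
                (arc > 80 & arc < 83), 400, 0) + rnorm(length(arc), 0, 5)
  par <- tract_params(threshold = 100, gap_close_kb = 2, min_tract_kb = 5)
  iv1 <- segment_tracts(data.frame(arc_kb = arc, idU = v), par)
  # rebuild a profile from the intervals and re-segment
  v2 <- vapply(arc, function(a)
    if (any(a >= iv1$start_kb & a < iv1$end_kb)) 400 else 0, numeric(1))
  iv2 <- segment_tracts(data.frame(arc_kb = arc, idU = v2), par)
  expect_identical(nrow(iv1), nrow(iv2))
  expect_lt(max(abs(iv1$start_kb - iv2$start_kb)), 0.5 + 1e-9)
  expect_lt(max(abs(iv1$end_kb - iv2$end_kb)), 0.5 + 1e-9)
})

test_that("noise-free extraction reproduces per-fiber adduct counts exactly", {
  fx <- fixture_analysis("none")
  rec <- fx$ana$records$records
  truth_counts <- table(factor(fx$pop$adducts$fiber_id,
                               levels = fx$pop$fibers$fiber_id))
  expect_identical(as.integer(sum(rec$n_signals)),
                   as.integer(nrow(fx$pop$adducts)))
  expect_identical(sort(as.integer(table(
    factor(fx$ana$signals$fiber_id, levels = fx$ana$fibers$fiber_id)))),
    sort(as.integer(truth_counts)))
})
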