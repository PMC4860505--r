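test_that("signal fraction counts fibers, not signals", {
  rec <- data.frame(n_signals = rep(c(1L, 0L), c(90L, 710L)))
  fs <- fraction_with_signal(rec)
  expect_equal(fs$fraction, 0.1125)
  expect_identical(fs$n_with_signal, 90L)
  expect_identical(fs$n_fibers, 800L)
  # multi-signal fibers count once
  rec2 <- data.frame(n_signals = c(5L, 0L))
  expect_equal(fraction_with_signal(rec2)$fraction, 0.5)
  expect_equal(fraction_with_signal(data.frame(n_signals = 0L))$fraction, 0)
  expect_equal(fraction_with_signal(data.frame(n_signals = 1:3))$fraction, 1)
  expect_error(fraction_with_signal(data.frame(n_signals = integer(0))),
               "no fiber")
})

test_that("density is total signals per total kb, scaled to 1000 kb", {
  expect_equal(signals_per_1000kb(data.frame(n_signals = 1,
                                             length_kb = 1000)), 1)
  expect_equal(signals_per_1000kb(data.frame(n_signals = c(2, 3),
                                             length_kb = c(800, 1200))), 2.5)
  expect_error(signals_per_1000kb(data.frame(n_signals = 1, length_kb = 0)),
               "length")
})

test_that("inter-adduct distances never span fibers", {
  sig <- data.frame(fiber_id = c(1, 2, 2, 2, 3),
                    arc_kb = c(30, 10, 60, 160, 500))
  d <- interadduct_distances(sig)
  expect_equal(sort(d), c(50, 100))
  expect_identical(interadduct_distances(
    data.frame(fiber_id = 1, arc_kb = 5)), numeric(0))
})

test_that("distances from a homogeneous simulation are exponential in mean", {
  set.seed(30)
  ad <- place_adducts(2e5, 5,
                      accessibility = list(accessible_fraction = 0,
                                           rate_ratio = 1))
  d <- interadduct_distances(data.frame(fiber_id = 1,
                                        arc_kb = ad$position_kb))
  expect_lt(abs(mean(d) - 200) / 200, 0.05)
})

test_that("encounter classification follows the scored categories", {
  # double-sided: tracts abut both sides of the signal
  expect_identical(classify_fiber(
    100, data.frame(start_kb = c(80, 102), end_kb = c(98, 130)), 200,
    adjacency_kb = 3)$category, "DOUBLE_SIDED")
  # no tract at all
  expect_identical(classify_fiber(100, NULL, 200)$category,
                   "SIGNAL_NO_TRACT")
  # tract far from the signal
  expect_identical(classify_fiber(
    100, data.frame(start_kb = 40, end_kb = 70), 200,
    adjacency_kb = 3)$category, "TRACT_DISTANT")
  # one-sided abutment
  expect_identical(classify_fiber(
    100, data.frame(start_kb = 70, end_kb = 100), 200)$category,
    "SINGLE_SIDED")
  # deeply embedded signal counts as replication on both sides
  expect_identical(classify_fiber(
    100, data.frame(start_kb = 60, end_kb = 140), 200)$category,
    "DOUBLE_SIDED")
  # no signals at all
  expect_identical(classify_fiber(numeric(0), NULL, 200)$category,
                   "NO_SIGNAL")
})

test_that("classification agrees with the brute-force oracle on a grid", {
  grid <- seq(0, 100, by = 10)
  sig_sets <- c(lapply(grid[2:10], function(p) p),
                combn(grid[2:10], 2, simplify = FALSE))
  iv <- combn(grid, 2, simplify = FALSE)           # start < end
  tract_sets <- c(list(NULL), lapply(iv, function(v)
    data.frame(start_kb = v[1], end_kb = v[2])))
  # pairs of non-overlapping intervals
  for (i in seq_along(iv)) for (j in seq_along(iv)) {
    if (iv[[i]][2] <= iv[[j]][1])
      tract_sets[[length(tract_sets) + 1L]] <-
        data.frame(start_kb = c(iv[[i]][1], iv[[j]][1]),
                   end_kb = c(iv[[i]][2], iv[[j]][2]))
  }
  n_checked <- 0L
  for (s in sig_sets) for (tr in tract_sets) {
    got <- classify_fiber(s, tr, 100, adjacency_kb = 2)$category
    want <- oracle_classify(s, tr, 100, adjacency_kb = 2)
    if (!identical(got, want))
      fail(sprintf("mismatch: signals %s tracts %s: %s vs %s",
                   paste(s, collapse = ","),
                   paste(sprintf("[%g,%g)", tr$start_kb, tr$end_kb),
                         collapse = " "), got, want))
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 20000)
})

test_that("encounter proportions cover the single/double subset only", {
  rec <- data.frame(
    n_signals = 1L,
    category_uncensored = rep(c("SINGLE_SIDED", "DOUBLE_SIDED",
                                "NO_SIGNAL", "TRACT_DISTANT"),
                              c(19L, 118L, 50L, 10L)))
  ep <- encounter_proportions(rec)
  expect_identical(ep$n, 137L)
  expect_equal(ep$single_fraction, 19 / 137)
  expect_equal(ep$double_fraction, 118 / 137)
  expect_equal(ep$single_fraction + ep$double_fraction, 1)
  all_single <- data.frame(category_uncensored = rep("SINGLE_SIDED", 4))
  expect_equal(encounter_proportions(all_single)$single_fraction, 1)
  few <- data.frame(category_uncensored = rep(c("SINGLE_SIDED",
                                                "DOUBLE_SIDED"), c(1, 3)))
  expect_equal(encounter_proportions(few)$single_fraction, 0.25)
  expect_error(encounter_proportions(
    data.frame(category_uncensored = "NO_SIGNAL")), "single")
})

test_that("ground-truth bypass density is unbiased over seeded runs", {
  dens <- vapply(1:50, function(s) {
    set.seed(4000 + s)
    ad <- place_adducts(6e5, 2.69,
                        accessibility = list(accessible_fraction = 0.3,
                                             rate_ratio = 4))
    nrow(ad) / 6e5 * 1000
  }, numeric(1))
  expect_lt(abs(mean(dens) - 2.69) / 2.69, 0.01)
})

test_that("bypass classification recovers the generator's event labels", {
  cfg <- simulation_config(n_fibers = 150L, seed = 91, adduct_rate = 2)
  pop <- simulate_fibers(cfg)
  rec <- records_from_truth(pop, adjacency_kb = 2)
  # expected per-fiber category from the generator's realized labels
  want <- vapply(pop$fibers$fiber_id, function(id) {
    ad <- pop$adducts[pop$adducts$fiber_id == id, ]
    tr <- pop$tracts[pop$tracts$fiber_id == id & pop$tracts$label == "IdU", ]
    if (nrow(ad) == 0) return("NO_SIGNAL")
    if (nrow(tr) == 0) return("SIGNAL_NO_TRACT")
    if (any(ad$realized == "both")) return("DOUBLE_SIDED")
    if (any(ad$realized %in% c("left", "right"))) return("SINGLE_SIDED")
    "TRACT_DISTANT"
  }, character(1))
  expect_identical(as.character(rec$records$category), want)
})

test_that("experiment summaries partition the fiber set", {
  fx <- fixture_analysis("none")
  rec <- fx$ana$records
  summ <- summarize_experiments(rec)
  cats <- c("NO_SIGNAL", "SIGNAL_NO_TRACT", "TRACT_DISTANT",
            "SINGLE_SIDED", "DOUBLE_SIDED")
  expect_equal(sum(summ[1, cats]), summ$n_fibers[1])
  expect_lte(summ$n_fibers_with_signal[1], summ$n_fibers[1])
  expect_equal(summ$density_per_1000kb[1],
               signals_per_1000kb(rec), tolerance = 1e-12)
})
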