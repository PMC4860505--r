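homog <- list(accessible_fraction = 0, rate_ratio = 1)

test_that("adduct placement follows the configured Poisson process", {
  # zero rate: empty
  set.seed(1)
  expect_identical(nrow(place_adducts(1000, 0)), 0L)
  expect_error(place_adducts(-5, 2), "length_kb")
  expect_error(place_adducts(100, -2), "adduct_rate")

  # homogeneous rate 5 per 1000 kb over 1e6 kb: gaps exponential with
  # mean 200 kb (sample mean within 3%)
  set.seed(42)
  ad <- place_adducts(1e6, 5, accessibility = homog)
  gaps <- diff(ad$position_kb)
  expect_gt(length(gaps), 4000)
  expect_lt(abs(mean(gaps) - 200) / 200, 0.03)

  # positions sorted and in range
  expect_true(!is.unsorted(ad$position_kb))
  expect_true(all(ad$position_kb >= 0 & ad$position_kb <= 1e6))
})

test_that("ICL:monoadduct labelling matches the configured 10:1 ratio", {
  set.seed(7)
  ad <- place_adducts(5e6, 4, accessibility = homog, icl_fraction = 10 / 11)
  expect_gt(nrow(ad), 1e4)
  ratio <- sum(ad$kind == "ICL") / sum(ad$kind == "mono")
  expect_lt(abs(ratio - 10) / 10, 0.05)
})

test_that("two-zone accessibility preserves the length-weighted mean rate", {
  set.seed(11)
  ad <- place_adducts(4e6, 5,
                      accessibility = list(accessible_fraction = 0.3,
                                           rate_ratio = 4))
  dens <- nrow(ad) / 4e6 * 1000
  expect_lt(abs(dens - 5) / 5, 0.02)
  # heterogeneity is real: gap variance exceeds the homogeneous
  # exponential's (mean 200 -> var 4e4)
  gaps <- diff(ad$position_kb)
  expect_gt(var(gaps), 4e4)
})

test_that("homogeneous inter-adduct gaps pass a KS test against the exponential", {
  pass <- 0L
  for (s in 1:20) {
    set.seed(1000 + s)
    ad <- place_adducts(2e5, 5, accessibility = homog)
    gaps <- diff(ad$position_kb)
    p <- suppressWarnings(ks.test(gaps, "pexp", rate = 5 / 1000))$p.value
    pass <- pass + (p > 0.01)
  }
  expect_gte(pass, 19L)
})

test_that("replication events honor the configured encounter model", {
  rep_par <- simulation_config()$replication

  # no encounters configured: no IdU tracts
  set.seed(3)
  ad <- place_adducts(500, 4, accessibility = homog)
  none <- place_replication(500, ad,
                            utils::modifyList(rep_par,
                                              list(encounter_fraction = 0,
                                                   distant_tract_prob = 0)))
  expect_identical(nrow(none$tracts), 0L)

  # single-sided fraction 0.15 over ~1e4 encounters
  set.seed(8)
  par2 <- utils::modifyList(rep_par, list(encounter_fraction = 1,
                                          distant_tract_prob = 0))
  events <- character(0)
  for (i in 1:250) {
    adi <- place_adducts(2500, 20, accessibility = homog)
    out <- place_replication(2500, adi, par2)
    events <- c(events, out$events$event)
  }
  expect_gt(length(events), 1e4)
  frac <- mean(events == "single")
  expect_lt(abs(frac - 0.15), 0.01)

  # double-sided tracts abut the adduct exactly on both sides
  set.seed(9)
  found_double <- FALSE
  for (i in 1:20) {
    adi <- place_adducts(1000, 5, accessibility = homog)
    out <- place_replication(1000, adi, par2)
    both <- which(out$events$realized == "both")
    for (j in both) {
      p <- adi$position_kb[j]
      tr <- out$tracts[out$tracts$linked_adduct == j, ]
      expect_identical(nrow(tr), 2L)
      expect_true(any(abs(tr$end_kb - p) < 1e-9))
      expect_true(any(abs(tr$start_kb - p) < 1e-9))
      found_double <- TRUE
    }
  }
  expect_true(found_double)

  # an adduct at the fiber start cannot be double-sided: degrades and
  # is flagged
  set.seed(10)
  par3 <- utils::modifyList(par2, list(single_sided_prob = 0))
  degr <- place_replication(60, data.frame(position_kb = 0.2,
                                           kind = "ICL"), par3)
  expect_identical(degr$events$realized, "right")
  expect_true(degr$events$degraded)
})

test_that("tracts stop a guard short of foreign adducts", {
  # the free (non-abutting) end of a linked tract keeps neighbor_guard_kb
  # of clearance from every other adduct, and no foreign adduct ever
  # falls inside a tract; adducts that are themselves closer together
  # than the guard are the unavoidable exception at the abutting end
  set.seed(12)
  rep_par <- utils::modifyList(simulation_config()$replication,
                               list(encounter_fraction = 1))
  for (i in 1:10) {
    ad <- place_adducts(2000, 10, accessibility = homog)
    out <- place_replication(2000, ad, rep_par)
    if (!nrow(out$tracts)) next
    for (k in seq_len(nrow(out$tracts))) {
      own <- out$tracts$linked_adduct[k]
      s <- out$tracts$start_kb[k]; e <- out$tracts$end_kb[k]
      others <- if (is.na(own)) ad$position_kb
                else ad$position_kb[-own]
      expect_false(any(others > s + 1e-9 & others < e - 1e-9))
      if (is.na(own)) {
        expect_false(any(others > s - 3 + 1e-9 & others < e + 3 - 1e-9))
      } else {
        p <- ad$position_kb[own]
        free_end <- if (abs(e - p) < 1e-9) s else e
        sgn <- if (abs(e - p) < 1e-9) -1 else 1
        # clearance beyond the free end, in the direction of extension
        lim <- free_end + sgn * 3
        encroach <- if (sgn > 0) others >= e - 1e-9 & others < lim - 1e-9
                    else others <= s + 1e-9 & others > lim + 1e-9
        expect_false(any(encroach))
      }
    }
  }
})

test_that("population simulation is deterministic and calibrated", {
  cfg <- simulation_config(n_fibers = 0L, seed = 1)
  empty <- simulate_fibers(cfg)
  expect_identical(nrow(empty$fibers), 0L)
  expect_identical(nrow(empty$adducts), 0L)

  cfg2 <- simulation_config(n_fibers = 300L, seed = 77, adduct_rate = 2.69)
  pop_a <- simulate_fibers(cfg2)
  pop_b <- simulate_fibers(cfg2)
  expect_identical(pop_a$fibers, pop_b$fibers)
  expect_identical(pop_a$adducts, pop_b$adducts)
  expect_identical(pop_a$tracts, pop_b$tracts)

  # total adduct count within 3 Poisson SDs of rate x length
  tot_kb <- sum(pop_a$fibers$length_kb)
  expected <- 0.00269 * tot_kb
  expect_lt(abs(nrow(pop_a$adducts) - expected), 3 * sqrt(expected))

  # CldU prelabel covers every fiber end to end
  cldu <- pop_a$tracts[pop_a$tracts$label == "CldU", ]
  expect_identical(nrow(cldu), 300L)
  expect_true(all(cldu$start_kb == 0))
  expect_equal(cldu$end_kb[order(cldu$fiber_id)],
               pop_a$fibers$length_kb)
})

test_that("laser mode restricts adducts to the carrier subpopulation", {
  cfg <- simulation_config(n_fibers = 400L, seed = 5,
                           treatment_mode = "laser",
                           laser_fiber_fraction = 0.25)
  pop <- simulate_fibers(cfg)
  carriers <- pop$fibers$fiber_id[pop$fibers$carries_adducts]
  expect_true(all(pop$adducts$fiber_id %in% carriers))
  expect_lt(abs(mean(pop$fibers$carries_adducts) - 0.25), 0.1)
  # per-fiber adduct law on carriers matches the lamp-mode law
  dens <- nrow(pop$adducts) /
    sum(pop$fibers$length_kb[pop$fibers$carries_adducts]) * 1000
  expect_lt(abs(dens - cfg$adduct_rate) / cfg$adduct_rate, 0.25)
})
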