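# Shared fixtures, built in code and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

noise_free_rc <- function(shape = c(512L, 1024L)) {
  render_config(image_shape = shape, background_level = 0,
                read_noise_sd = 0, shot_noise = FALSE)
}

# mid-sized population rendered once, with and without noise; spacing
# between adducts is kept resolvable (low rate) so that detection-level
# equivalence properties have their preconditions met
fixture_cfg <- function(rc, n_fibers = 30L, seed = 101L, rate = 2) {
  simulation_config(
    n_fibers = n_fibers, seed = seed, adduct_rate = rate,
    fiber_length_dist = length_dist(meanlog = log(150), sdlog = 0.3,
                                    min_kb = 60, max_kb = 320),
    render = rc)
}

fixture_noise_free <- function() cached("noise_free", {
  cfg <- fixture_cfg(noise_free_rc(c(1024L, 1024L)))
  pop <- simulate_fibers(cfg)
  flds <- render_images(pop)
  list(cfg = cfg, pop = pop, flds = flds)
})

fixture_noisy <- function() cached("noisy", {
  cfg <- fixture_cfg(render_config(image_shape = c(1024L, 1024L)))
  pop <- simulate_fibers(cfg)
  flds <- render_images(pop)
  list(cfg = cfg, pop = pop, flds = flds)
})

fixture_analysis <- function(noise = c("none", "default")) {
  noise <- match.arg(noise)
  nm <- paste0("analysis_", noise)
  cached(nm, {
    fx <- if (noise == "none") fixture_noise_free() else fixture_noisy()
    ana <- analyze_images(fx$flds, verbosity = 0L)
    c(fx, list(ana = ana))
  })
}

# build a bare imageset from channel matrices (for constructed fixtures)
make_imageset <- function(channels, pixel_um = 0.16, kb_per_um = 2.59) {
  rc <- render_config(pixel_um = pixel_um, kb_per_um = kb_per_um,
                      image_shape = dim(channels[[1]]))
  fiberglow:::new_imageset(channels, rc)
}

# draw a straight line of given intensity into a matrix
draw_line <- function(m, r0, c0, r1, c1, value = 300) {
  n <- max(abs(r1 - r0), abs(c1 - c0)) * 2 + 1
  rr <- round(seq(r0, r1, length.out = n))
  cc <- round(seq(c0, c1, length.out = n))
  m[unique(cbind(rr, cc))] <- value
  m
}

# independent brute-force encounter classifier: literal per-signal,
# per-tract loops over the category definition (two-sided adjacency
# windows, deep embedding counts both sides)
oracle_classify <- function(signals_kb, tracts, length_kb, adjacency_kb = 2) {
  if (length(signals_kb) == 0) return("NO_SIGNAL")
  if (is.null(tracts) || nrow(tracts) == 0) return("SIGNAL_NO_TRACT")
  level <- 0 # 0 distant, 1 single, 2 double
  for (p in signals_kb) {
    left <- FALSE; right <- FALSE
    for (k in seq_len(nrow(tracts))) {
      s <- tracts$start_kb[k]; e <- tracts$end_kb[k]
      if (s < p - adjacency_kb && e > p + adjacency_kb) {
        left <- TRUE; right <- TRUE
      }
      if (p - adjacency_kb <= e && e <= p + adjacency_kb) left <- TRUE
      if (p - adjacency_kb <= s && s <= p + adjacency_kb) right <- TRUE
    }
    lv <- if (left && right) 2 else if (left || right) 1 else 0
    level <- max(level, lv)
  }
  c("TRACT_DISTANT", "SINGLE_SIDED", "DOUBLE_SIDED")[level + 1]
}
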