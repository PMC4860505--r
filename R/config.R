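#' Rendering configuration
#'
#' Parameters controlling how ground-truth fibers are drawn as
#' multi-channel fluorescence images.
#'
#' @param pixel_um Pixel size in micrometres per pixel. Default 0.16.
#' @param kb_per_um Stretching constant of spread fibers, kilobases per
#'   micrometre of image. Default 2.59, the widely used value for
#'   conventionally spread fibers; every kb-denominated output depends on
#'   it, so it is recorded in all output headers.
#' @param psf_sigma_px Gaussian point-spread-function sigma in pixels.
#' @param background_level Mean background intensity (counts).
#' @param read_noise_sd Gaussian read-noise standard deviation (counts).
#' @param shot_noise Apply Poisson photon noise to signal + background.
#' @param photon_gain Counts per photon used by the shot-noise model.
#' @param image_shape Image size in pixels, \code{c(rows, cols)}.
#' @param channel_gains Named intensity scales for the three channels:
#'   \code{cldU} and \code{idU} are counts deposited per pixel of fiber
#'   path length before blurring; \code{qdot} is the integrated intensity
#'   of one quantum-dot spot.
#' @param lane_height_px,lane_gap_px Layout: vertical lane height per
#'   fiber row and horizontal gap between fibers sharing a lane.
#' @param margin_px Border margin kept free of fibers.
#'
#' @return An object of class \code{render_config} (a validated list).
#' @export
#' @examples
#' render_config(psf_sigma_px = 1.0)
render_config <- function(pixel_um = 0.16,
                          kb_per_um = 2.59,
                          psf_sigma_px = 1.2,
                          background_level = 120,
                          read_noise_sd = 6,
                          shot_noise = TRUE,
                          photon_gain = 1,
                          image_shape = c(2048L, 2048L),
                          channel_gains = c(cldU = 900, idU = 900, qdot = 2500),
                          lane_height_px = 16,
                          lane_gap_px = 30,
                          margin_px = 12) {
  rc <- list(pixel_um = pixel_um, kb_per_um = kb_per_um,
             psf_sigma_px = psf_sigma_px,
             background_level = background_level,
             read_noise_sd = read_noise_sd, shot_noise = shot_noise,
             photon_gain = photon_gain,
             image_shape = as.integer(image_shape),
             channel_gains = channel_gains,
             lane_height_px = lane_height_px, lane_gap_px = lane_gap_px,
             margin_px = margin_px)
  class(rc) <- "render_config"
  validate_render_config(rc)
}

validate_render_config <- function(rc) {
  if (!is.numeric(rc$pixel_um) || rc$pixel_um <= 0)
    stop("configuration error: pixel_um must be > 0", call. = FALSE)
  if (!is.numeric(rc$kb_per_um) || rc$kb_per_um <= 0)
    stop("configuration error: kb_per_um must be > 0", call. = FALSE)
  if (rc$psf_sigma_px < 0)
    stop("configuration error: psf_sigma_px must be >= 0", call. = FALSE)
  if (rc$background_level < 0 || rc$read_noise_sd < 0 || rc$photon_gain <= 0)
    stop("configuration error: noise parameters must be non-negative (gain > 0)",
         call. = FALSE)
  if (length(rc$image_shape) != 2L || any(rc$image_shape < 64L))
    stop("configuration error: image_shape must be two dimensions >= 64 px",
         call. = FALSE)
  needed <- c("cldU", "idU", "qdot")
  if (!all(needed %in% names(rc$channel_gains)))
    stop("configuration error: channel_gains must name cldU, idU and qdot",
         call. = FALSE)
  rc
}

# kb of fiber represented by one pixel of arc
kb_per_px <- function(rc) rc$pixel_um * rc$kb_per_um

#' Distribution specification for simulated lengths
#'
#' A small helper describing the fiber- and tract-length laws used by the
#' generator. Lognormal draws are truncated by resampling, which leaves
#' per-kb adduct densities unbiased.
#'
#' @param kind Distribution family: \code{"lognormal"} or \code{"fixed"}.
#' @param meanlog,sdlog Lognormal parameters (log-kb scale).
#' @param value_kb Length for \code{kind = "fixed"}.
#' @param min_kb,max_kb Truncation bounds in kb (resampled outside).
#' @return A \code{length_dist} list.
#' @export
length_dist <- function(kind = c("lognormal", "fixed"),
                        meanlog = log(280), sdlog = 0.45,
                        value_kb = 300, min_kb = 1, max_kb = Inf) {
  kind <- match.arg(kind)
  d <- list(kind = kind, meanlog = meanlog, sdlog = sdlog,
            value_kb = value_kb, min_kb = min_kb, max_kb = max_kb)
  if (d$min_kb <= 0 || d$max_kb <= d$min_kb && kind != "fixed")
    stop("configuration error: length bounds must satisfy 0 < min < max",
         call. = FALSE)
  class(d) <- "length_dist"
  d
}

draw_lengths <- function(dist, n) {
  if (n == 0L) return(numeric(0))
  if (dist$kind == "fixed") return(rep(dist$value_kb, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rlnorm(n, dist$meanlog, dist$sdlog)
    x <- x[x >= dist$min_kb & x <= dist$max_kb]
    out <- c(out, x)
  }
  out[seq_len(n)]
}

#' Simulation configuration
#'
#' Describes one simulated fiber-assay experiment: how many fibers, their
#' length law, the adduct placement process, the replication model and
#' the treatment scenario.
#'
#' @param n_fibers Number of fibers to generate.
#' @param fiber_length_dist A [length_dist()]; default lognormal with
#'   mean about 300 kb truncated to 30--700 kb.
#' @param adduct_rate Expected adducts per 1000 kb of fiber (the density
#'   the assay estimates; 2.69 is the calibration for the lower-dose
#'   condition, 4.48 for the higher dose).
#' @param icl_fraction Probability an adduct is an interstrand crosslink
#'   rather than a monoadduct. Default 10/11 (a 10:1 ICL:monoadduct
#'   ratio).
#' @param accessibility Two-zone chromatin accessibility model:
#'   \code{accessible_fraction} of each fiber's length reacts at
#'   \code{rate_ratio} times the rate of the rest, with the
#'   length-weighted mean rate pinned to \code{adduct_rate}. A
#'   \code{rate_ratio} of 1 gives a homogeneous Poisson process.
#' @param replication Replication-encounter model:
#'   \code{encounter_fraction} (probability an adduct has an adjacent
#'   replication event), \code{single_sided_prob} (probability that event
#'   is one-sided; default 0.15), \code{tract_length_dist} (a
#'   [length_dist()] for IdU tract lengths), \code{distant_tract_prob}
#'   (probability per fiber of an additional tract unlinked to any
#'   adduct) and \code{neighbor_guard_kb} (tracts never approach a
#'   foreign adduct closer than this).
#' @param treatment_mode \code{"lamp"} (whole-population UVA exposure:
#'   every fiber can carry adducts) or \code{"laser"} (region-of-interest
#'   photoactivation: only \code{laser_fiber_fraction} of fibers carry
#'   adducts, with the same per-fiber adduct law).
#' @param laser_fiber_fraction Fraction of fibers carrying adducts in
#'   laser mode.
#' @param render A [render_config()].
#' @param seed Integer seed; all stochastic draws flow from it.
#' @param origin_label Experiment/replicate identifier stamped on output.
#'
#' @return An object of class \code{sim_config}.
#' @export
#' @examples
#' cfg <- simulation_config(n_fibers = 10, seed = 7)
#' cfg$adduct_rate
simulation_config <- function(n_fibers = 300L,
                              fiber_length_dist = length_dist(min_kb = 30, max_kb = 700),
                              adduct_rate = 2.69,
                              icl_fraction = 10 / 11,
                              accessibility = list(accessible_fraction = 0.3,
                                                   rate_ratio = 4),
                              replication = list(
                                encounter_fraction = 0.5,
                                single_sided_prob = 0.15,
                                tract_length_dist = length_dist(
                                  meanlog = log(35), sdlog = 0.35,
                                  min_kb = 4, max_kb = 150),
                                distant_tract_prob = 0.2,
                                neighbor_guard_kb = 3),
                              treatment_mode = c("lamp", "laser"),
                              laser_fiber_fraction = 0.25,
                              render = render_config(),
                              seed = 1L,
                              origin_label = NULL) {
  treatment_mode <- match.arg(treatment_mode)
  if (is.null(origin_label)) origin_label <- treatment_mode
  cfg <- list(n_fibers = as.integer(n_fibers),
              fiber_length_dist = fiber_length_dist,
              adduct_rate = adduct_rate,
              icl_fraction = icl_fraction,
              accessibility = accessibility,
              replication = replication,
              treatment_mode = treatment_mode,
              laser_fiber_fraction = laser_fiber_fraction,
              render = render,
              seed = as.integer(seed),
              origin_label = origin_label)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop("configuration error: ", nm, " must be a probability in [0, 1]",
           call. = FALSE)
  }
  if (cfg$n_fibers < 0L)
    stop("configuration error: n_fibers must be >= 0", call. = FALSE)
  if (!is.numeric(cfg$adduct_rate) || cfg$adduct_rate < 0)
    stop("configuration error: adduct_rate must be >= 0", call. = FALSE)
  chk_prob(cfg$icl_fraction, "icl_fraction")
  chk_prob(cfg$accessibility$accessible_fraction, "accessible_fraction")
  if (cfg$accessibility$rate_ratio <= 0)
    stop("configuration error: rate_ratio must be > 0", call. = FALSE)
  chk_prob(cfg$replication$encounter_fraction, "encounter_fraction")
  chk_prob(cfg$replication$single_sided_prob, "single_sided_prob")
  chk_prob(cfg$replication$distant_tract_prob, "distant_tract_prob")
  chk_prob(cfg$laser_fiber_fraction, "laser_fiber_fraction")
  if (cfg$replication$neighbor_guard_kb < 0)
    stop("configuration error: neighbor_guard_kb must be >= 0", call. = FALSE)
  validate_render_config(cfg$render)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Fiber simulation configuration\n")
  cat(sprintf("  fibers:        %d (%s mode, label '%s')\n",
              x$n_fibers, x$treatment_mode, x$origin_label))
  cat(sprintf("  adduct rate:   %.3f per 1000 kb (ICL fraction %.3f)\n",
              x$adduct_rate, x$icl_fraction))
  cat(sprintf("  accessibility: %.0f%% of length at %.1fx rate\n",
              100 * x$accessibility$accessible_fraction,
              x$accessibility$rate_ratio))
  cat(sprintf("  replication:   encounter %.2f, single-sided %.2f\n",
              x$replication$encounter_fraction,
              x$replication$single_sided_prob))
  cat(sprintf("  calibration:   %.2f um/px, %.2f kb/um\n",
              x$render$pixel_um, x$render$kb_per_um))
  cat(sprintf("  seed:          %d\n", x$seed))
  invisible(x)
}

## ---- YAML configuration ----------------------------------------------------

known_keys <- list(
  top = c("n_fibers", "fiber_length_dist", "adduct_rate", "icl_fraction",
          "accessibility", "replication", "treatment_mode",
          "laser_fiber_fraction", "render", "seed", "origin_label"),
  dist = c("kind", "meanlog", "sdlog", "value_kb", "min_kb", "max_kb", "mean_kb"),
  accessibility = c("accessible_fraction", "rate_ratio"),
  replication = c("encounter_fraction", "single_sided_prob",
                  "tract_length_dist", "distant_tract_prob",
                  "neighbor_guard_kb"),
  render = c("pixel_um", "kb_per_um", "psf_sigma_px", "background_level",
             "read_noise_sd", "shot_noise", "photon_gain", "image_shape",
             "channel_gains", "lane_height_px", "lane_gap_px", "margin_px"))

reject_unknown <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("configuration error: unknown key(s) in ", where, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  x
}

dist_from_list <- function(x, where) {
  reject_unknown(x, known_keys$dist, where)
  # mean_kb is YAML sugar for the lognormal median-free mean
  if (!is.null(x$mean_kb) && is.null(x$meanlog)) {
    sdlog <- if (is.null(x$sdlog)) 0.45 else x$sdlog
    x$meanlog <- log(x$mean_kb) - sdlog^2 / 2
    x$sdlog <- sdlog
    x$mean_kb <- NULL
  }
  do.call(length_dist, x)
}

#' Read a simulation configuration from YAML
#'
#' Unknown keys anywhere in the file are rejected with an error, so a
#' typo cannot silently fall back to a default.
#'
#' @param path Path to a YAML file with the [simulation_config()] schema.
#' @return A validated \code{sim_config}.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  reject_unknown(y, known_keys$top, "configuration")
  if (!is.null(y$fiber_length_dist))
    y$fiber_length_dist <- dist_from_list(y$fiber_length_dist, "fiber_length_dist")
  if (!is.null(y$accessibility))
    reject_unknown(y$accessibility, known_keys$accessibility, "accessibility")
  if (!is.null(y$replication)) {
    reject_unknown(y$replication, known_keys$replication, "replication")
    if (!is.null(y$replication$tract_length_dist))
      y$replication$tract_length_dist <-
        dist_from_list(y$replication$tract_length_dist, "tract_length_dist")
  }
  if (!is.null(y$render)) {
    reject_unknown(y$render, known_keys$render, "render")
    if (!is.null(y$render$channel_gains))
      y$render$channel_gains <- unlist(y$render$channel_gains)
    y$render <- do.call(render_config, y$render)
  }
  # merge partial sub-lists over defaults
  defaults <- simulation_config()
  for (nm in c("accessibility", "replication"))
    if (!is.null(y[[nm]]))
      y[[nm]] <- utils::modifyList(defaults[[nm]], y[[nm]])
  do.call(simulation_config, y)
}

# short hash identifying a configuration (manifest + provenance metadata)
config_hash <- function(cfg) {
  canon <- jsonlite::toJSON(unclass_all(cfg), auto_unbox = TRUE, digits = NA)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(canon), f)
  unname(tools::md5sum(f))
}

unclass_all <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_all) else unclass(x)
}
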