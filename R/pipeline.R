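## End-to-end pipeline: simulate -> render -> trace -> extract ->
## quantify -> stats, with CSV outputs, logging and a run manifest.

log_msg <- function(level, ..., verbosity = 1L) {
  lvl <- c(error = 0L, warn = 1L, info = 1L, debug = 2L)[[level]]
  if (verbosity >= lvl)
    message(sprintf("[%s] %s", toupper(level), paste0(...)))
}

#' Write a pipeline CSV with a units/calibration header
#'
#' All tabular outputs share one dialect: comma-separated, UTF-8, "."
#' decimal, kb to three decimals, preceded by a single \code{#} comment
#' line recording units and the calibration constants in force.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param rc A [render_config()] supplying the calibration constants.
#' @return \code{path}, invisibly.
#' @export
write_fiber_csv <- function(df, path, rc = render_config()) {
  num <- vapply(df, is.numeric, logical(1))
  for (nm in names(df)[num])
    if (grepl("_kb$|_px$|density", nm)) df[[nm]] <- round(df[[nm]], 3)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf(
    "# units: kb (kilobases), px (pixels); pixel_um=%g; kb_per_um=%g",
    rc$pixel_um, rc$kb_per_um), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline CSV written by [write_fiber_csv()]
#' @param path CSV path.
#' @return Data frame (the comment header is skipped).
#' @export
read_fiber_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

manifest_entry <- function(paths) {
  ex <- paths[file.exists(paths)]
  as.list(tools::md5sum(ex))
}

#' Analyze rendered fields from the images alone
#'
#' Runs tracing, spot detection/assignment and tract segmentation on a
#' list of image fields and assembles per-fiber records. Edge-touching
#' traces are excluded. This is the imaging arm of the pipeline; the
#' renderer's ground truth is not consulted.
#'
#' @param fields A \code{fiber_fields} object from [render_images()], or
#'   a list of \code{fiber_imageset}s.
#' @param trace_par,spot_par,tract_par,max_dist_px Stage parameters.
#' @param adjacency_kb Classification adjacency tolerance.
#' @param origin_label Experiment label stamped on the records.
#' @param verbosity Logging level.
#' @return List with \code{records} (a [fiber_records()] object over all
#'   fields), \code{fibers}, \code{signals}, \code{tracts} data frames,
#'   and counters \code{crossing_count}, \code{unassigned}, \code{ties}.
#' @export
analyze_images <- function(fields, trace_par = trace_params(),
                           spot_par = spot_params(),
                           tract_par = tract_params(), max_dist_px = 3,
                           adjacency_kb = 2,
                           origin_label = "experiment", verbosity = 1L) {
  if (inherits(fields, "fiber_fields")) fields <- fields$fields
  if (inherits(fields, "fiber_imageset")) fields <- list(fields)
  fib_l <- sig_l <- trc_l <- list()
  offset <- 0L
  crossing <- unassigned <- ties <- 0L
  for (f in seq_along(fields)) {
    log_msg("info", "tracing field ", f, "/", length(fields),
            verbosity = verbosity)
    tr <- segment_fibers(fields[[f]], trace_par)
    ex <- extract_field(fields[[f]], tr, spot_par, tract_par, max_dist_px)
    crossing <- crossing + tr$crossing_count
    unassigned <- unassigned + ex$unassigned
    ties <- ties + ex$ties
    if (!nrow(tr$traces)) next
    keep_ids <- tr$traces$trace_id[!tr$traces$edge_touching]
    fib <- data.frame(fiber_id = tr$traces$trace_id + offset,
                      length_kb = tr$traces$length_kb,
                      origin_label = rep(origin_label, nrow(tr$traces)),
                      stringsAsFactors = FALSE)
    fib <- fib[tr$traces$trace_id %in% keep_ids, , drop = FALSE]
    sig <- ex$signals
    sig$fiber_id <- sig$trace_id + offset
    trc <- ex$tracts
    trc$fiber_id <- trc$trace_id + offset
    fib_l[[f]] <- fib
    sig_l[[f]] <- sig[sig$fiber_id %in% fib$fiber_id, , drop = FALSE]
    trc_l[[f]] <- trc[trc$fiber_id %in% fib$fiber_id, , drop = FALSE]
    offset <- offset + if (nrow(tr$traces)) max(tr$traces$trace_id) else 0L
  }
  fibers <- do.call(rbind, fib_l)
  signals <- do.call(rbind, sig_l)
  tracts <- do.call(rbind, trc_l)
  if (is.null(fibers))
    fibers <- data.frame(fiber_id = integer(0), length_kb = numeric(0),
                         origin_label = character(0))
  if (is.null(signals))
    signals <- data.frame(trace_id = integer(0), fiber_id = integer(0),
                          arc_kb = numeric(0), x = numeric(0),
                          y = numeric(0), peak_intensity = numeric(0),
                          snr = numeric(0))
  if (is.null(tracts))
    tracts <- data.frame(trace_id = integer(0), fiber_id = integer(0),
                         start_kb = numeric(0), end_kb = numeric(0),
                         mean_intensity = numeric(0))
  recs <- fiber_records(fibers, signals, tracts, adjacency_kb)
  list(records = recs, fibers = fibers, signals = signals,
       tracts = tracts, crossing_count = crossing,
       unassigned = unassigned, ties = ties)
}

#' Run the full fiber-assay pipeline
#'
#' Simulates a ground-truth population, optionally renders and
#' re-analyzes it from images (tracing, spot detection, tract
#' segmentation), quantifies per-fiber records and per-experiment
#' summaries, runs the encounter-proportion z test, and writes all
#' outputs plus a JSON manifest with file checksums.
#'
#' With \code{bypass_imaging = TRUE} the simulator's ground truth is fed
#' straight to quantification: the validation mode that isolates the
#' imaging stages' error.
#'
#' @param cfg A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @param bypass_imaging Skip rendering/detection and quantify ground
#'   truth directly.
#' @param write_tiff Write the rendered fields as 16-bit TIFFs (imaging
#'   mode only).
#' @param adjacency_kb Classification adjacency tolerance.
#' @param verbosity 0 = quiet, 1 = normal, 2 = verbose.
#' @return Invisibly, a list with \code{records},
#'   \code{summary}, \code{tests}, \code{population} and the
#'   \code{manifest} (also written as \code{manifest.json}).
#' @export
#' @examples
#' \donttest{
#' cfg <- simulation_config(n_fibers = 15, seed = 5,
#'   fiber_length_dist = length_dist(kind = "fixed", value_kb = 150),
#'   render = render_config(image_shape = c(512L, 512L)))
#' res <- run_pipeline(cfg, tempfile("run"), bypass_imaging = TRUE)
#' res$summary
#' }
run_pipeline <- function(cfg, out_dir, bypass_imaging = FALSE,
                         write_tiff = TRUE, adjacency_kb = 2,
                         verbosity = 1L) {
  cfg <- validate_sim_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rc <- cfg$render
  stage <- "simulate"
  res <- tryCatch({
    log_msg("info", "simulating ", cfg$n_fibers, " fibers (seed ",
            cfg$seed, ")", verbosity = verbosity)
    pop <- simulate_fibers(cfg)
    write_fiber_csv(pop$fibers[, c("fiber_id", "length_kb", "origin_label")],
                    file.path(out_dir, "ground_truth_fibers.csv"), rc)
    write_fiber_csv(pop$adducts,
                    file.path(out_dir, "ground_truth_adducts.csv"), rc)
    write_fiber_csv(pop$tracts,
                    file.path(out_dir, "ground_truth_tracts.csv"), rc)

    if (cfg$n_fibers == 0L) {
      log_msg("info", "zero fibers: stats stage skipped",
              verbosity = verbosity)
      recs <- fiber_records(pop$fibers,
                            data.frame(fiber_id = integer(0),
                                       arc_kb = numeric(0)),
                            data.frame(fiber_id = integer(0),
                                       start_kb = numeric(0),
                                       end_kb = numeric(0)),
                            adjacency_kb)
      summ <- data.frame(experiment_label = cfg$origin_label,
                         n_fibers = 0L, n_fibers_with_signal = 0L,
                         total_length_kb = 0, n_signals = 0L,
                         density_per_1000kb = NA_real_)
      tests <- data.frame(method = character(0), statistic = numeric(0),
                          df = numeric(0), p_value = numeric(0))
    } else if (bypass_imaging) {
      stage <- "quantify"
      log_msg("info", "bypassing imaging: quantifying ground truth",
              verbosity = verbosity)
      recs <- records_from_truth(pop, adjacency_kb)
      summ <- summarize_experiments(recs)
      tests <- pipeline_tests(recs, verbosity)
    } else {
      stage <- "render"
      log_msg("info", "rendering fields", verbosity = verbosity)
      flds <- render_images(pop, rc)
      if (write_tiff) {
        for (f in seq_along(flds$fields))
          write_imageset(flds$fields[[f]],
                         file.path(out_dir, sprintf("field_%03d.tif", f)))
      }
      stage <- "trace/extract"
      ana <- analyze_images(flds, adjacency_kb = adjacency_kb,
                            origin_label = cfg$origin_label,
                            verbosity = verbosity)
      write_fiber_csv(ana$fibers, file.path(out_dir, "fibers.csv"), rc)
      write_fiber_csv(ana$signals[, c("fiber_id", "arc_kb",
                                      "peak_intensity", "snr")],
                      file.path(out_dir, "signals.csv"), rc)
      write_fiber_csv(ana$tracts[, c("fiber_id", "start_kb", "end_kb",
                                     "mean_intensity")],
                      file.path(out_dir, "tracts.csv"), rc)
      stage <- "quantify"
      recs <- ana$records
      summ <- summarize_experiments(recs)
      tests <- pipeline_tests(recs, verbosity)
    }
    stage <- "write"
    write_fiber_csv(recs$records, file.path(out_dir, "records.csv"), rc)
    write_fiber_csv(summ, file.path(out_dir, "summary.csv"), rc)
    write_fiber_csv(tests, file.path(out_dir, "tests.csv"), rc)
    list(population = pop, records = recs, summary = summ, tests = tests)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         " (partial outputs preserved in ", out_dir, ")", call. = FALSE)
  })

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(package_version = as.character(packageVersion("fiberglow")),
                   config_hash = config_hash(cfg),
                   seed = cfg$seed,
                   bypass_imaging = bypass_imaging,
                   adjacency_kb = adjacency_kb,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   outputs = manifest_entry(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

pipeline_tests <- function(recs, verbosity = 1L) {
  rows <- list()
  ep <- tryCatch(encounter_proportions(recs), error = function(e) NULL)
  if (is.null(ep)) {
    log_msg("info", "no single/double-sided fibers: z test skipped",
            verbosity = verbosity)
  } else {
    zt <- two_proportion_z(ep$n_single, ep$n_double)
    rows[[1]] <- data.frame(method = zt$method, statistic = zt$statistic,
                            df = NA_real_, p_value = zt$p_value)
  }
  labs <- unique(records_df(recs)$experiment_label)
  if (length(labs) == 2L) {
    sig <- recs$signals
    rdf <- records_df(recs)
    d <- lapply(labs, function(l)
      interadduct_distances(sig[sig$fiber_id %in%
                                  rdf$fiber_id[rdf$experiment_label == l], ,
                                drop = FALSE]))
    if (all(lengths(d) > 0)) {
      ks <- compare_spacing(d[[1]], d[[2]])
      rows[[length(rows) + 1L]] <-
        data.frame(method = ks$method, statistic = ks$statistic,
                   df = NA_real_, p_value = ks$p_value)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(method = character(0), statistic = numeric(0),
               df = numeric(0), p_value = numeric(0))
}
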