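## Quantification: per-fiber records, signal fractions, densities per
## 1000 kb, inter-adduct distances, and the four-way classification of
## replication-fork encounters with adducts.

fiber_categories <- c("NO_SIGNAL", "SIGNAL_NO_TRACT", "TRACT_DISTANT",
                      "SINGLE_SIDED", "DOUBLE_SIDED")

#' Classify one fiber's replication-encounter pattern
#'
#' Mirrors the visual scoring of fiber images: a fiber with no
#' quantum-dot signal is \code{NO_SIGNAL}; with signals but no
#' replication tract, \code{SIGNAL_NO_TRACT}; otherwise each signal is
#' scored against the tract set. A tract is adjacent on the left of a
#' signal at position p if its end lies within \code{adjacency_kb} of p
#' (on either side: a detected tract boundary may overshoot the adduct
#' by a blur-sized amount), and symmetrically on the right via tract
#' starts; a signal lying more than \code{adjacency_kb} inside a tract
#' (a deeply embedded signal) has replication on both sides. Both sides
#' adjacent gives \code{DOUBLE_SIDED}, exactly one \code{SINGLE_SIDED};
#' a fiber whose tracts are never adjacent to any signal is
#' \code{TRACT_DISTANT}. The fiber-level category is the most advanced
#' state over its signals (DOUBLE > SINGLE > DISTANT).
#'
#' Signals within \code{adjacency_kb} of a fiber end cannot be scored
#' double-sided; they are flagged end-censored, and
#' [encounter_proportions()] excludes them by default.
#'
#' @param signals_kb Sorted numeric vector of signal arc positions (kb).
#' @param tracts Data frame of IdU intervals (\code{start_kb},
#'   \code{end_kb}, half-open).
#' @param length_kb Fiber length in kb.
#' @param adjacency_kb Adjacency tolerance in kb (default 2, about five
#'   pixels at the default calibration).
#' @return List with \code{category}, per-signal \code{signal_category},
#'   \code{end_censored} flags, and \code{category_uncensored} (the
#'   fiber category recomputed over non-censored signals only,
#'   \code{NA} if none remain).
#' @export
#' @examples
#' classify_fiber(100, data.frame(start_kb = 80, end_kb = 98), 200)$category
classify_fiber <- function(signals_kb, tracts, length_kb,
                           adjacency_kb = 2) {
  signals_kb <- sort(signals_kb)
  n <- length(signals_kb)
  if (n == 0L)
    return(list(category = "NO_SIGNAL", signal_category = character(0),
                end_censored = logical(0), category_uncensored = NA_character_))
  if (is.null(tracts) || nrow(tracts) == 0L)
    return(list(category = "SIGNAL_NO_TRACT",
                signal_category = rep("SIGNAL_NO_TRACT", n),
                end_censored = rep(FALSE, n),
                category_uncensored = "SIGNAL_NO_TRACT"))
  per <- character(n)
  cens <- logical(n)
  for (i in seq_len(n)) {
    p <- signals_kb[i]
    embedded <- any(tracts$start_kb < p - adjacency_kb &
                      tracts$end_kb > p + adjacency_kb)
    left <- embedded | any(abs(tracts$end_kb - p) <= adjacency_kb)
    right <- embedded | any(abs(tracts$start_kb - p) <= adjacency_kb)
    per[i] <- if (left && right) "DOUBLE_SIDED"
              else if (left || right) "SINGLE_SIDED"
              else "TRACT_DISTANT"
    cens[i] <- p < adjacency_kb || p > length_kb - adjacency_kb
  }
  rank_of <- function(x) match(x, c("TRACT_DISTANT", "SINGLE_SIDED",
                                    "DOUBLE_SIDED"))
  best <- function(cats) c("TRACT_DISTANT", "SINGLE_SIDED",
                           "DOUBLE_SIDED")[max(rank_of(cats))]
  unc <- per[!cens]
  list(category = best(per), signal_category = per, end_censored = cens,
       category_uncensored = if (length(unc)) best(unc) else NA_character_)
}

#' Build per-fiber records from signals and tracts
#'
#' Joins a fiber table (detected traces or ground truth) with its
#' signals and IdU tract intervals and classifies every fiber.
#'
#' @param fibers Data frame with \code{fiber_id}, \code{length_kb} and
#'   optionally \code{origin_label}.
#' @param signals Data frame with \code{fiber_id} and \code{arc_kb}.
#' @param tracts Data frame with \code{fiber_id}, \code{start_kb},
#'   \code{end_kb}.
#' @param adjacency_kb Adjacency tolerance passed to [classify_fiber()].
#' @param experiment_label Label used when \code{fibers} has none.
#' @return An object of class \code{fiber_records}: \code{records} data
#'   frame (\code{fiber_id}, \code{experiment_label}, \code{length_kb},
#'   \code{n_signals}, \code{n_idu_tracts}, \code{category},
#'   \code{category_uncensored}), plus the \code{signals} and
#'   \code{tracts} tables and \code{adjacency_kb}.
#' @export
fiber_records <- function(fibers, signals, tracts, adjacency_kb = 2,
                          experiment_label = "experiment") {
  lab <- if ("origin_label" %in% names(fibers)) fibers$origin_label
         else rep(experiment_label, nrow(fibers))
  n <- nrow(fibers)
  cat_v <- cat_u <- character(n)
  nsig <- ntr <- integer(n)
  for (i in seq_len(n)) {
    id <- fibers$fiber_id[i]
    s <- signals$arc_kb[signals$fiber_id == id]
    tr <- tracts[tracts$fiber_id == id, , drop = FALSE]
    cl <- classify_fiber(s, tr, fibers$length_kb[i], adjacency_kb)
    cat_v[i] <- cl$category
    cat_u[i] <- if (is.na(cl$category_uncensored)) cl$category
                else cl$category_uncensored
    nsig[i] <- length(s)
    ntr[i] <- nrow(tr)
  }
  records <- data.frame(fiber_id = fibers$fiber_id,
                        experiment_label = lab,
                        length_kb = fibers$length_kb,
                        n_signals = nsig, n_idu_tracts = ntr,
                        category = factor(cat_v, levels = fiber_categories),
                        category_uncensored =
                          factor(cat_u, levels = fiber_categories),
                        stringsAsFactors = FALSE)
  structure(list(records = records, signals = signals, tracts = tracts,
                 adjacency_kb = adjacency_kb),
            class = "fiber_records")
}

#' Ground-truth bypass: records straight from a simulated population
#'
#' Feeds the simulator's ground truth (adduct positions as signals, IdU
#' tracts as intervals) directly to quantification, skipping rendering
#' and detection. This is the validation mode: differences between a
#' bypass run and a full imaging run isolate detection error.
#'
#' @param pop A [simulate_fibers()] population.
#' @param adjacency_kb Adjacency tolerance.
#' @return A \code{fiber_records} object.
#' @export
records_from_truth <- function(pop, adjacency_kb = 2) {
  signals <- data.frame(fiber_id = pop$adducts$fiber_id,
                        arc_kb = pop$adducts$position_kb)
  idu <- pop$tracts[pop$tracts$label == "IdU",
                    c("fiber_id", "start_kb", "end_kb")]
  fiber_records(pop$fibers, signals, idu, adjacency_kb)
}

#' @export
print.fiber_records <- function(x, ...) {
  r <- x$records
  cat(sprintf("Fiber records: %d fibers, %d signals, %d IdU tracts\n",
              nrow(r), sum(r$n_signals), sum(r$n_idu_tracts)))
  print(table(r$category))
  invisible(x)
}

#' @export
summary.fiber_records <- function(object, ...) {
  r <- object$records
  print(object)
  if (nrow(r)) {
    fs <- fraction_with_signal(object)
    cat(sprintf("  fraction with signal: %.4f (%d / %d)\n",
                fs$fraction, fs$n_with_signal, fs$n_fibers))
    cat(sprintf("  density: %.3f signals per 1000 kb over %.0f kb\n",
                signals_per_1000kb(object), sum(r$length_kb)))
    ep <- tryCatch(encounter_proportions(object), error = function(e) NULL)
    if (!is.null(ep))
      cat(sprintf("  encounters: single %.3f, double %.3f (n = %d)\n",
                  ep$single_fraction, ep$double_fraction, ep$n))
  }
  invisible(object)
}

records_df <- function(records) {
  if (inherits(records, "fiber_records")) records$records else records
}

#' Fraction of fibers carrying at least one signal
#'
#' A fiber with multiple signals counts once: this counts fibers, not
#' signals.
#'
#' @param records A \code{fiber_records} object, or a data frame with an
#'   \code{n_signals} column.
#' @return List with \code{fraction}, \code{n_with_signal},
#'   \code{n_fibers}.
#' @export
#' @examples
#' # pooled published counts for the lower-dose condition: 90 of 800
#' rec <- data.frame(n_signals = rep(c(1, 0), c(90, 710)))
#' fraction_with_signal(rec)$fraction  # 0.1125
fraction_with_signal <- function(records) {
  r <- records_df(records)
  if (!nrow(r)) stop("no fiber records", call. = FALSE)
  k <- sum(r$n_signals >= 1L)
  list(fraction = k / nrow(r), n_with_signal = k, n_fibers = nrow(r))
}

#' Signal density per 1000 kb of fiber
#'
#' Total signals across records divided by total fiber length, times
#' 1000.
#'
#' @inheritParams fraction_with_signal
#' @return Density in signals per 1000 kb.
#' @export
signals_per_1000kb <- function(records) {
  r <- records_df(records)
  tot <- sum(r$length_kb)
  if (!is.finite(tot) || tot <= 0)
    stop("total fiber length must be > 0", call. = FALSE)
  sum(r$n_signals) / tot * 1000
}

#' Inter-adduct distances pooled across fibers
#'
#' For every fiber with at least two signals, the consecutive
#' differences of its sorted signal positions; never spans two fibers.
#'
#' @param records A \code{fiber_records} object, or a signals data frame
#'   with \code{fiber_id} and \code{arc_kb}.
#' @return Numeric vector of distances in kb.
#' @export
interadduct_distances <- function(records) {
  sig <- if (inherits(records, "fiber_records")) records$signals else records
  if (!nrow(sig)) return(numeric(0))
  unlist(lapply(split(sig$arc_kb, sig$fiber_id), function(p) {
    if (length(p) < 2L) numeric(0) else diff(sort(p))
  }), use.names = FALSE)
}

#' Single- versus double-sided encounter proportions
#'
#' Fractions over the SINGLE_SIDED / DOUBLE_SIDED subset only (they sum
#' to 1). End-censored signals are excluded by default: the
#' \code{category_uncensored} column is used, so a fiber whose only
#' single/double evidence sat within the adjacency tolerance of a fiber
#' end drops out.
#'
#' @param records A \code{fiber_records} object or records data frame.
#' @param use_censored Use the raw category including end-censored
#'   signals.
#' @return List with \code{single_fraction}, \code{double_fraction},
#'   \code{n_single}, \code{n_double}, \code{n}.
#' @export
#' @examples
#' # pooled published counts: 19 single-sided vs 118 double-sided
#' rec <- data.frame(
#'   n_signals = 1,
#'   category_uncensored = rep(c("SINGLE_SIDED", "DOUBLE_SIDED"), c(19, 118)))
#' encounter_proportions(rec)
encounter_proportions <- function(records, use_censored = FALSE) {
  r <- records_df(records)
  col <- if (use_censored || !"category_uncensored" %in% names(r))
    "category" else "category_uncensored"
  cats <- as.character(r[[col]])
  ns <- sum(cats == "SINGLE_SIDED", na.rm = TRUE)
  nd <- sum(cats == "DOUBLE_SIDED", na.rm = TRUE)
  n <- ns + nd
  if (n == 0L)
    stop("no single- or double-sided fibers to compare", call. = FALSE)
  list(single_fraction = ns / n, double_fraction = nd / n,
       n_single = ns, n_double = nd, n = n)
}

#' Per-experiment summary table
#'
#' One row per experiment label with the counts and densities reported
#' for fiber-assay experiments.
#'
#' @param records A \code{fiber_records} object.
#' @return Data frame with \code{experiment_label}, \code{n_fibers},
#'   \code{n_fibers_with_signal}, \code{total_length_kb},
#'   \code{n_signals}, \code{density_per_1000kb} and one count column
#'   per category.
#' @export
summarize_experiments <- function(records) {
  r <- records_df(records)
  out <- lapply(split(r, r$experiment_label), function(g) {
    cc <- table(factor(g$category, levels = fiber_categories))
    cbind(data.frame(experiment_label = g$experiment_label[1],
                     n_fibers = nrow(g),
                     n_fibers_with_signal = sum(g$n_signals >= 1),
                     total_length_kb = sum(g$length_kb),
                     n_signals = sum(g$n_signals),
                     density_per_1000kb =
                       sum(g$n_signals) / sum(g$length_kb) * 1000,
                     stringsAsFactors = FALSE),
          as.data.frame.matrix(t(as.matrix(cc))))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
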