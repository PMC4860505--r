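## Ground-truth simulation: Poisson adduct placement with two-zone
## chromatin accessibility, ICL/monoadduct labelling, and replication
## tracts abutting adducts on one or both sides.

#' Place psoralen adducts along one fiber
#'
#' Positions are drawn from a piecewise-constant-rate Poisson process.
#' One contiguous "accessible" zone covering \code{accessible_fraction}
#' of the fiber (uniform random offset) reacts at \code{rate_ratio}
#' times the rate of the remainder; rates are scaled so the
#' length-weighted mean equals \code{adduct_rate}. Each adduct is
#' independently an interstrand crosslink with probability
#' \code{icl_fraction}, otherwise a monoadduct.
#'
#' @param length_kb Fiber length in kb (> 0).
#' @param adduct_rate Expected adducts per 1000 kb.
#' @param accessibility List with \code{accessible_fraction} and
#'   \code{rate_ratio}; \code{rate_ratio = 1} gives a homogeneous
#'   process.
#' @param icl_fraction Probability an adduct is an ICL.
#' @return A data frame with columns \code{position_kb} (sorted
#'   ascending) and \code{kind} (\code{"ICL"} or \code{"mono"}).
#' @export
#' @examples
#' set.seed(1)
#' place_adducts(500, adduct_rate = 4.48)
place_adducts <- function(length_kb, adduct_rate,
                          accessibility = list(accessible_fraction = 0.3,
                                               rate_ratio = 4),
                          icl_fraction = 10 / 11) {
  if (!is.numeric(length_kb) || length_kb <= 0)
    stop("configuration error: length_kb must be > 0", call. = FALSE)
  if (!is.numeric(adduct_rate) || adduct_rate < 0)
    stop("configuration error: adduct_rate must be >= 0", call. = FALSE)
  f <- accessibility$accessible_fraction
  r <- accessibility$rate_ratio
  lam <- adduct_rate / 1000      # per kb
  pos <- if (adduct_rate == 0) {
    numeric(0)
  } else if (f <= 0 || f >= 1 || r == 1) {
    sort(runif(rpois(1L, lam * length_kb), 0, length_kb))
  } else {
    # mean rate constraint: f*r*ri + (1-f)*ri = lam
    ri <- lam / (f * r + (1 - f))
    ra <- r * ri
    a_len <- f * length_kb
    a_start <- runif(1L, 0, length_kb - a_len)
    n_a <- rpois(1L, ra * a_len)
    n_i <- rpois(1L, ri * (length_kb - a_len))
    p_a <- runif(n_a, a_start, a_start + a_len)
    # inaccessible zone is the two flanks; draw uniform over their union
    u <- runif(n_i, 0, length_kb - a_len)
    p_i <- ifelse(u < a_start, u, u + a_len)
    sort(c(p_a, p_i))
  }
  kind <- ifelse(rbinom(length(pos), 1L, icl_fraction) == 1L, "ICL", "mono")
  data.frame(position_kb = pos, kind = kind, stringsAsFactors = FALSE)
}

# truncated positive draw from a tract-length law
draw_tract_len <- function(dist) {
  for (i in 1:50) {
    x <- draw_lengths(dist, 1L)
    if (x > 0) return(x)
  }
  dist$min_kb
}

#' Place replication tracts around a fiber's adducts
#'
#' Each adduct independently receives an adjacent replication event with
#' probability \code{encounter_fraction}: single-sided (one IdU tract
#' ending exactly at the adduct, side chosen at random) with probability
#' \code{single_sided_prob}, otherwise double-sided (tracts abutting
#' both sides). Tracts are clipped to the fiber and truncated so they
#' never approach a \emph{different} adduct closer than
#' \code{neighbor_guard_kb}; a side with no room (adduct at the fiber
#' end, or a neighbor too close) degrades the event, which is flagged in
#' the output. Independent "distant" tracts unlinked to any adduct are
#' added with probability \code{distant_tract_prob} per fiber.
#'
#' @param length_kb Fiber length in kb.
#' @param adducts Data frame from [place_adducts()].
#' @param replication Replication parameter list (see
#'   [simulation_config()]).
#' @return List with \code{tracts} (data frame: \code{start_kb},
#'   \code{end_kb}, \code{label}, \code{linked_adduct}) and
#'   \code{events} (per-adduct data frame: \code{event} intended,
#'   \code{realized} sides obtained, \code{degraded} flag).
#' @export
place_replication <- function(length_kb, adducts, replication) {
  n <- nrow(adducts)
  ev <- data.frame(event = character(n), realized = character(n),
                   degraded = logical(n), stringsAsFactors = FALSE)
  tr <- list()
  min_len <- 1  # kb; a side with less room than this is unplaceable
  guard <- replication$neighbor_guard_kb
  pos <- adducts$position_kb
  for (j in seq_len(n)) {
    p <- pos[j]
    if (runif(1) > replication$encounter_fraction) {
      ev$event[j] <- "none"; ev$realized[j] <- "none"
      next
    }
    # room on each side, stopping a guard short of neighboring adducts
    left_lim <- if (j > 1L) pos[j - 1L] + guard else 0
    right_lim <- if (j < n) pos[j + 1L] - guard else length_kb
    left_room <- p - left_lim
    right_room <- right_lim - p
    single <- runif(1) < replication$single_sided_prob
    ev$event[j] <- if (single) "single" else "double"
    mk <- function(side) {
      len <- draw_tract_len(replication$tract_length_dist)
      if (side == "left") {
        s <- max(p - len, left_lim)
        if (p - s < min_len) return(NULL)
        c(s, p)
      } else {
        e <- min(p + len, right_lim)
        if (e - p < min_len) return(NULL)
        c(p, e)
      }
    }
    sides <- if (single) {
      pick <- if (runif(1) < 0.5) "left" else "right"
      # fall back to the other side if the chosen one has no room
      if ((pick == "left" && left_room < min_len) ||
          (pick == "right" && right_room < min_len)) {
        pick <- setdiff(c("left", "right"), pick)
      }
      pick
    } else c("left", "right")
    placed <- character(0)
    for (s in sides) {
      seg <- mk(s)
      if (!is.null(seg)) {
        tr[[length(tr) + 1L]] <- data.frame(start_kb = seg[1], end_kb = seg[2],
                                            label = "IdU", linked_adduct = j,
                                            stringsAsFactors = FALSE)
        placed <- c(placed, s)
      }
    }
    ev$realized[j] <- if (length(placed) == 2L) "both"
                      else if (length(placed) == 1L) placed
                      else "none"
    intended_both <- !single
    ev$degraded[j] <- (intended_both && length(placed) < 2L) ||
                      (single && length(placed) < 1L)
  }
  # distant tract unlinked to any adduct, kept a guard away from all
  if (runif(1) < replication$distant_tract_prob) {
    for (try in 1:20) {
      len <- min(draw_tract_len(replication$tract_length_dist), length_kb / 2)
      s <- runif(1, 0, max(length_kb - len, 0))
      e <- s + len
      clear <- all(pos < s - guard | pos > e + guard)
      overlap <- length(tr) &&
        any(vapply(tr, function(t) t$start_kb < e && t$end_kb > s, logical(1)))
      if (clear && !overlap) {
        tr[[length(tr) + 1L]] <- data.frame(start_kb = s, end_kb = e,
                                            label = "IdU", linked_adduct = NA_integer_,
                                            stringsAsFactors = FALSE)
        break
      }
    }
  }
  tracts <- if (length(tr)) do.call(rbind, tr) else
    data.frame(start_kb = numeric(0), end_kb = numeric(0),
               label = character(0), linked_adduct = integer(0),
               stringsAsFactors = FALSE)
  tracts <- tracts[order(tracts$start_kb), , drop = FALSE]
  rownames(tracts) <- NULL
  list(tracts = tracts, events = ev)
}

#' Simulate a ground-truth fiber population
#'
#' Draws \code{n_fibers} fiber lengths, covers each fiber with a
#' full-length CldU prelabel tract, places adducts and replication
#' tracts, and (in laser mode) restricts adducts to the configured
#' carrier subpopulation. Deterministic given \code{cfg$seed}.
#'
#' @param cfg A [simulation_config()].
#' @return An object of class \code{fiber_population}: list with data
#'   frames \code{fibers} (\code{fiber_id}, \code{length_kb},
#'   \code{carries_adducts}, \code{origin_label}), \code{adducts}
#'   (\code{fiber_id}, \code{position_kb}, \code{kind}, \code{event},
#'   \code{realized}, \code{degraded}), \code{tracts} (\code{fiber_id},
#'   \code{start_kb}, \code{end_kb}, \code{label},
#'   \code{linked_adduct}), plus the \code{config}.
#' @export
#' @examples
#' pop <- simulate_fibers(simulation_config(n_fibers = 20, seed = 3))
#' pop
simulate_fibers <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_fibers
  lens <- draw_lengths(cfg$fiber_length_dist, n)
  carries <- if (cfg$treatment_mode == "laser")
    runif(n) < cfg$laser_fiber_fraction else rep(TRUE, n)
  fibers <- data.frame(fiber_id = seq_len(n),
                       length_kb = lens,
                       carries_adducts = carries,
                       origin_label = rep(cfg$origin_label, n),
                       stringsAsFactors = FALSE)
  add_l <- vector("list", n)
  trc_l <- vector("list", n)
  for (i in seq_len(n)) {
    ad <- if (carries[i])
      place_adducts(lens[i], cfg$adduct_rate, cfg$accessibility,
                    cfg$icl_fraction)
    else data.frame(position_kb = numeric(0), kind = character(0),
                    stringsAsFactors = FALSE)
    rep_out <- place_replication(lens[i], ad, cfg$replication)
    if (nrow(ad)) {
      ad <- cbind(fiber_id = i, ad, rep_out$events)
      add_l[[i]] <- ad
    }
    tr <- rbind(
      data.frame(start_kb = 0, end_kb = lens[i], label = "CldU",
                 linked_adduct = NA_integer_, stringsAsFactors = FALSE),
      rep_out$tracts)
    trc_l[[i]] <- cbind(fiber_id = i, tr)
  }
  adducts <- if (length(add_l) && any(!vapply(add_l, is.null, logical(1))))
    do.call(rbind, add_l[!vapply(add_l, is.null, logical(1))])
  else data.frame(fiber_id = integer(0), position_kb = numeric(0),
                  kind = character(0), event = character(0),
                  realized = character(0), degraded = logical(0),
                  stringsAsFactors = FALSE)
  tracts <- if (n > 0) do.call(rbind, trc_l) else
    data.frame(fiber_id = integer(0), start_kb = numeric(0),
               end_kb = numeric(0), label = character(0),
               linked_adduct = integer(0), stringsAsFactors = FALSE)
  rownames(adducts) <- rownames(tracts) <- NULL
  structure(list(fibers = fibers, adducts = adducts, tracts = tracts,
                 config = cfg),
            class = "fiber_population")
}

#' @export
print.fiber_population <- function(x, ...) {
  n <- nrow(x$fibers)
  tot <- sum(x$fibers$length_kb)
  na <- nrow(x$adducts)
  cat(sprintf("Fiber population: %d fibers, %.0f kb total (%s mode)\n",
              n, tot, x$config$treatment_mode))
  if (n > 0)
    cat(sprintf("  adducts: %d (%.2f per 1000 kb ground truth; %d ICL, %d mono)\n",
                na, 1000 * na / tot, sum(x$adducts$kind == "ICL"),
                sum(x$adducts$kind == "mono")))
  idu <- x$tracts[x$tracts$label == "IdU", , drop = FALSE]
  cat(sprintf("  IdU tracts: %d on %d fibers\n",
              nrow(idu), length(unique(idu$fiber_id))))
  invisible(x)
}

#' @export
summary.fiber_population <- function(object, ...) {
  print(object)
  if (nrow(object$adducts)) {
    ev <- table(factor(object$adducts$realized,
                       levels = c("none", "left", "right", "both")))
    cat("  realized encounter sides:",
        paste(names(ev), ev, sep = "=", collapse = ", "), "\n")
  }
  invisible(object)
}
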