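# Stability statistics for stacked nanotubes.
#
# The headline statistic is the number of broken hydrogen bonds per
# nanosecond (BHB/ns): how often a backbone bond that is present at one
# frame is absent at the next, normalized by simulated time. It is
# reported in total and decomposed into cap (terminal-interface) and core
# contributions, because the capping unimers bond through a single
# interface and are the labile, dynamics-regulating component of the
# stack.

#' Broken hydrogen bonds per nanosecond
#'
#' A break event is a present-to-absent transition whose subsequent absent
#' run lasts at least `flicker_window` frames (a run truncated by the end
#' of the series counts: its persistence cannot be disproven). Window 0
#' counts every raw transition, so repeated flicker of one bond counts
#' repeatedly; larger windows discard transient sub-threshold flicker.
#' Rates are events divided by `(n_frames - 1) * frame_dt`.
#'
#' @param bond_states A `bond_state_series`.
#' @param flicker_window Minimum absent-run length, frames (>= 0).
#' @return A `stability_rates` list: `bhb_total`, `bhb_cap`, `bhb_core`
#'   (events/ns; total = cap + core exactly), per-bond-normalized rates,
#'   event counts, mean bond counts per class, and `simulated_time` (ns).
#' @export
broken_bonds_per_ns <- function(bond_states, flicker_window = 0L) {
  stopifnot(inherits(bond_states, "bond_state_series"))
  p <- bond_states$presence
  nf <- ncol(p)
  if (nf < 2L)
    stop("insufficient data: need >= 2 frames to count break events",
         call. = FALSE)
  if (flicker_window < 0) stop("flicker_window must be >= 0", call. = FALSE)

  breaks_of <- function(x) {
    r <- rle(as.logical(x))
    n <- length(r$lengths)
    if (n < 2L) return(0L)
    # absent runs that directly follow a present run
    j <- which(!r$values & seq_len(n) > 1L)
    if (flicker_window > 0L) {
      last <- j == n  # censored by end of series: keep
      j <- j[last | r$lengths[j] >= flicker_window]
    }
    length(j)
  }
  ev <- apply(p, 1L, breaks_of)
  time_ns <- (nf - 1L) * bond_states$frame_dt
  lab <- bond_states$labels
  n_cap <- sum(lab == "cap"); n_core <- sum(lab == "core")
  e_cap <- sum(ev[lab == "cap"]); e_core <- sum(ev[lab == "core"])

  structure(list(
    bhb_total = (e_cap + e_core) / time_ns,
    bhb_cap = e_cap / time_ns,
    bhb_core = e_core / time_ns,
    bhb_cap_per_bond = if (n_cap > 0) e_cap / n_cap / time_ns else NA_real_,
    bhb_core_per_bond = if (n_core > 0) e_core / n_core / time_ns
                        else NA_real_,
    events_total = e_cap + e_core,
    events_cap = e_cap, events_core = e_core,
    mean_count_total = mean(colSums(p)),
    mean_count_cap = mean(colSums(p[lab == "cap", , drop = FALSE])),
    mean_count_core = mean(colSums(p[lab == "core", , drop = FALSE])),
    flicker_window = as.integer(flicker_window),
    simulated_time = time_ns), class = "stability_rates")
}

#' Mean inter-unimer distance of a trajectory
#'
#' Mean over frames and adjacent ring pairs of the centroid-to-centroid
#' distance, centroids taken over the backbone atoms of each ring. For the
#' construction used here the axial amide displacements cancel around each
#' ring, so the ideal model returns its stacking spacing exactly.
#'
#' @param traj A `nanotube_trajectory` (or a `nanotube_model`, treated as
#'   a single frame).
#' @return Mean distance, Angstrom.
#' @export
mean_interunimer_distance <- function(traj) {
  if (inherits(traj, "nanotube_model")) {
    model <- traj
    frames <- array(traj$xyz, c(nrow(traj$xyz), 3, 1))
    nf <- 1L
  } else {
    stopifnot(inherits(traj, "nanotube_trajectory"))
    model <- traj$model; frames <- traj$frames; nf <- traj$n_frames
  }
  if (model$n_unimers < 2L)
    stop("need >= 2 rings to measure inter-unimer distance", call. = FALSE)
  per_frame <- vapply(seq_len(nf), function(k) {
    cen <- ring_centroids(frames[, , k], model$atoms)
    mean(sqrt(rowSums(diff(cen)^2)))
  }, numeric(1))
  mean(per_frame)
}

#' Detect dissociation events in a bond-count series
#'
#' The total count is smoothed with a running median (`median_window`
#' frames), then scanned for sustained drops: an event starts at the first
#' frame whose smoothed count sits at least `drop_threshold` bonds below
#' the median of the preceding (post-previous-event) segment and stays
#' that low for at least `persistence` frames. The defaults are tuned so a
#' full cap unbinding (8 bonds) triggers while thermal flicker of a few
#' bonds does not.
#'
#' @param count_series Data frame with a `total` column (as produced by
#'   [hbond_timeseries()]), or a numeric vector of counts.
#' @param drop_threshold Minimum sustained drop, bonds.
#' @param persistence Minimum duration of the depressed level, frames.
#' @param median_window Running-median width, frames (odd).
#' @return Data frame of events: `frame` (first depressed frame),
#'   `magnitude` (baseline minus depressed median, bonds). Zero rows when
#'   nothing qualifies.
#' @export
detect_dissociation_events <- function(count_series, drop_threshold = 6,
                                       persistence = 50L,
                                       median_window = 11L) {
  x <- if (is.data.frame(count_series)) count_series$total
       else as.numeric(count_series)
  n <- length(x)
  persistence <- as.integer(persistence)
  if (n < persistence + 1L)
    stop("series shorter than persistence + 1", call. = FALSE)
  k <- min(median_window, if (n %% 2L == 1L) n else n - 1L)
  if (k %% 2L == 0L) k <- k - 1L
  med <- if (k >= 3) stats::runmed(x, k) else x

  events <- data.frame(frame = integer(), magnitude = numeric())
  seg_start <- 1L
  t <- 2L
  while (t <= n - persistence + 1L) {
    baseline <- stats::median(med[seg_start:(t - 1L)])
    window <- med[t:(t + persistence - 1L)]
    if (med[t] <= baseline - drop_threshold &&
        all(window <= baseline - drop_threshold)) {
      events <- rbind(events, data.frame(
        frame = t, magnitude = baseline - stats::median(window)))
      seg_start <- t + persistence
      t <- t + persistence
    } else t <- t + 1L
  }
  events
}

#' Summarize a set of measured nanotube lengths
#'
#' Arithmetic mean, standard deviation and a histogram of per-tube
#' lengths, as measured from micrographs.
#'
#' @param lengths_nm Positive lengths, nm.
#' @param breaks Passed to [graphics::hist()] (`plot = FALSE`).
#' @return A `length_summary`: `n_tubes`, `mean_nm`, `sd_nm`, `min_nm`,
#'   `max_nm`, and histogram `bins` (data frame: lower, upper, count).
#' @export
summarize_lengths <- function(lengths_nm, breaks = "Sturges") {
  lengths_nm <- as.numeric(lengths_nm)
  if (length(lengths_nm) == 0L)
    stop("insufficient data: no lengths supplied", call. = FALSE)
  if (any(!is.finite(lengths_nm)) || any(lengths_nm <= 0))
    stop("lengths must be positive and finite (nm)", call. = FALSE)
  h <- graphics::hist(lengths_nm, breaks = breaks, plot = FALSE)
  structure(list(
    n_tubes = length(lengths_nm),
    mean_nm = mean(lengths_nm),
    sd_nm = if (length(lengths_nm) > 1L) stats::sd(lengths_nm) else 0,
    min_nm = min(lengths_nm), max_nm = max(lengths_nm),
    bins = data.frame(lower = utils::head(h$breaks, -1),
                      upper = h$breaks[-1], count = h$counts)),
    class = "length_summary")
}

#' Convert a tube length to a stacked-unimer count
#'
#' One unimer occupies one stacking repeat, so a tube of length L at
#' spacing d holds about L/d rings (never fewer than one).
#'
#' @param length_nm Tube length(s), nm.
#' @param spacing_nm Stacking repeat, nm. Default 0.485 (= 4.85 Angstrom).
#' @return Integer unimer count(s).
#' @export
length_to_unimer_count <- function(length_nm, spacing_nm = 0.485) {
  if (any(length_nm <= 0)) stop("length must be positive", call. = FALSE)
  if (!is.numeric(spacing_nm) || spacing_nm <= 0)
    stop("spacing must be positive", call. = FALSE)
  pmax(1L, as.integer(round(length_nm / spacing_nm)))
}

#' Full stability report for a trajectory
#'
#' Convenience wrapper chaining bond detection, break-rate estimation,
#' spacing measurement and event detection.
#'
#' @param traj A `nanotube_trajectory`.
#' @param criteria An [hbond_criteria()].
#' @param flicker_window See [broken_bonds_per_ns()].
#' @param drop_threshold,persistence,median_window See
#'   [detect_dissociation_events()].
#' @return A `stability_report` list combining the rate fields of
#'   [broken_bonds_per_ns()] with `mean_spacing` (Angstrom), the
#'   dissociation event table and the count series.
#' @export
stability_report <- function(traj, criteria = hbond_criteria(),
                             flicker_window = 0L, drop_threshold = 6,
                             persistence = 50L, median_window = 11L) {
  ts <- hbond_timeseries(traj, criteria)
  rates <- broken_bonds_per_ns(ts$bond_states, flicker_window)
  events <- if (nrow(ts$counts) >= persistence + 1L)
    detect_dissociation_events(ts$counts, drop_threshold, persistence,
                               median_window)
  else data.frame(frame = integer(), magnitude = numeric())
  out <- unclass(rates)
  out$mean_spacing <- mean_interunimer_distance(traj)
  out$dissociation_events <- events
  out$counts <- ts$counts
  class(out) <- "stability_report"
  out
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %.4g ns simulated\n", x$simulated_time))
  cat(sprintf("  BHB/ns total %.3g (cap %.3g + core %.3g)\n",
              x$bhb_total, x$bhb_cap, x$bhb_core))
  cat(sprintf("  mean bonds %.2f, mean spacing %.3f A, %d dissociation event(s)\n",
              x$mean_count_total, x$mean_spacing,
              nrow(x$dissociation_events)))
  invisible(x)
}
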