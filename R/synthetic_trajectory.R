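# Synthetic trajectories and bond-state dynamics with known ground truth.
#
# Atomistic MD of the real conjugates runs for hundreds to thousands of
# nanoseconds; here trajectories are emulated so that every downstream
# estimator can be validated against known truth: (i) thermal jitter as
# i.i.d. Gaussian displacement of every atom around the ideal model,
# (ii) an optional scripted cap-unbinding event, and (iii) two-state
# Markov bond flickering at prescribed break/reform rates.

#' Gaussian-jitter trajectory around an ideal model
#'
#' Frame 1 is the unperturbed model; every later frame displaces each atom
#' coordinate independently by zero-mean Gaussian noise of standard
#' deviation `sigma`. Frames are independent (jitter around the ideal
#' structure, not a random walk), emulating thermal fluctuation about a
#' stable stack.
#'
#' @param model A `nanotube_model`.
#' @param n_frames Number of frames (>= 1).
#' @param sigma Noise s.d. per coordinate, Angstrom (>= 0).
#' @param frame_dt Frame interval, ns.
#' @param seed Integer seed; required, scoped to this call.
#' @return A `nanotube_trajectory`: the model, a coordinate array
#'   `n_atoms x 3 x n_frames`, `frame_dt` and the seed.
#' @export
jitter_trajectory <- function(model, n_frames, sigma = 0.2,
                              frame_dt = 0.1, seed) {
  stopifnot(inherits(model, "nanotube_model"))
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be >= 1", call. = FALSE)
  if (!is.numeric(sigma) || sigma < 0)
    stop("sigma must be >= 0 (Angstrom)", call. = FALSE)
  if (frame_dt <= 0) stop("frame_dt must be > 0 (ns)", call. = FALSE)
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)

  na <- nrow(model$xyz)
  frames <- array(0, c(na, 3, n_frames))
  frames[, , 1] <- model$xyz
  if (n_frames > 1L) {
    noise <- withr::with_seed(seed,
      array(stats::rnorm(na * 3 * (n_frames - 1L), sd = sigma),
            c(na, 3, n_frames - 1L)))
    for (k in 2:n_frames)
      frames[, , k] <- model$xyz + noise[, , k - 1L]
  }
  structure(list(model = model, frames = frames, n_frames = n_frames,
                 frame_dt = frame_dt, seed = as.integer(seed)),
            class = "nanotube_trajectory")
}

#' @export
print.nanotube_trajectory <- function(x, ...) {
  cat(sprintf("<nanotube_trajectory> %d frames x %d atoms, dt %.3g ns\n",
              x$n_frames, dim(x$frames)[1], x$frame_dt))
  invisible(x)
}

#' Script a cap-unbinding event into a trajectory
#'
#' From `event_frame` onward the terminal ring (highest ring index) is
#' translated along +z by `displacement` and tilted by `tilt` degrees
#' about an in-plane axis through its centroid. A displacement of >= 3
#' Angstrom moves every donor/acceptor of the terminal interface outside
#' any sane hydrogen-bond cutoff, so the interface's bonds all vanish —
#' the signature of a capping unimer dissociating from the stack.
#'
#' @param traj A `nanotube_trajectory`.
#' @param event_frame First affected frame (1-based).
#' @param displacement Axial displacement, Angstrom (> 0).
#' @param tilt Tilt angle of the leaving ring, degrees.
#' @return The modified trajectory, with an `event` attribute recording
#'   the scripted parameters.
#' @export
script_cap_unbinding <- function(traj, event_frame, displacement = 10,
                                 tilt = 15) {
  stopifnot(inherits(traj, "nanotube_trajectory"))
  event_frame <- as.integer(event_frame)
  if (event_frame < 1L || event_frame > traj$n_frames)
    stop("event_frame out of range [1, ", traj$n_frames, "]", call. = FALSE)
  if (!is.numeric(displacement) || displacement <= 0)
    stop("displacement must be > 0 (Angstrom)", call. = FALSE)

  atoms <- traj$model$atoms
  sel <- atoms$ring == traj$model$n_unimers
  rot <- {
    t <- tilt * pi / 180
    matrix(c(1, 0, 0, 0, cos(t), -sin(t), 0, sin(t), cos(t)), 3, 3,
           byrow = TRUE)
  }
  for (k in event_frame:traj$n_frames) {
    sub <- traj$frames[sel, , k, drop = FALSE][, , 1]
    cen <- colMeans(sub)
    sub <- sweep(sweep(sub, 2, cen) %*% t(rot), 2, cen, "+")
    sub[, 3] <- sub[, 3] + displacement
    traj$frames[sel, , k] <- sub
  }
  traj$event <- list(frame = event_frame, displacement = displacement,
                     tilt = tilt, ring = traj$model$n_unimers)
  traj
}

#' Simulate two-state Markov hydrogen-bond dynamics
#'
#' Each bond is an independent formed/broken Markov chain observed every
#' `frame_dt` ns. Per-frame transition probabilities use the exact
#' exponential discretization `p = 1 - exp(-k * frame_dt)`, so the rate
#' parameters keep their meaning at coarse sampling. All bonds start
#' formed. Cap and core bonds may break at different rates, mirroring the
#' weaker hydrogen bonding of the terminal (capping) rings.
#'
#' @param n_cap_bonds,n_core_bonds Bond counts per class (octamer: 16 cap,
#'   40 core).
#' @param k_break_cap,k_break_core Break rates, 1/ns (>= 0).
#' @param k_reform Reform rate, 1/ns (>= 0), shared by both classes.
#' @param frame_dt Observation interval, ns.
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer seed; required.
#' @return A `bond_state_series`: logical presence matrix (bond x frame),
#'   `labels` ("cap"/"core" per bond), `frame_dt`, and a `truth` list with
#'   the simulated rates.
#' @export
simulate_bond_states <- function(n_cap_bonds = 16L, n_core_bonds = 40L,
                                 k_break_cap, k_break_core,
                                 k_reform, frame_dt = 0.1, n_frames,
                                 seed) {
  for (k in c(k_break_cap, k_break_core, k_reform))
    if (!is.numeric(k) || k < 0)
      stop("all rates must be >= 0 (1/ns)", call. = FALSE)
  if (frame_dt <= 0) stop("frame_dt must be > 0 (ns)", call. = FALSE)
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be >= 1", call. = FALSE)
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)

  nb <- n_cap_bonds + n_core_bonds
  labels <- rep(c("cap", "core"), c(n_cap_bonds, n_core_bonds))
  p_break <- 1 - exp(-ifelse(labels == "cap", k_break_cap, k_break_core) *
                       frame_dt)
  p_reform <- 1 - exp(-k_reform * frame_dt)

  presence <- matrix(NA, nb, n_frames)
  presence[, 1] <- TRUE
  if (n_frames > 1L) withr::with_seed(seed, {
    for (t in 2:n_frames) {
      u <- stats::runif(nb)
      s <- presence[, t - 1L]
      presence[, t] <- ifelse(s, u >= p_break, u < p_reform)
    }
  })
  structure(list(presence = presence, labels = labels,
                 frame_dt = frame_dt,
                 truth = list(k_break_cap = k_break_cap,
                              k_break_core = k_break_core,
                              k_reform = k_reform)),
            class = "bond_state_series")
}

#' @export
print.bond_state_series <- function(x, ...) {
  cat(sprintf(
    "<bond_state_series> %d bonds (%d cap, %d core) x %d frames, dt %.3g ns\n",
    nrow(x$presence), sum(x$labels == "cap"), sum(x$labels == "core"),
    ncol(x$presence), x$frame_dt))
  invisible(x)
}

#' Write a bond-state series to CSV (long format)
#'
#' Columns: bond_id, label, frame, present. A JSON sidecar with the truth
#' rates is written next to it when ground truth is available.
#'
#' @param bs A `bond_state_series`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_bond_states <- function(bs, path) {
  stopifnot(inherits(bs, "bond_state_series"))
  nb <- nrow(bs$presence); nf <- ncol(bs$presence)
  df <- data.frame(bond_id = rep(seq_len(nb), times = nf),
                   label = rep(bs$labels, times = nf),
                   frame = rep(seq_len(nf), each = nb),
                   present = as.integer(bs$presence))
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(bs$truth))
    jsonlite::write_json(bs$truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate per-tube length measurements
#'
#' Draws nanotube lengths from a lognormal distribution with the given
#' arithmetic mean and standard deviation, emulating hand-measured tube
#' lengths from micrographs (strictly positive, right-skewed).
#'
#' @param n_tubes Number of tubes measured.
#' @param mean_nm Target arithmetic mean length, nm.
#' @param sd_nm Target arithmetic standard deviation, nm.
#' @param seed Integer seed; required.
#' @return Numeric vector of lengths, nm.
#' @export
simulate_tem_lengths <- function(n_tubes, mean_nm, sd_nm, seed) {
  if (n_tubes < 1L) stop("n_tubes must be >= 1", call. = FALSE)
  if (mean_nm <= 0 || sd_nm < 0) stop("mean_nm > 0 and sd_nm >= 0 required",
                                      call. = FALSE)
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  cv2 <- (sd_nm / mean_nm)^2
  sdlog <- sqrt(log1p(cv2))
  meanlog <- log(mean_nm) - sdlog^2 / 2
  withr::with_seed(seed, stats::rlnorm(n_tubes, meanlog, sdlog))
}
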