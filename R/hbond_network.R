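# Geometric detection of backbone-backbone hydrogen bonds.
#
# A bond is counted between a donor amide (N-H) and an acceptor carbonyl
# oxygen on an ADJACENT ring when the N...O distance is within `d_max` and
# the N-H...O angle (vertex at H) is at least `theta_min`. These two
# cutoffs are the standard geometric criterion used by MD analysis suites;
# an energetic definition is deliberately out of scope. Intramolecular
# pairs are never counted: the statistic of interest is the inter-ring
# network that holds the stack together.

#' Hydrogen-bond detection criteria
#'
#' @param d_max Donor nitrogen to acceptor oxygen distance cutoff,
#'   Angstrom. Default 3.5.
#' @param theta_min Minimum N-H...O angle at the hydrogen, degrees
#'   (180 = linear). Default 120.
#' @return An object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(d_max = 3.5, theta_min = 120) {
  if (!is.numeric(d_max) || d_max <= 0)
    stop("d_max must be > 0 (Angstrom)", call. = FALSE)
  if (!is.numeric(theta_min) || theta_min < 0 || theta_min > 180)
    stop("theta_min must be in [0, 180] degrees", call. = FALSE)
  structure(list(d_max = d_max, theta_min = theta_min),
            class = "hbond_criteria")
}

# Donor (N,H) and acceptor (O) atom indices of a model, cached layout.
.hb_sites <- function(atoms) {
  dN <- which(atoms$atom == "N")
  dH <- which(atoms$atom == "H")
  aO <- which(atoms$atom == "O")
  # N and H rows come in the same (ring, residue) order by construction;
  # realign defensively in case atoms were reordered by I/O.
  key <- function(i) paste(atoms$ring[i], atoms$residue[i])
  dH <- dH[match(key(dN), key(dH))]
  list(N = dN, H = dH, O = aO,
       d_ring = atoms$ring[dN], d_res = atoms$residue[dN],
       a_ring = atoms$ring[aO], a_res = atoms$residue[aO])
}

#' Detect backbone hydrogen bonds in one frame
#'
#' Every donor H is assigned to at most one acceptor: among acceptors on
#' adjacent rings passing both cutoffs, the one at the smallest N...O
#' distance wins; exact ties break to the lowest acceptor residue index
#' (then ring index) so detection is deterministic.
#'
#' @param xyz n_atoms x 3 coordinate matrix (one frame).
#' @param model The `nanotube_model` supplying the atom table (topology).
#' @param criteria An [hbond_criteria()] object.
#' @return Data frame of bond records: donor ring/residue, acceptor
#'   ring/residue, `interface` (the lower of the two ring indices),
#'   `interface_class` ("cap"/"core"), `distance` (Angstrom), `angle`
#'   (degrees). Zero rows when nothing bonds.
#' @export
detect_hbonds <- function(xyz, model, criteria = hbond_criteria()) {
  stopifnot(inherits(model, "nanotube_model"),
            inherits(criteria, "hbond_criteria"))
  if (nrow(xyz) != nrow(model$atoms) || ncol(xyz) != 3L)
    stop("frame does not match topology: expected ",
         nrow(model$atoms), " x 3 coordinates", call. = FALSE)
  s <- .hb_sites(model$atoms)
  pairs <- .hb_candidate_pairs(s, adjacency = 1L)
  rec <- .hb_evaluate(xyz, s, pairs, criteria)
  classify_interfaces(rec, model$n_unimers)
}

# All donor x acceptor index pairs with ring separation == adjacency
# (adjacency NA: all intermolecular pairs, used by the brute-force path).
.hb_candidate_pairs <- function(s, adjacency = 1L) {
  nd <- length(s$N); na <- length(s$O)
  di <- rep(seq_len(nd), times = na)
  ai <- rep(seq_len(na), each = nd)
  sep <- abs(s$d_ring[di] - s$a_ring[ai])
  keep <- if (is.na(adjacency)) sep >= 1L else sep == adjacency
  cbind(donor = di[keep], acceptor = ai[keep])
}

.hb_evaluate <- function(xyz, s, pairs, criteria) {
  empty <- data.frame(donor_ring = integer(), donor_res = integer(),
                      acceptor_ring = integer(), acceptor_res = integer(),
                      interface = integer(), distance = numeric(),
                      angle = numeric())
  if (nrow(pairs) == 0L) return(empty)
  N <- xyz[s$N[pairs[, 1]], , drop = FALSE]
  H <- xyz[s$H[pairs[, 1]], , drop = FALSE]
  O <- xyz[s$O[pairs[, 2]], , drop = FALSE]
  dNO <- sqrt(rowSums((N - O)^2))
  u <- N - H; v <- O - H
  cosang <- rowSums(u * v) /
    (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  ok <- dNO <= criteria$d_max & ang >= criteria$theta_min
  if (!any(ok)) return(empty)
  di <- pairs[ok, 1]; ai <- pairs[ok, 2]
  cand <- data.frame(donor_ring = s$d_ring[di], donor_res = s$d_res[di],
                     acceptor_ring = s$a_ring[ai],
                     acceptor_res = s$a_res[ai],
                     distance = dNO[ok], angle = ang[ok])
  # one bond per donor hydrogen: closest acceptor, deterministic ties
  ord <- order(cand$donor_ring, cand$donor_res, cand$distance,
               cand$acceptor_res, cand$acceptor_ring)
  cand <- cand[ord, , drop = FALSE]
  first <- !duplicated(cand[, c("donor_ring", "donor_res")])
  rec <- cand[first, , drop = FALSE]
  rec$interface <- pmin(rec$donor_ring, rec$acceptor_ring)
  rownames(rec) <- NULL
  rec[, c("donor_ring", "donor_res", "acceptor_ring", "acceptor_res",
          "interface", "distance", "angle")]
}

#' Label bond records with their interface class
#'
#' Cap interfaces are the first and the last (the ones formed by the two
#' capping unimers); everything between is core. For a dimer the single
#' interface is cap.
#'
#' @param records Bond records with an `interface` column.
#' @param n_unimers Number of rings in the model.
#' @return `records` with an `interface_class` column added/updated.
#' @export
classify_interfaces <- function(records, n_unimers) {
  n_unimers <- as.integer(n_unimers)
  if (nrow(records) > 0 &&
      any(records$interface < 1L | records$interface > n_unimers - 1L))
    stop("interface index out of range for ", n_unimers, " unimers",
         call. = FALSE)
  cap_ifaces <- unique(c(1L, n_unimers - 1L))
  records$interface_class <-
    ifelse(records$interface %in% cap_ifaces, "cap", "core")
  records
}

#' Per-frame hydrogen-bond counts of a trajectory
#'
#' Runs [detect_hbonds()] on every frame and aggregates (i) a count series
#' (total, cap, core per frame) and (ii) a per-bond presence matrix keyed
#' by donor/acceptor identity, so individual break events are attributable
#' to specific bonds.
#'
#' @param traj A `nanotube_trajectory`.
#' @param criteria An [hbond_criteria()] object.
#' @return List with `counts` (data frame: frame, time_ns, total, cap,
#'   core) and `bond_states` (a `bond_state_series` over all bonds ever
#'   observed, labelled cap/core by interface).
#' @export
hbond_timeseries <- function(traj, criteria = hbond_criteria()) {
  stopifnot(inherits(traj, "nanotube_trajectory"))
  if (traj$n_frames < 1L) stop("empty trajectory", call. = FALSE)
  model <- traj$model
  s <- .hb_sites(model$atoms)
  pairs <- .hb_candidate_pairs(s, adjacency = 1L)

  recs <- vector("list", traj$n_frames)
  for (k in seq_len(traj$n_frames)) {
    r <- .hb_evaluate(traj$frames[, , k], s, pairs, criteria)
    recs[[k]] <- classify_interfaces(r, model$n_unimers)
  }
  counts <- data.frame(
    frame = seq_len(traj$n_frames),
    time_ns = (seq_len(traj$n_frames) - 1L) * traj$frame_dt,
    total = vapply(recs, nrow, integer(1)),
    cap = vapply(recs, function(r) sum(r$interface_class == "cap"),
                 integer(1)),
    core = vapply(recs, function(r) sum(r$interface_class == "core"),
                  integer(1)))

  keys <- lapply(recs, function(r) {
    if (nrow(r) == 0L) return(character(0))
    paste0(r$donor_ring, ".", r$donor_res, ">",
           r$acceptor_ring, ".", r$acceptor_res)
  })
  all_keys <- unique(unlist(keys))
  presence <- matrix(FALSE, length(all_keys), traj$n_frames,
                     dimnames = list(all_keys, NULL))
  for (k in seq_len(traj$n_frames))
    presence[match(keys[[k]], all_keys), k] <- TRUE
  labels <- character(length(all_keys))
  for (k in seq_len(traj$n_frames)) {
    idx <- match(keys[[k]], all_keys)
    labels[idx] <- recs[[k]]$interface_class
  }
  bs <- structure(list(presence = presence, labels = labels,
                       frame_dt = traj$frame_dt, truth = NULL),
                  class = "bond_state_series")
  list(counts = counts, bond_states = bs)
}
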