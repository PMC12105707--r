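# PDB input/output for nanotube models and trajectories (via bio3d).
#
# Convention: one chain per ring (A, B, C, ...), residues numbered within
# each chain, atom names N/H/C/O, residue names alternating ALA (L) / DAL
# (D) to mark the chirality pattern. Trajectories use one MODEL record per
# frame. Coordinates in Angstrom to 3 decimals (PDB format precision).

.chain_ids <- c(LETTERS, letters, as.character(0:9))

.pdb_fields <- function(model) {
  a <- model$atoms
  if (model$n_unimers > length(.chain_ids))
    stop("too many rings for distinct PDB chain identifiers", call. = FALSE)
  list(chain = .chain_ids[a$ring],
       resno = a$residue,
       resid = ifelse(a$residue %% 2L == 1L, "ALA", "DAL"),
       elety = a$atom)
}

#' Write a nanotube model to a PDB file
#'
#' One chain per ring; coordinates truncated to the format's 0.001 Angstrom
#' precision.
#'
#' @param model A `nanotube_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "nanotube_model"))
  f <- .pdb_fields(model)
  bio3d::write.pdb(file = path, xyz = as.vector(t(model$xyz)),
                   resno = f$resno, resid = f$resid,
                   elety = f$elety, chain = f$chain)
  invisible(path)
}

#' Write a trajectory as a multi-MODEL PDB file
#'
#' @param traj A `nanotube_trajectory` (see [jitter_trajectory()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "nanotube_trajectory"))
  f <- .pdb_fields(traj$model)
  xyz <- t(apply(traj$frames, 3, function(m) as.vector(t(m))))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = f$resno, resid = f$resid,
                   elety = f$elety, chain = f$chain)
  invisible(path)
}

# Report the first line of a PDB file that breaks the fixed-width ATOM
# format, to make parse failures actionable.
.locate_pdb_fault <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) return(list(line = 0L, why = "file is empty"))
  rec <- grepl("^(ATOM|HETATM)", lines)
  if (!any(rec)) return(list(line = 1L, why = "no ATOM records"))
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      return(list(line = i, why = "ATOM record shorter than 54 columns"))
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz))
      return(list(line = i, why = "non-numeric coordinate field"))
  }
  NULL
}

#' Read a nanotube model (or trajectory) from a PDB file
#'
#' Reconstructs the atom table from chains (one ring per chain, in order of
#' first appearance) and infers each residue's amide face from the axial
#' direction of its N-H vector. Multi-MODEL files yield a
#' `nanotube_trajectory` when `frame_dt` is given, otherwise only the first
#' MODEL is returned.
#'
#' @param path PDB file path.
#' @param frame_dt Frame interval in ns; when supplied and the file has
#'   several MODELs, a trajectory is returned.
#' @return A `nanotube_model`, or a `nanotube_trajectory` for multi-MODEL
#'   input with `frame_dt`.
#' @export
read_structure <- function(path, frame_dt = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  fault <- .locate_pdb_fault(path)
  if (!is.null(fault))
    stop(sprintf("PDB parse error in '%s' at line %d: %s",
                 path, fault$line, fault$why), call. = FALSE)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  ring <- match(at$chain, unique(at$chain))
  atoms <- data.frame(ring = ring, residue = at$resno,
                      atom = at$elety, face = 0L)
  n_unimers <- max(ring)
  n_frames <- nrow(pdb$xyz)
  frames <- array(NA_real_, c(nrow(atoms), 3, n_frames))
  for (k in seq_len(n_frames))
    frames[, , k] <- matrix(pdb$xyz[k, ], ncol = 3, byrow = TRUE)
  xyz <- frames[, , 1]

  cen <- ring_centroids(xyz, atoms)
  axis <- if (n_unimers >= 2) {
    v <- cen[n_unimers, ] - cen[1, ]
    v / sqrt(sum(v^2))
  } else c(0, 0, 1)
  spacing <- if (n_unimers >= 2) {
    d <- diff(cen)
    mean(sqrt(rowSums(d^2)))
  } else NA_real_

  # amide face from the N->H direction projected on the tube axis
  nres <- max(atoms$residue)
  for (r in seq_len(n_unimers)) for (j in seq_len(nres)) {
    sel <- atoms$ring == r & atoms$residue == j
    iN <- which(sel & atoms$atom == "N")
    iH <- which(sel & atoms$atom == "H")
    if (length(iN) == 1L && length(iH) == 1L)
      atoms$face[sel] <- as.integer(sign(sum((xyz[iH, ] - xyz[iN, ]) * axis)))
  }

  model <- structure(
    list(atoms = atoms, xyz = xyz,
         n_unimers = n_unimers, n_residues = nres,
         spacing = spacing, radius = NA_real_, amide_offset = NA_real_,
         arrangement = "antiparallel", registry_rotation = NA_real_,
         axis = axis),
    class = "nanotube_model")

  if (n_frames > 1L && !is.null(frame_dt)) {
    structure(list(model = model, frames = frames,
                   n_frames = n_frames, frame_dt = frame_dt,
                   seed = NA_integer_),
              class = "nanotube_trajectory")
  } else model
}
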