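# Idealized cyclic D,L-peptide nanotube geometry.
#
# A cyclic peptide of alternating D- and L-residues adopts a flat ring with
# the backbone amides perpendicular to the ring plane, so rings stack into
# beta-sheet-like nanotubes held by inter-ring N-H...O=C hydrogen bonds.
# Only the four backbone sites that define those bonds are modelled per
# residue: amide nitrogen N, amide hydrogen H, carbonyl carbon C and
# carbonyl oxygen O. Sidechains and the polymer corona carry no hydrogen
# bonds of interest and are omitted.

# Bond lengths used to place H and O along the tube axis (Angstrom).
.NH_BOND <- 1.0
.CO_BOND <- 1.23

#' Build one idealized cyclic peptide ring
#'
#' Constructs a planar ring of `n_residues` backbone amide units. Residue
#' `i` sits at angle `2*pi*(i-1)/n_residues` on a circle of radius `radius`
#' in the z = 0 plane. The amide face alternates around the ring (the
#' alternating D/L chirality pattern): odd residues point their N-H along
#' +z, even residues along -z. The N atom is displaced by `amide_offset`
#' along the face direction, H sits one N-H bond length beyond it; the
#' carbonyl C and O are displaced oppositely, so each face exposes
#' `n_residues/2` donors (H out) and `n_residues/2` acceptors (O out).
#'
#' @param n_residues Even integer >= 4. An alternating D/L chirality
#'   pattern closes only for an even residue count.
#' @param radius Ring radius in Angstrom (backbone circle).
#' @param amide_offset Axial displacement of N (and C) from the ring plane,
#'   Angstrom. Sets the ideal inter-ring N...O distance:
#'   `spacing - 2*amide_offset - 1.23`.
#' @return An object of class `ring_geometry`: per-residue coordinates of
#'   N, H, C, O (matrices `n_residues` x 3, Angstrom) plus the `face`
#'   vector (+1/-1, direction of each residue's N-H).
#' @examples
#' ring <- build_ring(8)
#' sum(ring$face > 0)  # 4 donors on the +z face
#' @export
build_ring <- function(n_residues = 8L, radius = 4.0, amide_offset = 0.5) {
  n_residues <- as.integer(n_residues)
  if (length(n_residues) != 1L || is.na(n_residues) || n_residues < 4L)
    stop("n_residues must be a single integer >= 4", call. = FALSE)
  if (n_residues %% 2L != 0L)
    stop("invalid chirality pattern: an alternating D,L cyclic peptide ",
         "requires an even number of residues, got ", n_residues,
         call. = FALSE)
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("radius must be a positive number (Angstrom)", call. = FALSE)
  if (!is.numeric(amide_offset) || length(amide_offset) != 1L ||
      amide_offset <= 0)
    stop("amide_offset must be a positive number (Angstrom)", call. = FALSE)

  i <- seq_len(n_residues)
  phi <- 2 * pi * (i - 1) / n_residues
  face <- ifelse(i %% 2L == 1L, 1L, -1L)   # alternates strictly
  base <- cbind(radius * cos(phi), radius * sin(phi), 0)

  z <- function(h) cbind(0, 0, h)
  N <- base + z(face * amide_offset)
  H <- N + z(face * .NH_BOND)
  C <- base - z(face * amide_offset)
  O <- C - z(face * .CO_BOND)

  structure(
    list(n_residues = n_residues, radius = radius,
         amide_offset = amide_offset, face = face,
         N = N, H = H, C = C, O = O),
    class = "ring_geometry")
}

# Rigid transform applied to every atom matrix of a ring.
.transform_ring <- function(ring, rot = diag(3), shift = c(0, 0, 0)) {
  for (a in c("N", "H", "C", "O"))
    ring[[a]] <- sweep(ring[[a]] %*% t(rot), 2, shift, "+")
  ring
}

.rotz <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

# 180-degree rotation about x: flips a ring upside down (antiparallel).
.flip_x <- diag(c(1, -1, -1))

#' Stack rings into a nanotube model
#'
#' Places `n_unimers` copies of `ring` along the +z axis at intervals of
#' `spacing`. In the antiparallel arrangement every second ring is flipped
#' (180 degrees about x, reversing its amide faces) and rotated about the
#' axis by `registry_rotation` degrees so that each donor column on one
#' ring face sits head-on over an acceptor column on the neighbouring face.
#' For a flipped ring the donor/acceptor roles of the two residue parity
#' classes swap, which offsets the columns by half the residue spacing
#' twice, i.e. a full `360/n_residues`; that angle is therefore the default
#' registry restoring perfect donor-over-acceptor alignment.
#'
#' @param ring A `ring_geometry` from [build_ring()].
#' @param n_unimers Number of stacked rings (>= 1).
#' @param spacing Centroid-to-centroid distance between adjacent rings,
#'   Angstrom. Default 4.85, the beta-sheet-like stacking repeat.
#' @param arrangement `"antiparallel"` (default) or `"parallel"`.
#' @param registry_rotation Rotation (degrees) applied to alternate rings.
#'   `NULL` selects `360/n_residues` for antiparallel and 0 for parallel.
#' @return An object of class `nanotube_model` with an atom table
#'   (`$atoms`: ring, residue, atom name, face) and coordinate matrix
#'   (`$xyz`, n_atoms x 3, Angstrom), plus the stacking parameters.
#' @examples
#' tube <- stack_rings(build_ring(8), n_unimers = 8)
#' n_interfaces(tube)  # 7
#' @export
stack_rings <- function(ring, n_unimers, spacing = 4.85,
                        arrangement = c("antiparallel", "parallel"),
                        registry_rotation = NULL) {
  stopifnot(inherits(ring, "ring_geometry"))
  n_unimers <- as.integer(n_unimers)
  if (length(n_unimers) != 1L || is.na(n_unimers) || n_unimers < 1L)
    stop("n_unimers must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("spacing must be a positive number (Angstrom)", call. = FALSE)
  arrangement <- match.arg(arrangement)
  if (is.null(registry_rotation))
    registry_rotation <-
      if (arrangement == "antiparallel") 360 / ring$n_residues else 0

  nres <- ring$n_residues
  atom_names <- c("N", "H", "C", "O")
  rings <- vector("list", n_unimers)
  for (k in seq_len(n_unimers)) {
    rk <- ring
    flipped <- arrangement == "antiparallel" && k %% 2L == 0L
    if (flipped) {
      rk <- .transform_ring(rk, rot = .flip_x)
      rk$face <- -rk$face
    }
    if (k %% 2L == 0L && registry_rotation != 0)
      rk <- .transform_ring(rk, rot = .rotz(registry_rotation))
    rk <- .transform_ring(rk, shift = c(0, 0, (k - 1) * spacing))
    rings[[k]] <- rk
  }

  xyz <- do.call(rbind, lapply(rings, function(r)
    do.call(rbind, lapply(atom_names, function(a) r[[a]]))))
  atoms <- do.call(rbind, lapply(seq_len(n_unimers), function(k)
    data.frame(ring = k,
               residue = rep(seq_len(nres), times = length(atom_names)),
               atom = rep(atom_names, each = nres),
               face = rep(rings[[k]]$face, times = length(atom_names)))))
  # reorder so atoms of one residue are contiguous: ring, residue, N,H,C,O
  ord <- order(atoms$ring, atoms$residue,
               match(atoms$atom, atom_names))
  atoms <- atoms[ord, , drop = FALSE]
  xyz <- xyz[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  dimnames(xyz) <- NULL

  structure(
    list(atoms = atoms, xyz = xyz,
         n_unimers = n_unimers, n_residues = nres,
         spacing = spacing, radius = ring$radius,
         amide_offset = ring$amide_offset,
         arrangement = arrangement,
         registry_rotation = registry_rotation,
         axis = c(0, 0, 1)),
    class = "nanotube_model")
}

#' Number of inter-ring interfaces in a model
#' @param model A `nanotube_model`.
#' @export
n_interfaces <- function(model) model$n_unimers - 1L

#' Cap/core class of each interface
#'
#' The two terminal rings are the capping unimers; the interfaces they form
#' (the first and the last) are cap interfaces, all others core. A dimer's
#' single interface is cap.
#'
#' @param n_unimers Number of rings in the stack (>= 2).
#' @return Character vector of length `n_unimers - 1`, values `"cap"` or
#'   `"core"`, named by interface index.
#' @export
interface_classes <- function(n_unimers) {
  n_unimers <- as.integer(n_unimers)
  if (n_unimers < 2L) stop("need at least 2 unimers to have an interface",
                           call. = FALSE)
  ni <- n_unimers - 1L
  cls <- rep("core", ni)
  cls[unique(c(1L, ni))] <- "cap"
  names(cls) <- seq_len(ni)
  cls
}

#' Per-ring backbone centroids of one coordinate frame
#'
#' @param xyz n_atoms x 3 coordinate matrix (one frame).
#' @param atoms Atom table of the model (`model$atoms`).
#' @return n_rings x 3 matrix of centroids (over all backbone sites).
#' @export
ring_centroids <- function(xyz, atoms) {
  stopifnot(nrow(xyz) == nrow(atoms))
  idx <- split(seq_len(nrow(atoms)), atoms$ring)
  t(vapply(idx, function(j) colMeans(xyz[j, , drop = FALSE]),
           numeric(3)))
}

#' Apply a rigid-body transform to coordinates
#'
#' @param xyz n x 3 coordinate matrix.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 translation vector (Angstrom).
#' @export
apply_rigid_transform <- function(xyz, rotation = diag(3),
                                  translation = c(0, 0, 0)) {
  sweep(xyz %*% t(rotation), 2, translation, "+")
}

#' Model metadata as a plain list (JSON-ready)
#' @param model A `nanotube_model`.
#' @export
model_metadata <- function(model) {
  list(n_unimers = model$n_unimers,
       n_residues = model$n_residues,
       n_atoms = nrow(model$atoms),
       spacing_A = model$spacing,
       radius_A = model$radius,
       amide_offset_A = model$amide_offset,
       arrangement = model$arrangement,
       registry_rotation_deg = model$registry_rotation,
       n_interfaces = n_interfaces(model),
       max_hbonds = model$n_residues * max(0L, n_interfaces(model)))
}

#' @export
print.nanotube_model <- function(x, ...) {
  cat(sprintf(
    "<nanotube_model> %d rings x %d residues (%s), spacing %.2f A\n",
    x$n_unimers, x$n_residues, x$arrangement, x$spacing))
  cat(sprintf("  %d interfaces, up to %d backbone H-bonds\n",
              n_interfaces(x), x$n_residues * max(0L, n_interfaces(x))))
  invisible(x)
}
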