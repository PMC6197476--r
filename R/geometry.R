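# Coordinate-level primitives: Rg, Kabsch superposition, distances, angles,
# backbone torsion rotation. All lengths in Angstrom, all angles in degrees
# at the API surface.

#' Rigid-body transform
#'
#' @param rotation 3x3 proper rotation matrix (det +1)
#' @param translation length-3 vector, Angstrom
#' @return object of class `saxs_transform`
#' @export
saxs_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3))) stopf("rotation must be 3x3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6) {
    stopf("rotation must be orthonormal with det +1")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "saxs_transform")
}

#' Apply a rigid transform to coordinates or a structure
#'
#' Maps x to R x + t. When applied to a structure, any recorded symmetry
#' frames in `info` (entries with `center`/`axes`) are transformed too.
#'
#' @param x N x 3 matrix or `saxs_structure`
#' @param tr a `saxs_transform`
#' @return transformed object of the same type
#' @export
apply_transform <- function(x, tr) {
  if (inherits(x, "saxs_structure")) {
    s <- set_coords(x, apply_transform(coords(x), tr))
    for (nm in names(s$info)) {
      fr <- s$info[[nm]]
      if (is.list(fr) && !is.null(fr$center) && !is.null(fr$axes)) {
        fr$center <- as.numeric(tr$rotation %*% fr$center + tr$translation)
        fr$axes <- fr$axes %*% t(tr$rotation)
        s$info[[nm]] <- fr
      }
    }
    return(s)
  }
  sweep(as.matrix(x) %*% t(tr$rotation), 2, -tr$translation)
}

#' Invert a rigid transform
#' @param tr a `saxs_transform`
#' @return the inverse `saxs_transform`
#' @export
invert_transform <- function(tr) {
  saxs_transform(t(tr$rotation),
                 as.numeric(-t(tr$rotation) %*% tr$translation))
}

#' Compose two rigid transforms (apply `a` then `b`)
#' @param a,b `saxs_transform` objects
#' @return the composed `saxs_transform`
#' @export
compose_transforms <- function(a, b) {
  saxs_transform(b$rotation %*% a$rotation,
                 as.numeric(b$rotation %*% a$translation + b$translation))
}

#' Rotation about an arbitrary axis (Rodrigues)
#'
#' @param axis direction vector (normalized internally)
#' @param angle_deg rotation angle, degrees, right-handed about `axis`
#' @param center point on the axis (default origin)
#' @return a `saxs_transform`
#' @export
axis_rotation <- function(axis, angle_deg, center = c(0, 0, 0)) {
  k <- unit(axis)
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  # enforce exact orthonormality against accumulated rounding
  sv <- svd(R)
  R <- sv$u %*% t(sv$v)
  saxs_transform(R, as.numeric(center - R %*% center))
}

#' Radius of gyration
#'
#' Rg^2 = sum(w_i |r_i - rbar|^2) / sum(w_i), with rbar the weighted
#' centroid.
#'
#' @param s a `saxs_structure` (or N x 3 coordinate matrix)
#' @param weights per-atom positive weights; default uniform
#' @return Rg in Angstrom
#' @export
radius_of_gyration <- function(s, weights = NULL) {
  xyz <- if (inherits(s, "saxs_structure")) coords(s) else as.matrix(s)
  n <- nrow(xyz)
  if (is.null(n) || n < 1) stopf("radius_of_gyration needs at least one atom")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w <= 0)) stopf("weights must be positive, one per atom")
  ctr <- colSums(xyz * w) / sum(w)
  d2 <- rowSums(sweep(xyz, 2, ctr)^2)
  sqrt(sum(w * d2) / sum(w))
}

centroid <- function(xyz) colMeans(as.matrix(xyz))

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rotation+translation taking `mobile` onto `reference`,
#' computed over paired atom selections; the transform applies to all atoms
#' of `mobile`.
#'
#' @param mobile,reference `saxs_structure` objects (or coordinate matrices)
#' @param sel_mobile,sel_reference equal-length atom index vectors (>= 3,
#'   non-degenerate); default: all atoms (requires equal atom counts)
#' @return list with `transform` (a `saxs_transform`), `rmsd` over the
#'   selection, and `aligned` (mobile with the transform applied) when the
#'   input was a structure
#' @export
superpose <- function(mobile, reference, sel_mobile = NULL,
                      sel_reference = NULL) {
  xm <- if (inherits(mobile, "saxs_structure")) coords(mobile) else as.matrix(mobile)
  xr <- if (inherits(reference, "saxs_structure")) coords(reference) else as.matrix(reference)
  if (is.null(sel_mobile)) sel_mobile <- seq_len(nrow(xm))
  if (is.null(sel_reference)) sel_reference <- seq_len(nrow(xr))
  if (is.character(sel_mobile)) sel_mobile <- label_indices(mobile, sel_mobile)
  if (is.character(sel_reference)) sel_reference <- label_indices(reference, sel_reference)
  if (length(sel_mobile) != length(sel_reference)) {
    stopf("paired selections must have equal size")
  }
  if (length(sel_mobile) < 3) stopf("superposition needs >= 3 paired atoms")
  A <- xm[sel_mobile, , drop = FALSE]
  B <- xr[sel_reference, , drop = FALSE]
  ca <- centroid(A); cb <- centroid(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  # degenerate (collinear or coincident) selections have rank < 2 covariance
  if (qr(Ac)$rank < 2) stopf("degenerate selection: atoms coincident or collinear")
  H <- t(Ac) %*% Bc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- saxs_transform(R, as.numeric(cb - R %*% ca))
  rmsd <- sqrt(mean(rowSums((apply_transform(A, tr) - B)^2)))
  out <- list(transform = tr, rmsd = rmsd)
  if (inherits(mobile, "saxs_structure")) {
    out$aligned <- apply_transform(mobile, tr)
  }
  out
}

#' Minimum inter-structure atom distance
#'
#' The quantity monitored by the assembly clash filter: structures are
#' rejected when any inter-structure pair is closer than the threshold
#' (strict inequality; an exactly-threshold pair passes).
#'
#' @param a,b `saxs_structure` objects or coordinate matrices, non-empty
#' @param below optional early-exit threshold: return as soon as a pair
#'   closer than `below` is seen (the returned value is then just some
#'   distance `< below`, sufficient for a verdict)
#' @return minimum distance in Angstrom
#' @export
min_pair_distance <- function(a, b, below = 0) {
  xa <- if (inherits(a, "saxs_structure")) coords(a) else as.matrix(a)
  xb <- if (inherits(b, "saxs_structure")) coords(b) else as.matrix(b)
  if (nrow(xa) < 1 || nrow(xb) < 1) stopf("min_pair_distance needs non-empty inputs")
  .min_dist(xa, xb, below)
}

#' Angle subtended at a vertex
#'
#' @param p1,vertex,p2 length-3 points; `p1 != vertex != p2`
#' @return angle in degrees, in [0, 180]
#' @export
three_point_angle <- function(p1, vertex, p2) {
  u <- as.numeric(p1) - as.numeric(vertex)
  v <- as.numeric(p2) - as.numeric(vertex)
  if (vnorm(u) < 1e-9 || vnorm(v) < 1e-9) {
    stopf("three_point_angle: coincident points")
  }
  cosang <- sum(unit(u) * unit(v))
  rad2deg(acos(max(-1, min(1, cosang))))
}

# ---- Backbone dihedrals -----------------------------------------------------

# Locate one backbone atom (N/CA/C) of (chain, resno); NA if absent.
backbone_atom <- function(s, chain, resno, name) {
  i <- which(s$atoms$chain == chain & s$atoms$resno == resno &
             s$atoms$elety == name)
  if (length(i) != 1) NA_integer_ else i
}

# IUPAC dihedral: cis = 0, counterclockwise positive looking from atom 1 to
# atom 4.
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / vnorm(b2)
  rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
}

# The four backbone atom indices defining phi or psi of (chain, resno).
dihedral_atoms <- function(s, chain, resno, angle_name) {
  angle_name <- match.arg(tolower(angle_name), c("phi", "psi"))
  if (angle_name == "phi") {
    idx <- c(backbone_atom(s, chain, resno - 1L, "C"),
             backbone_atom(s, chain, resno, "N"),
             backbone_atom(s, chain, resno, "CA"),
             backbone_atom(s, chain, resno, "C"))
  } else {
    idx <- c(backbone_atom(s, chain, resno, "N"),
             backbone_atom(s, chain, resno, "CA"),
             backbone_atom(s, chain, resno, "C"),
             backbone_atom(s, chain, resno + 1L, "N"))
  }
  if (anyNA(idx)) {
    stopf("residue %s/%d lacks the backbone atoms for %s", chain, resno,
          angle_name)
  }
  idx
}

#' Measure a backbone dihedral
#'
#' @param s a `saxs_structure` with N/CA/C backbone atoms at the pivot
#' @param chain chain id
#' @param resno residue number
#' @param angle_name `"phi"` or `"psi"`
#' @return dihedral in degrees (IUPAC convention)
#' @export
measure_dihedral <- function(s, chain, resno, angle_name) {
  idx <- dihedral_atoms(s, chain, resno, angle_name)
  xyz <- coords(s)
  dihedral_angle(xyz[idx[1], ], xyz[idx[2], ], xyz[idx[3], ], xyz[idx[4], ])
}

# Atom indices rotated by a phi/psi pivot: everything C-terminal of the
# rotated bond within the same chain (atom order is chain order). Inter-chain
# links are not connectivity.
torsion_downstream <- function(s, chain, resno, angle_name) {
  idx <- dihedral_atoms(s, chain, resno, angle_name)
  bond_end <- idx[3]  # CA for phi, C for psi: atoms strictly after it move
  chain_atoms <- which(s$atoms$chain == chain)
  chain_atoms[chain_atoms > bond_end]
}

#' Rotate a backbone torsion
#'
#' Rotates all atoms C-terminal of the pivot bond (within the pivot's chain)
#' by `delta` degrees about the bond axis, increasing the measured dihedral
#' by `delta`. Bond lengths and angles are untouched; upstream atoms do not
#' move.
#'
#' @param s a `saxs_structure`
#' @param chain chain id of the pivot residue
#' @param resno residue number of the pivot residue
#' @param angle_name `"phi"` or `"psi"`
#' @param delta rotation in degrees
#' @return the rotated `saxs_structure`
#' @export
apply_torsion <- function(s, chain, resno, angle_name, delta) {
  idx <- dihedral_atoms(s, chain, resno, angle_name)
  if (abs(delta) < 1e-15) return(s)
  xyz <- coords(s)
  axis_from <- xyz[idx[2], ]
  axis_to <- xyz[idx[3], ]
  moving <- torsion_downstream(s, chain, resno, angle_name)
  if (!length(moving)) return(s)
  # axis oriented so that a positive delta increases the measured
  # (IUPAC-convention) dihedral by delta
  tr <- axis_rotation(axis_from - axis_to, delta, center = axis_from)
  xyz[moving, ] <- apply_transform(xyz[moving, , drop = FALSE], tr)
  set_coords(s, xyz)
}
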