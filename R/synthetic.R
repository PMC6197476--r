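# Toy-structure and synthetic-profile generators. These stand in for the
# real inputs of the analysis (a homology-model antibody, a crystal-structure
# tetramer, docked poses, and reduced experimental SAXS data) with the same
# statistical structure at desk scale: compact pseudo-atom domains, a real
# polypeptide hinge with ideal backbone geometry, exact D2 antigen symmetry,
# and Q-dependent Gaussian counting noise. Every generator is a pure
# function of (config, seed).

IDEAL_N_CA <- 1.458
IDEAL_CA_C <- 1.525
IDEAL_C_N <- 1.329
# zigzag half-angle giving a 114-degree backbone bond angle
ZIGZAG_DEG <- 33

#' Toy-structure build configuration
#'
#' @param domain_radius radius of each compact pseudo-domain, Angstrom
#' @param atoms_per_domain pseudo-atoms per domain (>= 10)
#' @param hinge_length hinge residue count (>= 3)
#' @param seed integer RNG seed
#' @param lattice_spacing lattice constant for the jittered atom lattice;
#'   `NULL` derives it from the domain volume and atom count
#' @param arm_angle_deg angle between the two antibody arms at the central
#'   domain, degrees (antibody generator only)
#' @return object of class `toy_build_config`
#' @export
toy_build_config <- function(domain_radius = 25, atoms_per_domain = 150,
                             hinge_length = 5, seed = 1,
                             lattice_spacing = NULL, arm_angle_deg = 80) {
  if (domain_radius <= 0) stopf("domain_radius must be > 0")
  if (atoms_per_domain < 10) stopf("atoms_per_domain must be >= 10")
  if (hinge_length < 3) stopf("hinge_length must be >= 3")
  if (is.null(lattice_spacing)) {
    lattice_spacing <- (4 / 3 * pi * domain_radius^3 / atoms_per_domain)^(1 / 3)
  }
  if (lattice_spacing <= 0) stopf("lattice_spacing must be > 0")
  structure(list(domain_radius = domain_radius,
                 atoms_per_domain = atoms_per_domain,
                 hinge_length = as.integer(hinge_length),
                 seed = as.integer(seed),
                 lattice_spacing = lattice_spacing,
                 arm_angle_deg = arm_angle_deg),
            class = "toy_build_config")
}

# Jittered-lattice ball: `n` carbon-like point scatterers filling a sphere
# of radius `r`, centred on the origin. Cheap Debye sums with realistic Rg
# and P(r) shapes. Deterministic for a given RNG state.
domain_cloud <- function(r, n, spacing) {
  k <- ceiling(r / spacing) + 1L
  g <- expand.grid(x = (-k:k) * spacing, y = (-k:k) * spacing,
                   z = (-k:k) * spacing)
  g <- as.matrix(g)
  d <- sqrt(rowSums(g^2))
  ord <- order(d)
  g <- g[ord[seq_len(min(n, nrow(g)))], , drop = FALSE]
  while (nrow(g) < n) {  # spacing too coarse for n points: refine
    spacing <- spacing * 0.8
    return(domain_cloud(r, n, spacing))
  }
  g <- g + matrix(runif(3 * n, -0.3, 0.3) * spacing, n, 3)
  sweep(g, 2, colMeans(g))
}

# Extended-backbone hinge: `nres` residues of N/CA/C atoms zigzagging along
# `u` (in the plane spanned by u and vperp), all bond lengths ideal.
# Returns list(xyz, names).
hinge_backbone <- function(start, u, vperp, nres) {
  u <- unit(u); vperp <- unit(vperp - sum(vperp * u) * u)
  lens <- rep(c(IDEAL_N_CA, IDEAL_CA_C, IDEAL_C_N), nres)[seq_len(3 * nres - 1)]
  ca <- cos(deg2rad(ZIGZAG_DEG)); sa <- sin(deg2rad(ZIGZAG_DEG))
  xyz <- matrix(0, 3 * nres, 3)
  xyz[1, ] <- start
  sgn <- 1
  for (b in seq_along(lens)) {
    d <- ca * u + sgn * sa * vperp
    xyz[b + 1L, ] <- xyz[b, ] + lens[b] * d
    sgn <- -sgn
  }
  list(xyz = xyz, names = rep(c("N", "CA", "C"), nres))
}

toy_atoms <- function(xyz, chain, resno, elety, resid, element) {
  data.frame(serial = seq_len(nrow(xyz)), chain = chain, resno = resno,
             resid = resid, elety = elety, element = element,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Toy Y-shaped antibody
#'
#' Three compact pseudo-domains (two antigen-binding arms `Fab1`, `Fab2` and
#' a central `Fc`) joined by two polypeptide hinges with ideal backbone
#' geometry, as one connected chain `A` ordered
#' Fab1 - hinge1 - Fc - hinge2 - Fab2. The two Fab clouds are congruent
#' (one is a rotated copy of the other) so rigid alignment between Fab
#' copies is exact. Hinge residues carry valid phi/psi pivots; the default
#' pivot set (interior hinge residues, the analogue of upper-hinge residues
#' of a real heavy chain) is stored in `info$default_pivots`.
#'
#' Labels: `Fab1`, `Fab2`, `Fc` (domains), `hinge1`, `hinge2`,
#' `paratope1`/`paratope2` (distal binding faces), `anchor1`/`anchor2`
#' (single Fc-proximal hinge atoms, the toy analogue of the heavy-chain
#' residue-211 C-alpha used by the ring-closure filter).
#'
#' @param cfg a `toy_build_config`
#' @return a `saxs_structure`
#' @export
make_toy_antibody <- function(cfg = toy_build_config()) {
  stopifnot(inherits(cfg, "toy_build_config"))
  with_seed(cfg$seed, {
    R <- cfg$domain_radius
    n <- cfg$atoms_per_domain
    h <- cfg$hinge_length
    pad <- 2.5
    # hinge end-to-end span along its axis
    lens <- rep(c(IDEAL_N_CA, IDEAL_CA_C, IDEAL_C_N), h)[seq_len(3 * h - 1)]
    span <- sum(lens) * cos(deg2rad(ZIGZAG_DEG))
    L <- 2 * R + 2 * pad + span
    alpha <- deg2rad(cfg$arm_angle_deg / 2)
    u1 <- c(sin(alpha), cos(alpha), 0)
    u2 <- c(-sin(alpha), cos(alpha), 0)
    rot12 <- axis_rotation(c(0, 0, 1), cfg$arm_angle_deg)$rotation

    fab_cloud <- domain_cloud(R, n, cfg$lattice_spacing)
    fc_cloud <- domain_cloud(R, n, cfg$lattice_spacing)
    fab1 <- sweep(fab_cloud, 2, -L * u1)          # at L*u1
    fab2 <- sweep(fab_cloud %*% t(rot12), 2, -L * u2)
    hin1 <- hinge_backbone((L - R - pad) * u1, -u1, c(0, 0, 1), h)
    hin2 <- hinge_backbone((R + pad) * u2, u2, c(0, 0, 1), h)

    res <- 0L
    blocks <- list(
      list(xyz = fab1, elety = "CA", resid = "ALA", element = "C",
           per_res = 1L),
      list(xyz = hin1$xyz, elety = hin1$names, resid = "GLY",
           element = ifelse(hin1$names == "N", "N", "C"), per_res = 3L),
      list(xyz = fc_cloud, elety = "CA", resid = "ALA", element = "C",
           per_res = 1L),
      list(xyz = hin2$xyz, elety = hin2$names, resid = "GLY",
           element = ifelse(hin2$names == "N", "N", "C"), per_res = 3L),
      list(xyz = fab2, elety = "CA", resid = "ALA", element = "C",
           per_res = 1L))
    atoms_list <- list()
    ranges <- list()
    res_ranges <- list()
    at0 <- 0L
    for (bi in seq_along(blocks)) {
      b <- blocks[[bi]]
      nb <- nrow(b$xyz)
      nres <- nb %/% b$per_res
      resno <- res + rep(seq_len(nres), each = b$per_res)
      atoms_list[[bi]] <- toy_atoms(b$xyz, "A", resno, b$elety, b$resid,
                                    b$element)
      ranges[[bi]] <- at0 + seq_len(nb)
      res_ranges[[bi]] <- c(res + 1L, res + nres)
      res <- res + nres
      at0 <- at0 + nb
    }
    atoms <- do.call(rbind, atoms_list)
    atoms$serial <- seq_len(nrow(atoms))

    # distal binding faces: outer cap of each Fab along its arm direction
    proj1 <- (fab1 %*% u1) - L
    proj2 <- (fab2 %*% u2) - L
    paratope_local <- which(proj1 > 0.5 * R)  # same cloud indices both arms
    labels <- list(
      Fab1 = ranges[[1]], hinge1 = ranges[[2]], Fc = ranges[[3]],
      hinge2 = ranges[[4]], Fab2 = ranges[[5]],
      paratope1 = ranges[[1]][paratope_local],
      paratope2 = ranges[[5]][which(proj2 > 0.5 * R)],
      # Fc-proximal hinge C-alphas: hinge1 last residue, hinge2 first residue
      anchor1 = ranges[[2]][3L * (h - 1L) + 2L],
      anchor2 = ranges[[4]][2L])
    hr1 <- res_ranges[[2]]; hr2 <- res_ranges[[4]]
    piv <- rbind(
      expand.grid(chain = "A", resno = (hr1[1] + 1L):(hr1[2] - 1L),
                  angle = c("phi", "psi"), stringsAsFactors = FALSE),
      expand.grid(chain = "A", resno = (hr2[1] + 1L):(hr2[2] - 1L),
                  angle = c("phi", "psi"), stringsAsFactors = FALSE))
    info <- list(default_pivots = piv,
                 units = c("Fab1", "hinge1", "Fc", "hinge2", "Fab2"),
                 arm_length = L, kind = "toy_antibody")
    saxs_structure(atoms, labels, info)
  })
}

#' Toy D2-symmetric tetramer antigen
#'
#' Four identical compact pseudo-subunits placed as exact images of one
#' subunit under the D2 rotations about the x and y axes (plus their
#' product), centre of mass exactly at the origin. The two orthogonal
#' 2-fold axes are recorded as a geometric frame in `info$c2`
#' (`center`, `axes` rows), which rigid transforms carry along.
#'
#' Labels: `sub1` .. `sub4`.
#'
#' @param cfg a `toy_build_config`; `domain_radius` is the subunit radius
#' @return a `saxs_structure`
#' @export
make_toy_tetramer <- function(cfg = toy_build_config(domain_radius = 18,
                                                     atoms_per_domain = 110)) {
  stopifnot(inherits(cfg, "toy_build_config"))
  with_seed(cfg$seed, {
    R <- cfg$domain_radius
    n <- cfg$atoms_per_domain
    cloud <- domain_cloud(R, n, cfg$lattice_spacing)
    d <- 1.285 * R  # subunit-centre distance from origin (near-contact packing)
    c0 <- d * c(1, 1, 1) / sqrt(3)
    sub0 <- sweep(cloud, 2, -c0)
    rots <- list(diag(3),
                 diag(c(1, -1, -1)),   # C2 about x
                 diag(c(-1, 1, -1)),   # C2 about y
                 diag(c(-1, -1, 1)))   # product
    atoms_list <- list()
    labels <- list()
    at0 <- 0L
    for (k in 1:4) {
      xyz <- sub0 %*% t(rots[[k]])
      atoms_list[[k]] <- toy_atoms(xyz, LETTERS[k], seq_len(n), "CA", "SUB",
                                   "C")
      labels[[paste0("sub", k)]] <- at0 + seq_len(n)
      at0 <- at0 + n
    }
    atoms <- do.call(rbind, atoms_list)
    atoms$serial <- seq_len(nrow(atoms))
    info <- list(c2 = list(center = c(0, 0, 0),
                           axes = rbind(c(1, 0, 0), c(0, 1, 0))),
                 kind = "toy_tetramer")
    saxs_structure(atoms, labels, info)
  })
}

#' Extract one antigen-binding arm as a standalone Fab
#'
#' The extract keeps the arm's cloud in its antibody frame, relabelled
#' `fabatoms` (all atoms) and `paratope` (the distal binding face). The
#' hinge is not part of the extract; ring-closure anchors stay with the
#' antibody.
#'
#' @param ab a toy antibody
#' @param which 1 or 2, which arm
#' @return a `saxs_structure` with labels `fabatoms`, `paratope`
#' @export
extract_fab <- function(ab, which = 1) {
  fl <- if (which == 1) "Fab1" else "Fab2"
  pl <- if (which == 1) "paratope1" else "paratope2"
  idx <- label_indices(ab, fl)
  s <- extract_structure(ab, idx)
  # re-map the paratope label into the extract
  par <- match(label_indices(ab, pl), idx)
  s$labels <- list(fabatoms = seq_len(n_atoms(s)), paratope = sort(par))
  s$info <- list(kind = "toy_fab")
  s
}

#' Rigidly dock a Fab onto one antigen subunit
#'
#' Stands in for a docking run: the antigen is rotated (seeded spin about
#' the approach axis and alignment of the chosen subunit toward the
#' paratope face) and translated so that the minimum Fab-antigen atom
#' distance comes out near `gap`. The Fab does not move.
#'
#' @param ab a Fab structure carrying a `paratope` label
#' @param ag an antigen with `sub1..sub4` labels and a recorded `c2` frame
#' @param subunit subunit label to dock against (default `"sub1"`)
#' @param gap target minimum inter-structure distance, Angstrom
#' @param seed integer seed (spin orientation)
#' @param max_retry placement retries before failing
#' @return combined `saxs_structure` with units `fab` and `antigen`
#' @export
make_docked_pose <- function(ab, ag, subunit = "sub1", gap = 4, seed = 1,
                             max_retry = 20) {
  par <- coords(ab, "paratope")
  fc_ctr <- centroid(coords(ab))
  w <- unit(centroid(par) - fc_ctr)
  with_seed(seed, {
    for (attempt in seq_len(max_retry)) {
      spin <- runif(1, 0, 360)
      agk <- ag
      # align chosen subunit direction against the approach axis
      v_s <- centroid(coords(agk, subunit)) - centroid(coords(agk))
      if (vnorm(v_s) > 1e-9) {
        axis <- cross3(unit(v_s), -w)
        ang <- three_point_angle(unit(v_s), c(0, 0, 0), -w)
        if (vnorm(axis) > 1e-9 && ang > 1e-9) {
          agk <- apply_transform(agk, axis_rotation(axis, ang,
                                                    centroid(coords(agk))))
        }
      }
      agk <- apply_transform(agk, axis_rotation(w, spin, centroid(coords(agk))))
      # start beyond contact, then walk the antigen in along the axis
      target <- centroid(par) + w * (gap + 2 * vnorm(
        centroid(coords(agk, subunit)) - centroid(coords(agk))) + 40)
      shift <- target - centroid(coords(agk, subunit))
      agk <- apply_transform(agk, saxs_transform(diag(3), shift))
      for (it in 1:8) {
        d <- min_pair_distance(ab, agk)
        if (abs(d - gap) < 0.2) break
        agk <- apply_transform(agk,
                               saxs_transform(diag(3), -w * (d - gap) * 0.9))
      }
      d <- min_pair_distance(ab, agk)
      if (d >= max(gap - 0.5, 0) && d <= gap + 2) {
        pose <- combine_structures(list(fab = ab, antigen = agk))
        pose$info$docked_subunit <- subunit
        pose$info$gap <- gap
        pose$info$min_distance <- d
        return(pose)
      }
    }
  })
  stopf("could not place antigen at gap %.2f A within %d retries", gap,
        max_retry)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Counting-noise model for synthetic profiles
#'
#' sigma(Q) = a * I(Q) * (1 + b * Q): a relative floor plus a
#' Q-proportional term, the monotone relative-error growth seen in real
#' size-exclusion SAXS.
#'
#' @param a relative noise floor (default 0.02)
#' @param b Q-proportional growth, Angstrom (default 5)
#' @param seed integer seed
#' @return object of class `noise_model`
#' @export
noise_model <- function(a = 0.02, b = 5, seed = 1) {
  if (a <= 0 || b < 0) stopf("need a > 0, b >= 0")
  structure(list(a = a, b = b, seed = as.integer(seed)),
            class = "noise_model")
}

#' Synthetic noisy scattering profile of a ground-truth structure
#'
#' Debye profile of `truth` plus additive Gaussian noise with standard
#' deviation sigma(Q) from the noise model; the sigma column is included.
#'
#' @param truth a `saxs_structure`
#' @param qgrid momentum-transfer grid, Angstrom^-1
#' @param noise a `noise_model`
#' @param ff form-factor table (default point scatterers)
#' @return a `saxs_profile` with sigma present
#' @export
make_synthetic_profile <- function(truth, qgrid, noise = noise_model(),
                                   ff = form_factor_table("point")) {
  clean <- debye_profile(truth, qgrid, ff)
  sig <- noise$a * clean$intensity * (1 + noise$b * clean$q)
  noisy <- with_seed(noise$seed,
                     clean$intensity + rnorm(length(sig), 0, sig))
  saxs_profile(clean$q, noisy, sig)
}

#' Artificially extended variant of an assembled complex
#'
#' Translates each rigid unit of a complex radially away from the overall
#' centroid, producing the kind of over-extended model that scattering data
#' of a compact particle must rank poorly.
#'
#' @param cplx an assembled complex with `info$topology$units`
#' @param factor radial expansion factor for unit centroids (> 1 extends)
#' @return the extended `saxs_structure`
#' @export
extend_complex <- function(cplx, factor = 2) {
  units <- cplx$info$topology$units
  if (is.null(units)) stopf("complex lacks topology unit metadata")
  ctr <- centroid(coords(cplx))
  xyz <- coords(cplx)
  for (u in units) {
    idx <- label_indices(cplx, u)
    uc <- centroid(xyz[idx, , drop = FALSE])
    xyz[idx, ] <- sweep(xyz[idx, , drop = FALSE], 2,
                        -( (factor - 1) * (uc - ctr)))
  }
  set_coords(cplx, xyz)
}
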