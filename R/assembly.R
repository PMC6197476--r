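# Rigid-body assembly of candidate antibody-antigen complexes from building
# blocks: symmetric replication of a docked Fab across an antigen 2-fold
# (Fab2-antigen blocks), attachment of full antibodies by Fab alignment,
# and the monodentate-chain / bidentate-ring builders. Structures are never
# deformed: every step is a rigid superposition followed by geometric
# acceptance filters (clash distance, arm angle window, ring anchor
# distance). There is no force field; the filters are the
# structure-determining steps.

#' Geometric acceptance filters for complex assembly
#'
#' @param clash_min reject when any newly apposed inter-unit atom pair is
#'   closer than this (strict inequality; exactly `clash_min` passes).
#'   Default 8.0 Angstrom.
#' @param angle_window admissible arm-arm angle at the central domain
#'   (Fab-Fc-Fab, computed between domain centroids), degrees; default
#'   [70, 90], the pre-filter for ring-forming antibody conformations
#' @param ring_calpha_max largest admissible distance between the anchor
#'   atoms (heavy-chain residue-211 analogues) of the two free Fab sites
#'   before ring closure; default 40 Angstrom
#' @param closure_tol largest admissible joint-superposition RMSD when the
#'   ring-closing antibody is placed onto the two free Fab sites, Angstrom.
#'   This replaces the energy minimization a production pipeline would run
#'   after closure.
#' @return object of class `assembly_filters`
#' @export
assembly_filters <- function(clash_min = 8.0, angle_window = c(70, 90),
                             ring_calpha_max = 40.0, closure_tol = 12) {
  if (clash_min <= 0) stopf("clash_min must be > 0")
  if (length(angle_window) != 2 || angle_window[1] > angle_window[2]) {
    stopf("angle_window must be a non-empty [lo, hi]")
  }
  if (ring_calpha_max <= 0) stopf("ring_calpha_max must be > 0")
  structure(list(clash_min = clash_min, angle_window = angle_window,
                 ring_calpha_max = ring_calpha_max,
                 closure_tol = closure_tol),
            class = "assembly_filters")
}

#' Arm-arm angle of an antibody
#'
#' Angle at the central-domain centroid between the two arm centroids
#' (the reference points are domain centroids).
#'
#' @param ab a structure with `Fab1`, `Fc`, `Fab2` labels
#' @return angle in degrees
#' @export
fab_fc_fab_angle <- function(ab) {
  three_point_angle(centroid(coords(ab, "Fab1")),
                    centroid(coords(ab, "Fc")),
                    centroid(coords(ab, "Fab2")))
}

# clash verdict: TRUE = passes (min distance >= clash_min; strict '<'
# rejects, boundary equality accepts)
clash_ok <- function(a, b, clash_min) {
  min_pair_distance(a, b, below = clash_min) >= clash_min
}

#' Symmetric replication of a docked Fab across an antigen 2-fold
#'
#' The second Fab is a copy of the docked one rotated 180 degrees about a
#' recorded antigen 2-fold axis, producing a Fab2-antigen building block.
#' Rejected (reported, not fatal) when the two Fabs come closer than
#' `clash_min`.
#'
#' @param pose a docked pose with units `fab` and `antigen` (the antigen
#'   carrying a recorded `c2` frame)
#' @param axis which recorded 2-fold axis (row index, 1 or 2)
#' @param filters an `assembly_filters`
#' @return list: `structure` (units `fab1`, `fab2`, `antigen`; `NULL` on
#'   rejection), `accepted`, `min_fab_fab`
#' @export
symmetrize_pose <- function(pose, axis = 1, filters = assembly_filters()) {
  fr <- pose$info[["antigen.c2"]]
  if (is.null(fr)) stopf("pose has no recorded antigen 2-fold frame")
  tr <- axis_rotation(fr$axes[axis, ], 180, fr$center)
  fab1 <- extract_structure(pose, "fab")
  fab1$info <- list()
  fab2 <- apply_transform(fab1, tr)
  dmin <- min_pair_distance(fab1, fab2)
  if (dmin < filters$clash_min) {
    return(list(structure = NULL, accepted = FALSE, min_fab_fab = dmin))
  }
  ag <- extract_structure(pose, "antigen")
  ag$info <- list(c2 = fr)
  blk <- combine_structures(list(fab1 = fab1, fab2 = fab2, antigen = ag))
  blk$info$sym_axis <- axis
  blk$info$docked_subunit <- pose$info$docked_subunit
  list(structure = blk, accepted = TRUE, min_fab_fab = dmin)
}

# positional correspondence of a congruent Fab cloud, excluding the binding
# face (alignment regions exclude interfacial residues)
fab_align_subset <- function(ab, fab_label, paratope_label) {
  f <- label_indices(ab, fab_label)
  p <- label_indices(ab, paratope_label)
  which(!(f %in% p))  # positions within the Fab cloud
}

#' Align a full antibody onto an anchor Fab of a complex
#'
#' The antibody is superposed so that one of its arms lands exactly on the
#' anchor Fab (alignment over the arm cloud excluding the binding face, so
#' the docked pose is maintained); the complex does not move. Rejected when
#' any newly apposed pair (antibody minus the aligned arm, against the
#' whole complex) is closer than `clash_min`.
#'
#' @param ab a toy antibody
#' @param cplx the (partial) complex
#' @param anchor_fab label in `cplx` of the Fab to align onto
#' @param fab which antibody arm to align (1 or 2)
#' @param filters an `assembly_filters`
#' @return list: `structure` (the aligned antibody; `NULL` on rejection),
#'   `accepted`, `rmsd` (alignment), `min_clash`
#' @export
attach_antibody <- function(ab, cplx, anchor_fab, fab = 1,
                            filters = assembly_filters()) {
  fab_label <- if (fab == 1) "Fab1" else "Fab2"
  par_label <- if (fab == 1) "paratope1" else "paratope2"
  sub <- fab_align_subset(ab, fab_label, par_label)
  sel_mob <- label_indices(ab, fab_label)[sub]
  sel_ref <- label_indices(cplx, anchor_fab)[sub]
  sp <- superpose(ab, cplx, sel_mob, sel_ref)
  aligned <- sp$aligned
  rest <- extract_structure(aligned,
                            setdiff(seq_len(n_atoms(aligned)),
                                    label_indices(aligned, fab_label)))
  # the anchor Fab is overlaid by the antibody's own arm: contacts with it
  # are intramolecular, so it is excluded from the newly-apposed scan
  cplx_rest <- extract_structure(cplx,
                                 setdiff(seq_len(n_atoms(cplx)),
                                         label_indices(cplx, anchor_fab)))
  dmin <- min_pair_distance(rest, cplx_rest, below = filters$clash_min)
  if (dmin < filters$clash_min) {
    return(list(structure = NULL, accepted = FALSE, rmsd = sp$rmsd,
                min_clash = dmin))
  }
  list(structure = aligned, accepted = TRUE, rmsd = sp$rmsd, min_clash = dmin)
}

# assemble the final complex structure with topology metadata
finish_complex <- function(units, kind, edges, extra = list()) {
  cplx <- combine_structures(units)
  n_ab <- sum(startsWith(names(units), "ab"))
  n_ag <- sum(startsWith(names(units), "ag"))
  cplx$info$topology <- c(list(kind = kind, n_antibody = n_ab,
                               n_antigen = n_ag, units = names(units),
                               edges = edges), extra)
  cplx
}

draw_member <- function(e) {
  if (inherits(e, "saxs_ensemble")) {
    ensemble_member(e, sample.int(length(e), 1L))
  } else {
    e[[sample.int(length(e), 1L)]]
  }
}

as_member_list <- function(e) {
  if (inherits(e, "saxs_ensemble")) {
    lapply(seq_along(e$coords), function(i) ensemble_member(e, i))
  } else e
}

#' Build an ensemble of monodentate 2:2 complexes
#'
#' Chain topology antigen2 - antibody1 - antigen1(shared) - antibody2: two
#' full antibodies aligned onto the two Fabs of a shared Fab2-antigen
#' block, and a second antigen attached to a free arm of the first antibody
#' through a docked Fab-antigen pose. Every emitted member passes all
#' clash checks.
#'
#' @param fab2_blocks list/ensemble of Fab2-antigen blocks (from
#'   [symmetrize_pose()])
#' @param fab_poses list/ensemble of docked Fab-antigen poses (for the
#'   pendant antigen)
#' @param antibodies `saxs_ensemble` (or list) of antibody conformations
#' @param filters an `assembly_filters`
#' @param n_target accepted members wanted
#' @param seed integer seed
#' @param max_attempts attempt cap
#' @return `saxs_ensemble` of complexes (empty, with diagnostics attribute
#'   `attempts`, if nothing is accepted)
#' @export
build_monodentate_ensemble <- function(fab2_blocks, fab_poses, antibodies,
                                       filters = assembly_filters(),
                                       n_target = 10, seed = 1,
                                       max_attempts = 200 * max(1, n_target)) {
  blocks <- as_member_list(fab2_blocks)
  poses <- as_member_list(fab_poses)
  if (!length(blocks) || !length(poses)) stopf("empty input ensemble")
  members <- list()
  meta <- NULL
  template <- NULL
  attempts <- 0L
  with_seed(seed, {
    while (length(members) < n_target && attempts < max_attempts) {
      attempts <- attempts + 1L
      blk <- draw_member(fab2_blocks)
      a1 <- attach_antibody(draw_member(antibodies), blk, "fab1", fab = 1,
                            filters = filters)
      if (!a1$accepted) next
      # second antibody: clash against block (minus its own anchor fab) and
      # against the first antibody
      a2 <- attach_antibody(draw_member(antibodies), blk, "fab2", fab = 1,
                            filters = filters)
      if (!a2$accepted) next
      if (!clash_ok(extract_structure(
            a2$structure, setdiff(seq_len(n_atoms(a2$structure)),
                                  label_indices(a2$structure, "Fab1"))),
            a1$structure, filters$clash_min)) next
      # pendant antigen on antibody 1's free arm, via a docked pose
      pose <- draw_member(fab_poses)
      sub <- fab_align_subset(a1$structure, "Fab2", "paratope2")
      sp <- superpose(pose, a1$structure,
                      label_indices(pose, "fab")[sub],
                      label_indices(a1$structure, "Fab2")[sub])
      ag2 <- extract_structure(apply_transform(pose, sp$transform), "antigen")
      ab1_not_fab2 <- extract_structure(
        a1$structure, setdiff(seq_len(n_atoms(a1$structure)),
                              label_indices(a1$structure, "Fab2")))
      ag1 <- extract_structure(blk, "antigen")
      if (!clash_ok(ag2, ab1_not_fab2, filters$clash_min)) next
      if (!clash_ok(ag2, a2$structure, filters$clash_min)) next
      if (!clash_ok(ag2, ag1, filters$clash_min)) next
      cplx <- finish_complex(
        list(ag1 = ag1, ab1 = a1$structure, ab2 = a2$structure, ag2 = ag2),
        "monodentate",
        edges = list(c("ag2", "ab1"), c("ab1", "ag1"), c("ag1", "ab2")))
      if (is.null(template)) template <- cplx
      if (n_atoms(cplx) != n_atoms(template)) next  # mixed block sizes
      members[[length(members) + 1L]] <- coords(cplx)
      meta <- rbind(meta, data.frame(
        member = length(members), attempt = attempts,
        rg = radius_of_gyration(cplx), align_rmsd = sp$rmsd))
    }
  })
  if (is.null(template)) {
    e <- saxs_ensemble(saxs_structure(data.frame(
      serial = 1L, chain = "A", resno = 1L, resid = "GLY", elety = "CA",
      element = "C", x = 0, y = 0, z = 0)), list())
    attr(e, "attempts") <- attempts
    return(e)
  }
  e <- saxs_ensemble(template, members, meta)
  attr(e, "attempts") <- attempts
  e
}

# anchor point of the free Fab slot of a placed block: the image of the
# bound antibody's hinge anchor under the block's recorded antigen 2-fold
slot_anchor <- function(block, ab, which_fab) {
  fr <- block$info[["antigen.c2"]]
  tr <- axis_rotation(fr$axes[block$info$sym_axis, ], 180, fr$center)
  anchor <- coords(ab, if (which_fab == 1) "anchor1" else "anchor2")
  drop(apply_transform(anchor, tr))
}

#' Build an ensemble of bidentate (cyclic) 2:2 complexes
#'
#' Antibody conformations with arm angles inside the filter window are
#' collected first; a Fab2-antigen block is aligned onto each arm of a
#' selected antibody; the ring-closure distance between the anchor atoms
#' of the two free Fab sites is required to stay under `ring_calpha_max`;
#' finally a second angle-filtered antibody is placed by jointly
#' superposing both of its arms onto the two free sites (closure RMSD at
#' most `closure_tol`, standing in for post-assembly relaxation). Both
#' antigens end up doubly shared: the linkage graph is a single 4-cycle.
#'
#' @param antibodies `saxs_ensemble` (or list) of antibody conformations
#' @param fab2_blocks list/ensemble of Fab2-antigen blocks
#' @param filters an `assembly_filters`
#' @param n_target accepted members wanted
#' @param seed integer seed
#' @param max_attempts attempt cap
#' @param n_closure_candidates closing antibodies tried per ring
#' @return `saxs_ensemble` of complexes with per-member filter diagnostics
#' @export
build_bidentate_ensemble <- function(antibodies, fab2_blocks,
                                     filters = assembly_filters(),
                                     n_target = 10, seed = 1,
                                     max_attempts = 2500 * max(1, n_target),
                                     n_closure_candidates = 20) {
  abs_all <- as_member_list(antibodies)
  angles <- vapply(abs_all, fab_fc_fab_angle, 0)
  sel <- which(angles >= filters$angle_window[1] &
               angles <= filters$angle_window[2])
  members <- list()
  meta <- NULL
  template <- NULL
  attempts <- 0L
  arm_sep_all <- vapply(sel, function(ci) {
    vnorm(centroid(coords(abs_all[[ci]], "Fab1")) -
          centroid(coords(abs_all[[ci]], "Fab2")))
  }, 0)
  blocks <- as_member_list(fab2_blocks)
  if (length(sel) && length(blocks)) with_seed(seed, {
    ab_order <- sel[sample.int(length(sel))]
    for (ab_i in rep(ab_order, length.out = max_attempts)) {
      if (length(members) >= n_target || attempts >= max_attempts) break
      ab1 <- abs_all[[ab_i]]
      # place every block on each arm once, then enumerate pairs that
      # satisfy the ring-closure anchor distance (the rate-limiting filter)
      placed <- list()
      anchors <- list()
      for (k in 1:2) {
        fab_label <- if (k == 1) "Fab1" else "Fab2"
        par_label <- if (k == 1) "paratope1" else "paratope2"
        sub <- fab_align_subset(ab1, fab_label, par_label)
        rest <- extract_structure(
          ab1, setdiff(seq_len(n_atoms(ab1)), label_indices(ab1, fab_label)))
        placed[[k]] <- lapply(blocks, function(blk) {
          sp <- superpose(blk, ab1, label_indices(blk, "fab1")[sub],
                          label_indices(ab1, fab_label)[sub])
          p <- apply_transform(blk, sp$transform)
          if (!clash_ok(extract_structure(p, "antigen"), rest,
                        filters$clash_min)) return(NULL)
          p
        })
        anchors[[k]] <- lapply(placed[[k]], function(p) {
          if (is.null(p)) NULL else slot_anchor(p, ab1, k)
        })
      }
      pair_grid <- expand.grid(i = seq_along(blocks), j = seq_along(blocks))
      pair_grid <- pair_grid[sample.int(nrow(pair_grid)), ]
      for (pr in seq_len(nrow(pair_grid))) {
        if (length(members) >= n_target || attempts >= max_attempts) break
        attempts <- attempts + 1L
        p1 <- placed[[1]][[pair_grid$i[pr]]]
        p2 <- placed[[2]][[pair_grid$j[pr]]]
        if (is.null(p1) || is.null(p2)) next
        ring_d <- vnorm(anchors[[1]][[pair_grid$i[pr]]] -
                        anchors[[2]][[pair_grid$j[pr]]])
        if (ring_d >= filters$ring_calpha_max) next
        pl <- list(p1, p2)
        ag_a <- extract_structure(pl[[1]], "antigen")
        ag_a$info <- list(c2 = ag_a$info[["antigen.c2"]])
        ag_b <- extract_structure(pl[[2]], "antigen")
        ag_b$info <- list(c2 = ag_b$info[["antigen.c2"]])
        if (!clash_ok(ag_a, ag_b, filters$clash_min)) next
      # closing antibody: joint two-arm superposition onto the free sites.
      # Necessary condition for small closure RMSD: the candidate's
      # arm-centroid separation matches the slot separation, so candidates
      # are tried in order of that mismatch.
      slot_a <- coords(pl[[1]], "fab2")
      slot_b <- coords(pl[[2]], "fab2")
      slot_sep <- vnorm(centroid(slot_a) - centroid(slot_b))
      best <- NULL
      cand_idx <- sel[order(abs(arm_sep_all - slot_sep))]
      cand_idx <- cand_idx[seq_len(min(n_closure_candidates,
                                       length(cand_idx)))]
      for (ci in cand_idx) {
        ab2 <- abs_all[[ci]]
        for (orient in 1:2) {
          tgt <- if (orient == 1) rbind(slot_a, slot_b) else
                                  rbind(slot_b, slot_a)
          src <- rbind(coords(ab2, "Fab1"), coords(ab2, "Fab2"))
          sp2 <- superpose(src, tgt)
          if (is.null(best) || sp2$rmsd < best$rmsd) {
            best <- list(rmsd = sp2$rmsd, ab = ab2, tr = sp2$transform)
          }
        }
      }
      if (is.null(best) || best$rmsd > filters$closure_tol) next
      ab2p <- apply_transform(best$ab, best$tr)
      # clash checks on non-interface unit pairs
      ab1_core <- extract_structure(
        ab1, setdiff(seq_len(n_atoms(ab1)),
                     c(label_indices(ab1, "Fab1"), label_indices(ab1, "Fab2"))))
      ab2_core <- extract_structure(
        ab2p, setdiff(seq_len(n_atoms(ab2p)),
                      c(label_indices(ab2p, "Fab1"),
                        label_indices(ab2p, "Fab2"))))
      if (!clash_ok(ab1_core, ag_a, filters$clash_min)) next
      if (!clash_ok(ab1_core, ag_b, filters$clash_min)) next
      if (!clash_ok(ab2_core, ag_a, filters$clash_min)) next
      if (!clash_ok(ab2_core, ag_b, filters$clash_min)) next
      if (!clash_ok(ab1, ab2p, filters$clash_min)) next
      cplx <- finish_complex(
        list(ag_a = ag_a, ag_b = ag_b, ab1 = ab1, ab2 = ab2p),
        "bidentate",
        edges = list(c("ab1", "ag_a"), c("ag_a", "ab2"), c("ab2", "ag_b"),
                     c("ag_b", "ab1")),
        extra = list(ring_anchor_distance = ring_d,
                     closure_rmsd = best$rmsd))
      if (is.null(template)) template <- cplx
      if (n_atoms(cplx) != n_atoms(template)) next
      members[[length(members) + 1L]] <- coords(cplx)
      meta <- rbind(meta, data.frame(
        member = length(members), attempt = attempts,
        rg = radius_of_gyration(cplx),
        angle_ab1 = fab_fc_fab_angle(ab1),
        angle_ab2 = fab_fc_fab_angle(best$ab),
        ring_anchor_distance = ring_d, closure_rmsd = best$rmsd))
      }
    }
  })
  if (is.null(template)) {
    e <- saxs_ensemble(saxs_structure(data.frame(
      serial = 1L, chain = "A", resno = 1L, resid = "GLY", elety = "CA",
      element = "C", x = 0, y = 0, z = 0)), list())
    attr(e, "attempts") <- attempts
    attr(e, "n_angle_pass") <- length(sel)
    return(e)
  }
  e <- saxs_ensemble(template, members, meta)
  attr(e, "attempts") <- attempts
  attr(e, "n_angle_pass") <- length(sel)
  e
}

#' Linkage-graph class of an assembled complex
#'
#' @param cplx a complex with topology metadata
#' @return `"path"` (acyclic chain), `"cycle"` (single ring) or `"other"`
#' @export
topology_graph_class <- function(cplx) {
  edges <- cplx$info$topology$edges
  if (is.null(edges)) stopf("complex lacks topology edges")
  nodes <- unique(unlist(edges))
  deg <- table(factor(unlist(edges), levels = nodes))
  n <- length(nodes); m <- length(edges)
  if (m == n && all(deg == 2)) return("cycle")
  if (m == n - 1 && sum(deg == 1) == 2 && all(deg <= 2)) return("path")
  "other"
}
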