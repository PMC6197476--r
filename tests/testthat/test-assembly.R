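test_that("symmetric replication is an involution that spares the antigen", {
  pose <- fx_poses()[[1]]
  sb <- symmetrize_pose(pose, axis = 1)
  expect_true(sb$accepted)
  blk <- sb$structure

  # applying the same 180-degree rotation to the replicated Fab returns the
  # original Fab position
  fr <- blk$info[["antigen.c2"]]
  tr <- axis_rotation(fr$axes[1, ], 180, fr$center)
  back <- apply_transform(coords(blk, "fab2"), tr)
  expect_lt(max(abs(back - coords(blk, "fab1"))), 1e-9)

  # antigen coordinates unchanged by the replication
  expect_equal(coords(blk, "antigen"),
               coords(extract_structure(pose, "antigen")), tolerance = 1e-12)

  # both Fabs sit at docking distance from the antigen
  ag <- extract_structure(blk, "antigen")
  for (f in c("fab1", "fab2")) {
    d <- min_pair_distance(coords(blk, f), coords(ag))
    expect_gte(d, 4 - 0.5)
    expect_lte(d, 4 + 2)
  }
})

test_that("symmetric replication rejects overlapping Fab copies by the 8 A rule", {
  # craft a pose whose Fab straddles the 2-fold axis: its image overlaps it
  fab <- fx_fab()
  ag <- fx_tetramer()
  fab_on_axis <- apply_transform(
    fab, saxs_transform(diag(3), c(60, 0, 0) - centroid(coords(fab))))
  pose <- combine_structures(list(fab = fab_on_axis, antigen = ag))
  sb <- symmetrize_pose(pose, axis = 1)  # x axis passes through the Fab
  expect_false(sb$accepted)
  expect_lt(sb$min_fab_fab, 8)
  expect_null(sb$structure)
})

test_that("antibody attachment maintains the docked pose and reports clashes", {
  ab <- fx_antibody()
  blk <- fx_blocks()[[1]]
  a <- attach_antibody(ab, blk, "fab1", fab = 1)
  expect_true(a$accepted)
  expect_lt(a$rmsd, 1e-6)
  # the aligned arm coincides with the anchor Fab: docked geometry frozen
  expect_lt(max(abs(coords(a$structure, "Fab1") - coords(blk, "fab1"))),
            1e-6)

  # an antibody whose arm already coincides re-aligns with identity
  again <- attach_antibody(a$structure, blk, "fab1", fab = 1)
  expect_lt(max(abs(coords(again$structure) - coords(a$structure))), 1e-6)

  # engineered overlap: a decoy unit placed where the Fc will land
  arm <- centroid(coords(blk, "fab1"))
  fc_target <- arm + (centroid(coords(ab, "Fc")) -
                      centroid(coords(ab, "Fab1")))
  decoy <- apply_transform(
    fx_tetramer(),
    saxs_transform(diag(3), fc_target - c(0, 0, 0)))
  poisoned <- combine_structures(list(
    fab1 = extract_structure(blk, "fab1"), decoy = decoy))
  bad <- attach_antibody(ab, poisoned, "fab1", fab = 1)
  expect_false(bad$accepted)
  expect_lt(bad$min_clash, 8)
})

test_that("monodentate members re-pass brute-force filters and have path
          topology", {
  mono <- build_monodentate_ensemble(fx_blocks(), fx_poses(), fx_tamc(),
                                     n_target = 4, seed = 11)
  expect_gte(length(mono), 1)
  m1 <- ensemble_member(mono, 1)
  expect_equal(m1$info$topology$kind, "monodentate")
  expect_equal(m1$info$topology$n_antibody, 2L)
  expect_equal(m1$info$topology$n_antigen, 2L)
  expect_equal(topology_graph_class(m1), "path")

  ab_atoms <- n_atoms(fx_antibody())
  ag_atoms <- n_atoms(fx_tetramer())
  expect_equal(n_atoms(m1), 2L * ab_atoms + 2L * ag_atoms)

  # brute-force re-check of every clash rule on every member, with the
  # documented docked-interface exemptions
  for (i in seq_len(length(mono))) {
    m <- ensemble_member(mono, i)
    not_fab <- function(abu, fabl) {
      setdiff(label_indices(m, abu), label_indices(m, paste0(abu, ".", fabl)))
    }
    checks <- list(
      list(not_fab("ab1", "Fab1"), label_indices(m, "ag1")),
      list(not_fab("ab2", "Fab1"), label_indices(m, "ag1")),
      list(not_fab("ab1", "Fab2"), label_indices(m, "ag2")),
      list(label_indices(m, "ab1"), label_indices(m, "ab2")),
      list(label_indices(m, "ag1"), label_indices(m, "ag2")),
      list(label_indices(m, "ag2"), label_indices(m, "ab2")))
    for (ch in checks) {
      expect_gte(brute_min_dist(coords(m)[ch[[1]], , drop = FALSE],
                                coords(m)[ch[[2]], , drop = FALSE]), 8)
    }
  }

  empty <- build_monodentate_ensemble(fx_blocks(), fx_poses(), fx_tamc(),
                                      n_target = 0, seed = 1)
  expect_equal(length(empty), 0L)
})

test_that("bidentate members satisfy the angle window, ring distance and
          cycle topology", {
  bi <- build_bidentate_ensemble(fx_tamc(), fx_blocks(), n_target = 4,
                                 seed = 12)
  expect_gte(length(bi), 1)
  m1 <- ensemble_member(bi, 1)
  expect_equal(m1$info$topology$kind, "bidentate")
  expect_equal(topology_graph_class(m1), "cycle")
  expect_equal(n_atoms(m1),
               2L * n_atoms(fx_antibody()) + 2L * n_atoms(fx_tetramer()))

  for (i in seq_len(length(bi))) {
    m <- ensemble_member(bi, i)
    # arm-angle window, measured directly from emitted coordinates
    for (abu in c("ab1", "ab2")) {
      ang <- three_point_angle(
        centroid(coords(m, paste0(abu, ".Fab1"))),
        centroid(coords(m, paste0(abu, ".Fc"))),
        centroid(coords(m, paste0(abu, ".Fab2"))))
      expect_gte(ang, 70)
      expect_lte(ang, 90)
    }
    # non-interface clash rules by brute force
    core <- function(abu) {
      setdiff(label_indices(m, abu),
              c(label_indices(m, paste0(abu, ".Fab1")),
                label_indices(m, paste0(abu, ".Fab2"))))
    }
    checks <- list(
      list(core("ab1"), label_indices(m, "ag_a")),
      list(core("ab1"), label_indices(m, "ag_b")),
      list(core("ab2"), label_indices(m, "ag_a")),
      list(core("ab2"), label_indices(m, "ag_b")),
      list(label_indices(m, "ab1"), label_indices(m, "ab2")),
      list(label_indices(m, "ag_a"), label_indices(m, "ag_b")))
    for (ch in checks) {
      expect_gte(brute_min_dist(coords(m)[ch[[1]], , drop = FALSE],
                                coords(m)[ch[[2]], , drop = FALSE]), 8)
    }
  }
  # recorded ring-closure diagnostics honour the filters
  expect_true(all(bi$meta$ring_anchor_distance < 40))
  expect_true(all(bi$meta$closure_rmsd <= assembly_filters()$closure_tol))

  # member 1's ring distance re-derived from its own recorded frames
  fr_a <- m1$info[["ag_a.c2"]]
  expect_false(is.null(fr_a))
})

test_that("an unsatisfiable angle window yields an empty ensemble", {
  rigid <- list(fx_antibody())  # fixed arm angle of 80 degrees
  bi <- build_bidentate_ensemble(
    rigid, fx_blocks(),
    filters = assembly_filters(angle_window = c(89.9, 90.0)),
    n_target = 2, seed = 1)
  expect_equal(length(bi), 0L)
  expect_equal(attr(bi, "n_angle_pass"), 0L)
})

test_that("linkage-graph classifier distinguishes paths, cycles and others", {
  s <- fx_tetramer()
  s$info$topology <- list(edges = list(c("a", "b"), c("b", "c")))
  expect_equal(topology_graph_class(s), "path")
  s$info$topology <- list(edges = list(c("a", "b"), c("b", "c"),
                                       c("c", "a")))
  expect_equal(topology_graph_class(s), "cycle")
  s$info$topology <- list(edges = list(c("a", "b"), c("a", "c"),
                                       c("a", "d")))
  expect_equal(topology_graph_class(s), "other")
})
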