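# Backbone torsion-angle Monte Carlo: non-overlapping configurational
# ensembles generated by random phi/psi pivots at hinge residues, with a
# pure hard-sphere acceptance rule (no energy function) -- accepted moves
# become the current state, exactly the chain-of-states scheme used to
# sample hinge flexibility of an antibody at production scale.

#' Torsion-angle Monte Carlo configuration
#'
#' @param pivots data.frame with columns `chain`, `resno`, `angle`
#'   (`"phi"`/`"psi"`): the sampled pivot set. Default `NULL` uses the
#'   structure's own `info$default_pivots` (the toy hinge interior, the
#'   analogue of upper-hinge heavy-chain residues 212-214).
#' @param max_step maximum torsion step, degrees, in (0, 180]
#' @param n_accept number of accepted members to collect (>= 0)
#' @param overlap_cutoff hard-sphere clash distance, Angstrom (> 0);
#'   default 1.8, a heavy-atom contact distance
#' @param seed integer seed
#' @param max_attempts total attempt cap before failing with an
#'   acceptance-rate diagnostic
#' @param restart_after consecutive rejections before resetting to the
#'   input structure (prevents trapping)
#' @return object of class `tamc_config`
#' @export
tamc_config <- function(pivots = NULL, max_step = 30, n_accept = 100,
                        overlap_cutoff = 1.8, seed = 1,
                        max_attempts = NULL, restart_after = 1000) {
  if (max_step <= 0 || max_step > 180) stopf("max_step must be in (0, 180]")
  if (n_accept < 0) stopf("n_accept must be >= 0")
  if (overlap_cutoff <= 0) stopf("overlap_cutoff must be > 0")
  if (is.null(max_attempts)) max_attempts <- max(2000L, 200L * n_accept)
  structure(list(pivots = pivots, max_step = max_step,
                 n_accept = as.integer(n_accept),
                 overlap_cutoff = overlap_cutoff, seed = as.integer(seed),
                 max_attempts = as.integer(max_attempts),
                 restart_after = as.integer(restart_after)),
            class = "tamc_config")
}

#' Structural ensemble over a fixed topology
#'
#' Members share the template's atom count and ordering; only coordinates
#' differ. Per-member metadata lives in `meta`.
#'
#' @param template a `saxs_structure`
#' @param coords_list list of N x 3 coordinate matrices
#' @param meta data.frame with one row per member
#' @return object of class `saxs_ensemble`
#' @export
saxs_ensemble <- function(template, coords_list, meta = NULL) {
  n <- n_atoms(template)
  for (m in coords_list) {
    if (nrow(m) != n) stopf("ensemble member atom count differs from template")
  }
  if (is.null(meta)) meta <- data.frame(member = seq_along(coords_list))
  structure(list(template = template, coords = coords_list, meta = meta),
            class = "saxs_ensemble")
}

#' @export
print.saxs_ensemble <- function(x, ...) {
  cat(sprintf("<saxs_ensemble> %d members x %d atoms\n",
              length(x$coords), n_atoms(x$template)))
  invisible(x)
}

#' @export
length.saxs_ensemble <- function(x) length(x$coords)

#' Materialize one ensemble member as a structure
#' @param e a `saxs_ensemble`
#' @param i member index
#' @return a `saxs_structure`
#' @export
ensemble_member <- function(e, i) set_coords(e$template, e$coords[[i]])

# Minimum distance between distinct rigid units of a toy antibody,
# skipping residue neighbours (covalent junctions). This is the
# overlap criterion: a configuration is clash-free iff this is >= cutoff.
#' Minimum inter-unit atom distance of a multi-domain structure
#'
#' Scans all atom pairs belonging to different named units (domains and
#' hinges), excluding pairs within `excl_resno` residues along the chain
#' (covalently bonded junctions).
#'
#' @param s a `saxs_structure` with `info$units` naming its unit labels
#' @param below optional early-exit threshold (see [min_pair_distance()])
#' @param excl_resno residue-separation exclusion (default 2)
#' @return minimum distance, Angstrom
#' @export
min_interdomain_distance <- function(s, below = 0, excl_resno = 2) {
  units <- s$info$units %||% names(s$labels)
  xyz <- coords(s)
  resno <- s$atoms$resno
  best <- Inf
  for (i in seq_along(units)) {
    for (j in seq_along(units)) {
      if (j <= i) next
      d <- .min_dist_excl(xyz, label_indices(s, units[i]),
                          label_indices(s, units[j]), resno,
                          as.integer(excl_resno), below)
      if (d < best) best <- d
      if (below > 0 && best < below) return(best)
    }
  }
  best
}

#' Torsion-angle Monte Carlo sampling
#'
#' Iterates: choose a pivot uniformly, draw a torsion step from
#' Uniform(-max_step, +max_step), rotate, and accept iff no inter-unit atom
#' pair is closer than the overlap cutoff. Accepted configurations become
#' the current state; sampling stops after `n_accept` acceptances. After
#' `restart_after` consecutive rejections the state resets to the input
#' structure. Deterministic given the seed.
#'
#' @param s starting `saxs_structure`; must itself be overlap-free
#' @param cfg a `tamc_config`
#' @return a `saxs_ensemble`; `meta` records move index, pivot, step and Rg
#' @export
tamc_sample <- function(s, cfg = tamc_config()) {
  pivots <- cfg$pivots %||% s$info$default_pivots
  if (is.null(pivots) || !nrow(pivots)) stopf("no pivots given or stored")
  for (k in seq_len(nrow(pivots))) {  # fail early on unresolvable pivots
    dihedral_atoms(s, pivots$chain[k], pivots$resno[k], pivots$angle[k])
  }
  if (is.finite(cfg$overlap_cutoff) &&
      min_interdomain_distance(s, below = cfg$overlap_cutoff) <
        cfg$overlap_cutoff) {
    stopf("input structure is not overlap-free at cutoff %.2f A",
          cfg$overlap_cutoff)
  }
  members <- vector("list", cfg$n_accept)
  meta <- data.frame(member = integer(0), move = integer(0),
                     pivot = character(0), delta = numeric(0),
                     rg = numeric(0))
  if (cfg$n_accept == 0L) {
    return(saxs_ensemble(s, members, meta))
  }
  with_seed(cfg$seed, {
    cur <- s
    n_found <- 0L
    attempts <- 0L
    consecutive_rej <- 0L
    while (n_found < cfg$n_accept) {
      attempts <- attempts + 1L
      if (attempts > cfg$max_attempts) {
        stopf(paste0("torsion MC failed: %d/%d acceptances after %d ",
                     "attempts (acceptance rate %.3f); is the overlap ",
                     "cutoff too large?"),
              n_found, cfg$n_accept, attempts - 1L,
              n_found / (attempts - 1L))
      }
      k <- sample.int(nrow(pivots), 1L)
      delta <- runif(1, -cfg$max_step, cfg$max_step)
      cand <- apply_torsion(cur, pivots$chain[k], pivots$resno[k],
                            pivots$angle[k], delta)
      ok <- min_interdomain_distance(cand, below = cfg$overlap_cutoff) >=
        cfg$overlap_cutoff
      if (ok) {
        cur <- cand
        n_found <- n_found + 1L
        consecutive_rej <- 0L
        members[[n_found]] <- coords(cur)
        meta <- rbind(meta, data.frame(
          member = n_found, move = attempts,
          pivot = sprintf("%s/%d/%s", pivots$chain[k], pivots$resno[k],
                          pivots$angle[k]),
          delta = delta, rg = radius_of_gyration(cur)))
      } else {
        consecutive_rej <- consecutive_rej + 1L
        if (consecutive_rej >= cfg$restart_after) {
          cur <- s
          consecutive_rej <- 0L
        }
      }
    }
    e <- saxs_ensemble(s, members, meta)
    e$acceptance_rate <- n_found / attempts
    e
  })
}

#' Write an ensemble as a PDB directory plus a TSV manifest
#'
#' @param e a `saxs_ensemble`
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix
#' @return invisibly, the manifest path
#' @export
write_ensemble <- function(e, dir, prefix = "member") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(e))
  for (i in seq_along(e$coords)) {
    files[i] <- file.path(dir, sprintf("%s_%04d.pdb", prefix, i))
    write_structure(ensemble_member(e, i), files[i])
  }
  manifest <- cbind(e$meta, file = basename(files))
  mpath <- file.path(dir, paste0(prefix, "_manifest.tsv"))
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(mpath)
}
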