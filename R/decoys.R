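# Uniform random unit vector (normalized Gaussian 3-vector).
.random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# Ligand centroid over all heavy atoms.
.centroid <- function(chain) {
  colMeans(as.matrix(chain$atoms[, c("x", "y", "z")]))
}

#' Perturb a native dimer into a decoy of known deviation
#'
#' Rotates the ligand by `rot_deg` about a random axis through its centroid
#' and translates it along a random direction by `trans_ang`; the receptor
#' is untouched. With `rot_deg = 0` the iRMSD against the native equals
#' `trans_ang` exactly (every ligand atom moves by the same vector).
#'
#' @param native a `dimer_structure`.
#' @param rot_deg rotation magnitude in degrees (>= 0).
#' @param trans_ang translation magnitude in Angstrom (>= 0).
#' @param seed integer seed; same seed gives an identical pose.
#' @return list with `dimer` (the perturbed `dimer_structure`) and
#'   `transform` (the ligand-frame `rigid_transform` applied).
#' @export
perturb_native <- function(native, rot_deg, trans_ang, seed = 1L) {
  stopifnot(inherits(native, "dimer_structure"))
  if (rot_deg < 0 || trans_ang < 0) stop("perturbation magnitudes must be >= 0")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  axis <- .random_unit()
  dir <- .random_unit()
  R <- rotation_about_axis(axis, rot_deg)
  cen <- .centroid(native$ligand)
  # rotate about the ligand centroid, then translate
  shift <- cen - as.numeric(R %*% cen) + dir * trans_ang
  tf <- rigid_transform(R, shift)
  out <- native
  out$ligand <- apply_transform(tf, native$ligand)
  list(dimer = out, transform = tf)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Contact/clash score used to rank sampled or perturbed poses: heavy-atom
# pairs in the 4-6 Angstrom shell count +1, pairs closer than 2.5 Angstrom
# count -clash_weight each.
.pose_score <- function(dimer, shell = c(4.0, 6.0), clash_dist = 2.5,
                        clash_weight = 10) {
  d2 <- .cross_dist2(chain_coords(dimer$receptor), chain_coords(dimer$ligand))
  contacts <- sum(d2 >= shell[1]^2 & d2 <= shell[2]^2)
  clashes <- sum(d2 < clash_dist^2)
  contacts - clash_weight * clashes
}

#' Generate a ranked decoy set by controlled perturbation
#'
#' Produces `n` decoys of the native complex spanning a magnitude schedule
#' (rotation/translation pairs, recycled across decoys), scores each with a
#' contact-minus-clash score and returns them ranked by decreasing score.
#' Quality ground truth (iRMSD against the native) is included.
#'
#' @param native a `dimer_structure`.
#' @param n number of decoys (>= 1).
#' @param magnitude_schedule data.frame with columns `rot_deg`, `trans_ang`;
#'   rows are recycled over the `n` decoys. The default spans near-native
#'   to far poses.
#' @param seed integer seed.
#' @return list with `decoys` (list of `dimer_structure`, ranked) and
#'   `index` (data.frame: rank, score, rot_deg, trans_ang, irmsd).
#' @export
generate_decoy_set <- function(native, n,
                               magnitude_schedule = data.frame(
                                 rot_deg = c(0, 5, 10, 20, 40, 80),
                                 trans_ang = c(0, 1, 2, 5, 10, 20)),
                               seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  sched <- magnitude_schedule[rep_len(seq_len(nrow(magnitude_schedule)), n), ,
                              drop = FALSE]
  poses <- vector("list", n)
  for (i in seq_len(n)) {
    sub_seed <- as.integer((as.numeric(seed) * 100003 + i) %% 2147483629)
    poses[[i]] <- perturb_native(native, sched$rot_deg[i], sched$trans_ang[i],
                                 seed = sub_seed)
  }
  dimers <- lapply(poses, `[[`, "dimer")
  scores <- vapply(dimers, .pose_score, numeric(1))
  quality <- vapply(dimers, irmsd, numeric(1), reference = native)
  ord <- order(scores, decreasing = TRUE)
  idx <- data.frame(rank = seq_len(n), score = scores[ord],
                    rot_deg = sched$rot_deg[ord], trans_ang = sched$trans_ang[ord],
                    irmsd = quality[ord])
  list(decoys = dimers[ord], index = idx)
}

#' Naive exhaustive rigid-body sampler
#'
#' A deliberately simple stand-in for an FFT docking engine: a coarse set of
#' ligand rotations crossed with a translation grid around the receptor,
#' scored by contact count (4-6 Angstrom shell) minus `clash_weight` times
#' the count of clashing atom pairs (< 2.5 Angstrom). Near-duplicate poses
#' (ligand CA RMSD < 1 Angstrom) are removed before ranking.
#'
#' @param receptor,ligand `chain_structure` objects.
#' @param n_rotations number of ligand orientations sampled (>= 1).
#' @param grid_step translation grid spacing in Angstrom (> 0).
#' @param clash_weight penalty per clashing atom pair.
#' @param n_keep maximum number of poses returned.
#' @param seed seed for the rotation set.
#' @return list with `decoys` (ranked list of `dimer_structure`) and
#'   `index` (rank, score).
#' @export
naive_rigid_sample <- function(receptor, ligand, n_rotations = 8L,
                               grid_step = 3.0, clash_weight = 10,
                               n_keep = 50L, seed = 1L) {
  stopifnot(inherits(receptor, "chain_structure"), inherits(ligand, "chain_structure"))
  if (n_rotations < 1) stop("n_rotations must be >= 1")
  if (grid_step <= 0) stop("grid_step must be positive")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rots <- c(list(diag(3)), lapply(seq_len(max(0L, n_rotations - 1L)), function(i) {
    rotation_about_axis(.random_unit(), stats::runif(1, 0, 360))
  }))
  rc <- chain_coords(receptor)
  lc0 <- chain_coords(ligand)
  lig_cen <- colMeans(lc0)
  rec_cen <- colMeans(rc)
  # translation grid: ligand centroid positions in a box around the receptor,
  # padded by the two radii of gyration
  rad <- function(m, cen) max(sqrt(rowSums(sweep(m, 2, cen)^2)))
  pad <- rad(lc0, lig_cen) + 4
  lo <- apply(rc, 2, min) - pad; hi <- apply(rc, 2, max) + pad
  gx <- seq(lo[1], hi[1], by = grid_step)
  gy <- seq(lo[2], hi[2], by = grid_step)
  gz <- seq(lo[3], hi[3], by = grid_step)
  grid <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  # coarse prefilter: keep grid points within plausible contact range of the
  # receptor surface (centroid distance between min and max feasible)
  dcen <- sqrt(rowSums(sweep(grid, 2, rec_cen)^2))
  feasible <- dcen <= rad(rc, rec_cen) + rad(lc0, lig_cen) + 6
  grid <- grid[feasible, , drop = FALSE]
  if (nrow(grid) == 0L) stop("degenerate inputs: empty translation grid")

  poses <- list(); scores <- numeric(0)
  for (R in rots) {
    lc_rot <- sweep(sweep(lc0, 2, lig_cen) %*% t(R), 2, lig_cen, `+`)
    for (g in seq_len(nrow(grid))) {
      shiftv <- grid[g, ] - lig_cen
      lc <- sweep(lc_rot, 2, shiftv, `+`)
      d2 <- .cross_dist2(rc, lc)
      mind2 <- min(d2)
      if (mind2 > 36) next  # no atom pair within the 6 A shell
      contacts <- sum(d2 >= 16 & d2 <= 36)
      clashes <- sum(d2 < 6.25)
      sc <- contacts - clash_weight * clashes
      tf <- rigid_transform(R, lig_cen - as.numeric(R %*% lig_cen) + shiftv)
      poses[[length(poses) + 1L]] <- tf
      scores[length(scores) + 1L] <- sc
    }
  }
  if (length(poses) == 0L) stop("sampler produced no scored poses")
  ord <- order(scores, decreasing = TRUE)
  # deduplicate by ligand CA RMSD < 1 A, greedily from the top
  ca0 <- chain_coords(ligand, atom_name = "CA")
  kept <- integer(0); kept_ca <- list()
  for (i in ord) {
    ca_i <- apply_transform(poses[[i]], ca0)
    dup <- any(vapply(kept_ca, function(k) rmsd_coords(ca_i, k) < 1.0, logical(1)))
    if (!dup) {
      kept <- c(kept, i)
      kept_ca[[length(kept_ca) + 1L]] <- ca_i
      if (length(kept) >= n_keep) break
    }
  }
  decoys <- lapply(kept, function(i) {
    d <- dimer_structure(receptor, apply_transform(poses[[i]], ligand),
                         label = "sampled")
    d
  })
  list(decoys = decoys,
       index = data.frame(rank = seq_along(kept), score = scores[kept]))
}

#' Write a decoy set to a directory
#'
#' Serializes each decoy as `decoy_<rank>.pdb` plus an `index.tsv` with the
#' rank/score (and quality, when present) bookkeeping.
#'
#' @param decoy_set list as returned by [generate_decoy_set()] or
#'   [naive_rigid_sample()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_decoy_set <- function(decoy_set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(decoy_set$decoys)) {
    write_pdb(decoy_set$decoys[[i]], file.path(dir, sprintf("decoy_%04d.pdb", i)))
  }
  utils::write.table(decoy_set$index, file.path(dir, "index.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
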