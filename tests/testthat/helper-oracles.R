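# Independent brute-force oracles used across the suite. These never call
# the package routines they check.

# Confusion-matrix metrics by expanding counts into 0/1 vectors:
# TPR/FPR/ACC as means, MCC as the Pearson correlation of the vectors.
oracle_confusion_metrics <- function(tp, fp, tn, fn) {
  truth <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
  pred <- c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn))
  mcc <- suppressWarnings(stats::cor(pred, truth))
  if (is.na(mcc)) mcc <- 0
  list(
    tpr = if (tp + fn > 0) mean(pred[truth == 1]) else NA_real_,
    fpr = if (fp + tn > 0) mean(pred[truth == 0]) else NA_real_,
    acc = mean(pred == truth),
    mcc = mcc
  )
}

# AUC as the probability that a random positive outscores a random negative
# (ties count one half).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Minimum RMSD over all proper rotations (+ optimal translation) by
# numerical minimization over Euler angles from many starts.
oracle_min_rmsd <- function(moving, fixed) {
  A <- sweep(moving, 2, colMeans(moving))
  B <- sweep(fixed, 2, colMeans(fixed))
  euler_rot <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  f <- function(ang) sqrt(mean(rowSums((A %*% t(euler_rot(ang)) - B)^2)))
  starts <- as.matrix(expand.grid(z = seq(0, 2 * pi, length.out = 5)[-5],
                                  y = seq(0, pi, length.out = 4),
                                  x = seq(0, 2 * pi, length.out = 5)[-5]))
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    r <- stats::optim(starts[i, ], f, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
    if (r$value < best) best <- r$value
  }
  best
}

# Graph metrics from an adjacency matrix: mean degree, diameter of the
# largest component via repeated BFS, mean local clustering via triangle
# counting (degree < 2 contributes 0).
oracle_graph_metrics <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  bfs_dist <- function(src) {
    d <- rep(Inf, n); d[src] <- 0
    frontier <- src
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(adj[v, ] > 0 & is.infinite(d))
        d[nb] <- d[v] + 1
        nxt <- c(nxt, nb)
      }
      frontier <- unique(nxt)
    }
    d
  }
  # connected components via BFS
  comp <- rep(0L, n); k <- 0L
  for (v in seq_len(n)) {
    if (comp[v] == 0L) {
      k <- k + 1L
      comp[is.finite(bfs_dist(v))] <- k
    }
  }
  big <- which(comp == which.max(tabulate(comp)))
  diam <- 0
  for (v in big) {
    d <- bfs_dist(v)
    diam <- max(diam, max(d[is.finite(d) & comp == comp[v]]))
  }
  local_cc <- vapply(seq_len(n), function(v) {
    if (deg[v] < 2) return(0)
    nb <- which(adj[v, ] > 0)
    links <- sum(adj[nb, nb]) / 2
    links / choose(deg[v], 2)
  }, numeric(1))
  list(mean_degree = mean(deg), diameter = diam,
       mean_clustering = mean(local_cc))
}

# Interface membership of a dimer by a direct all-pair distance scan on raw
# coordinates (independent of the package's interface_residues()).
oracle_interface <- function(dimer, cutoff = 10) {
  ra <- dimer$receptor$atoms
  la <- dimer$ligand$atoms
  rres <- integer(0); lres <- integer(0)
  for (i in seq_len(nrow(ra))) {
    for (j in seq_len(nrow(la))) {
      d <- sqrt((ra$x[i] - la$x[j])^2 + (ra$y[i] - la$y[j])^2 +
                  (ra$z[i] - la$z[j])^2)
      if (d <= cutoff) {
        rres <- c(rres, ra$res_seq[i])
        lres <- c(lres, la$res_seq[j])
      }
    }
  }
  list(receptor = sort(unique(rres)), ligand = sort(unique(lres)))
}

# Small shared fixtures -------------------------------------------------

toy_dimer_fixture <- function(seed = 3L) make_toy_dimer(40L, 30L, seed = seed)

# A two-residue, two-chain PDB text with CA atoms a known distance apart.
two_ca_pdb <- function(dx = 5.0) {
  paste(
    sprintf("ATOM      1  CA  ALA A   1    %8.3f%8.3f%8.3f  1.00  0.00           C",
            0, 0, 0),
    sprintf("ATOM      2  CA  GLY B   1    %8.3f%8.3f%8.3f  1.00  0.00           C",
            dx, 0, 0),
    "END", sep = "\n")
}
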