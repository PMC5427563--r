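#' Synthetic-data configuration
#'
#' Study conditions for the synthetic generator. Class-conditional feature
#' medians default to the benchmark values where printed (attractive vdW
#' -0.230 interacting / 0.214 non-interacting; repulsive vdW -0.187 /
#' -0.195; hydrogen bond -0.068 / 0.418); the remaining terms use medians
#' chosen once to be mildly discriminative on the Z-score scale.
#' Annotation co-annotation pass rates default to CC 0.82 (interacting) /
#' 0.58 (random), BP 0.93 / 0.32, MF 0.48 / 0.52.
#'
#' @param seed integer master seed.
#' @param n_proteins miniature-proteome size.
#' @param length_range residue-count range for toy monomers.
#' @param n_true_pairs number of planted interactions.
#' @param n_decoys decoys generated per planted pair.
#' @param feature_medians 2-row matrix (interacting, non_interacting) over
#'   [energy_feature_names()].
#' @param feature_spread Laplace scale of each feature around its median.
#' @param annotation_rates list per aspect: c(pos, neg) pass rates.
#' @param n_train training examples generated per class.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_proteins = 20L,
                         length_range = c(50L, 120L),
                         n_true_pairs = NULL, n_decoys = 20L,
                         feature_medians = default_feature_medians(),
                         feature_spread = 0.4,
                         annotation_rates = list(CC = c(pos = 0.82, neg = 0.58),
                                                 BP = c(pos = 0.93, neg = 0.32),
                                                 MF = c(pos = 0.48, neg = 0.52)),
                         n_train = 300L) {
  stopifnot(n_proteins >= 2, length_range[1] >= 20,
            all(unlist(annotation_rates) >= 0), all(unlist(annotation_rates) <= 1))
  n_possible <- n_proteins * (n_proteins - 1) / 2
  if (is.null(n_true_pairs)) {
    # ~8% planted density, matching the scale of proteome-wide positive rates
    n_true_pairs <- max(3L, min(n_possible - 1L, round(0.08 * n_possible)))
  }
  if (n_true_pairs >= n_possible) {
    stop("n_true_pairs must leave at least one non-interacting pair")
  }
  structure(list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 n_true_pairs = as.integer(n_true_pairs),
                 n_decoys = as.integer(n_decoys),
                 feature_medians = feature_medians,
                 feature_spread = feature_spread,
                 annotation_rates = annotation_rates,
                 n_train = as.integer(n_train)),
            class = "synth_config")
}

#' Default class-conditional feature medians
#'
#' @return 2 x 10 matrix with rows `interacting`, `non_interacting` and
#'   columns [energy_feature_names()].
#' @export
default_feature_medians <- function() {
  m <- rbind(
    interacting     = c(global_energy = -0.40, vdw_attractive = -0.230,
                        vdw_repulsive = -0.187, atomic_contact_energy = -0.15,
                        internal_energy = 0.00, hbond = -0.068,
                        partial_electrostatics = -0.10, disulfide = 0.00,
                        pi_stacking = -0.05, aliphatic = -0.10),
    non_interacting = c(global_energy = 0.30, vdw_attractive = 0.214,
                        vdw_repulsive = -0.195, atomic_contact_energy = 0.10,
                        internal_energy = 0.05, hbond = 0.418,
                        partial_electrostatics = 0.05, disulfide = 0.00,
                        pi_stacking = 0.02, aliphatic = 0.08))
  m[, energy_feature_names()]
}

# Ideal alpha-helix CA trace: rise 1.5 A/residue, 100 degrees/residue, with
# the radius set so consecutive CA-CA distances are ~3.8 A; CB placed 1.5 A
# radially outward from each CA.
.helix_coords <- function(n_residues) {
  rise <- 1.5; turn <- 100 * pi / 180
  radius <- sqrt(3.8^2 - rise^2) / (2 * sin(turn / 2))
  i <- seq_len(n_residues)
  th <- i * turn
  ca <- cbind(radius * cos(th), radius * sin(th), rise * i)
  cb <- cbind((radius + 1.5) * cos(th), (radius + 1.5) * sin(th), rise * i)
  list(ca = ca, cb = cb)
}

#' Generate a toy helical monomer
#'
#' An idealized alpha-helical CA+CB trace (rise 1.5 A, 100 degrees per
#' residue) with a seeded random sequence; deliberately biologically naive,
#' but PDB-writable and valid input for every distance-based stage.
#'
#' @param n_residues chain length (>= 5).
#' @param seed integer seed (controls the sequence).
#' @param chain_id chain label.
#' @return a `chain_structure`.
#' @export
make_toy_monomer <- function(n_residues, seed = 1L, chain_id = "A") {
  if (n_residues < 5) stop("toy monomer needs at least 5 residues")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  aa3 <- setdiff(names(.AA321), "GLY")  # every residue carries a CB
  res_names <- sample(aa3, n_residues, replace = TRUE)
  h <- .helix_coords(n_residues)
  atoms <- data.frame(
    res_seq = rep(seq_len(n_residues), each = 2L),
    res_name = rep(res_names, each = 2L),
    atom_name = rep(c("CA", "CB"), n_residues),
    element = "C",
    x = as.vector(rbind(h$ca[, 1], h$cb[, 1])),
    y = as.vector(rbind(h$ca[, 2], h$cb[, 2])),
    z = as.vector(rbind(h$ca[, 3], h$cb[, 3])))
  chain_structure(chain_id, atoms)
}

# Place a ligand chain against a receptor chain: parallel helix axes, the
# ligand rotated about its own axis by a seeded azimuth, axis separation
# searched so that there is no clash (< 2.5 A), the chains touch (< 5 A
# somewhere) and the combined 10 A interface has >= min_interface residues.
.place_ligand <- function(receptor, ligand, seed = 1L, min_interface = 20L,
                          max_tries = 12L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rl <- chain_length(receptor); ll <- chain_length(ligand)
  z_shift <- 1.5 * (rl - ll) / 2
  for (try in seq_len(max_tries)) {
    azimuth <- stats::runif(1, 0, 360)
    Rz <- rotation_about_axis(c(0, 0, 1), azimuth)
    for (sep in seq(8, 18, by = 0.5)) {
      lig <- ligand
      m <- as.matrix(lig$atoms[, c("x", "y", "z")])
      m <- m %*% t(Rz)                       # spin about own axis
      m[, 1] <- m[, 1] + sep                 # shift axis along x
      m[, 3] <- m[, 3] + z_shift             # center the overlap
      lig$atoms$x <- m[, 1]; lig$atoms$y <- m[, 2]; lig$atoms$z <- m[, 3]
      d2 <- .cross_dist2(chain_coords(receptor), chain_coords(lig))
      mind <- sqrt(min(d2))
      if (mind <= 2.5) next
      if (mind >= 5.0) break                 # chains no longer touch
      dm <- dimer_structure(receptor, lig, label = "toy")
      iface <- interface_residues(dm, 10.0)
      if (length(iface$receptor_residues) + length(iface$ligand_residues) >=
          min_interface) {
        return(dm)
      }
    }
  }
  stop("could not place ligand without clash and with a >= ", min_interface,
       "-residue interface")
}

#' Generate a toy native dimer
#'
#' Two toy helical monomers packed side by side so the combined 10 A
#' interface holds at least 20 residues and no heavy-atom pair clashes
#' below 2.5 A. The larger chain is the receptor.
#'
#' @param receptor_len,ligand_len chain lengths (>= 20).
#' @param seed integer seed.
#' @param label dimer identifier.
#' @return a `dimer_structure`.
#' @export
make_toy_dimer <- function(receptor_len = 40L, ligand_len = 30L, seed = 1L,
                           label = "toy_dimer") {
  if (receptor_len < 20 || ligand_len < 20) stop("chain lengths must be >= 20")
  a <- make_toy_monomer(max(receptor_len, ligand_len), seed = seed, chain_id = "A")
  b <- make_toy_monomer(min(receptor_len, ligand_len), seed = seed + 1L,
                        chain_id = "B")
  dm <- .place_ligand(a, b, seed = seed + 2L)
  dm$label <- label
  dm
}

#' Pack two existing monomers into a toy dimer
#'
#' Role assignment (larger chain = receptor) followed by the same clash-free
#' side-by-side placement used by [make_toy_dimer()].
#'
#' @param chain_a,chain_b `chain_structure` objects (distinct chain ids).
#' @param seed integer seed.
#' @param label dimer identifier.
#' @return a `dimer_structure`.
#' @export
pack_dimer <- function(chain_a, chain_b, seed = 1L, label = "dimer") {
  roles <- assign_roles(chain_a, chain_b, label = label)
  dm <- .place_ligand(roles$receptor, roles$ligand, seed = seed)
  dm$label <- label
  dm
}

#' Draw class-conditional synthetic energy features
#'
#' Each term is drawn from a two-sided exponential (Laplace) distribution
#' centered at the class-conditional median, so sample medians converge to
#' the configured targets.
#'
#' @param class "interacting" or "non_interacting".
#' @param n number of feature rows (>= 1).
#' @param config a `synth_config`.
#' @param seed integer seed.
#' @param pair_ids optional pair identifiers (recycled rank 1 rows
#'   otherwise generated).
#' @param model_rank model rank recorded per row.
#' @return feature data.frame with pair_id, model_rank, the ten terms and a
#'   label column (1 = interacting).
#' @export
synth_energy_features <- function(class = c("interacting", "non_interacting"),
                                  n, config = synth_config(), seed = 1L,
                                  pair_ids = NULL, model_rank = 1L) {
  class <- match.arg(class)
  if (n < 1) stop("n must be >= 1")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  med <- config$feature_medians[class, ]
  b <- config$feature_spread
  cols <- energy_feature_names()
  vals <- sapply(cols, function(cn) {
    med[[cn]] + sample(c(-1, 1), n, replace = TRUE) * stats::rexp(n, rate = 1 / b)
  })
  if (n == 1L) vals <- matrix(vals, nrow = 1, dimnames = list(NULL, cols))
  if (is.null(pair_ids)) {
    pair_ids <- sprintf("%s_%05d", class, seq_len(n))
  }
  out <- data.frame(pair_id = pair_ids, model_rank = model_rank)
  out <- cbind(out, as.data.frame(vals))
  out$label <- if (class == "interacting") 1L else 0L
  out
}

# Base term distribution for one aspect: k terms with probabilities p such
# that the collision probability sum(p^2) equals the target random-pair
# share rate. One heavy term plus k-1 equal light terms.
.aspect_term_distribution <- function(neg_rate, aspect) {
  k <- max(2L, as.integer(ceiling(1 / neg_rate)) + 1L)
  c1 <- 1 / (k - 1)
  disc <- c1^2 - (1 + c1) * (c1 - neg_rate)
  if (disc < 0) stop("infeasible random-pair share rate ", neg_rate)
  a <- (c1 + sqrt(disc)) / (1 + c1)
  p <- c(a, rep((1 - a) / (k - 1), k - 1))
  names(p) <- sprintf("%s:%04d", aspect, seq_len(k))
  p
}

#' Generate synthetic GO-slim annotations
#'
#' Assigns each protein one slim term per aspect from a term distribution
#' whose pairwise collision probability equals the configured random-pair
#' pass rate; designated interacting pairs are then nudged (term copied or
#' forced distinct with the calibrated probability) so their expected pass
#' rate matches the configured positive rate.
#'
#' @param protein_ids unique protein identifiers.
#' @param interacting_pairs data.frame with `protein_a`, `protein_b`.
#' @param config a `synth_config`.
#' @param seed integer seed.
#' @return annotation list shaped like [load_annotations()] output.
#' @export
synth_annotations <- function(protein_ids, interacting_pairs,
                              config = synth_config(), seed = 1L) {
  if (anyDuplicated(protein_ids)) stop("protein ids must be unique")
  rates <- config$annotation_rates
  if (any(unlist(rates) < 0 | unlist(rates) > 1)) stop("rates must be in [0, 1]")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  slots <- c(CC = "cc_terms", BP = "bp_terms", MF = "mf_terms")
  term_of <- list()
  for (aspect in names(rates)) {
    p <- .aspect_term_distribution(rates[[aspect]][["neg"]], aspect)
    term_of[[aspect]] <- stats::setNames(
      sample(names(p), length(protein_ids), replace = TRUE, prob = p),
      protein_ids)
    pos <- rates[[aspect]][["pos"]]; neg <- rates[[aspect]][["neg"]]
    if (nrow(interacting_pairs) > 0) {
      for (i in seq_len(nrow(interacting_pairs))) {
        a <- interacting_pairs$protein_a[i]; b <- interacting_pairs$protein_b[i]
        if (pos >= neg) {
          q <- (pos - neg) / (1 - neg)
          if (stats::runif(1) < q) term_of[[aspect]][[b]] <- term_of[[aspect]][[a]]
        } else {
          q <- (neg - pos) / neg
          if (stats::runif(1) < q &&
              term_of[[aspect]][[b]] == term_of[[aspect]][[a]]) {
            others <- setdiff(names(p), term_of[[aspect]][[a]])
            pr <- p[others] / sum(p[others])
            term_of[[aspect]][[b]] <- sample(others, 1L, prob = pr)
          }
        }
      }
    }
  }
  ann <- lapply(protein_ids, function(pid) {
    list(cc_terms = unname(term_of[["CC"]][[pid]]),
         bp_terms = unname(term_of[["BP"]][[pid]]),
         mf_terms = unname(term_of[["MF"]][[pid]]))
  })
  names(ann) <- protein_ids
  ann
}

#' Build a miniature end-to-end scenario on disk
#'
#' Generates a self-contained experiment directory: toy monomer structures,
#' native dimers and ranked decoy sets for every planted interaction,
#' class-conditional energy features for all candidate pairs plus a labeled
#' training table, synthetic GO-slim annotations, reference edges and a
#' ground-truth manifest. Deterministic given `config$seed`.
#'
#' @param dir output directory.
#' @param config a `synth_config`.
#' @return `dir`, invisibly; the directory layout is
#'   structures/ (PDB), decoys/<pair>/ (PDB + index.tsv), features.tsv,
#'   features_train.tsv, annotations.tsv, reference_edges.tsv,
#'   manifest.yaml.
#' @export
build_scenario <- function(dir, config = synth_config()) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create scenario directory: ", dir)
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  n <- config$n_proteins
  ids <- sprintf("P%03d", seq_len(n))
  lens <- sample(seq(config$length_range[1], config$length_range[2]), n,
                 replace = TRUE)
  monomer_seeds <- sample.int(1e6, n)
  dir.create(file.path(dir, "structures"), showWarnings = FALSE)
  monomers <- list()
  for (i in seq_len(n)) {
    monomers[[ids[i]]] <- make_toy_monomer(lens[i], seed = monomer_seeds[i])
    write_pdb(monomers[[ids[i]]], file.path(dir, "structures",
                                            paste0(ids[i], ".pdb")))
  }
  # planted interactions: distinct unordered pairs
  all_pairs <- t(utils::combn(ids, 2))
  sel <- sample.int(nrow(all_pairs), config$n_true_pairs)
  true_pairs <- data.frame(protein_a = all_pairs[sel, 1],
                           protein_b = all_pairs[sel, 2])
  # native dimers + decoys per planted pair (schedule includes the native)
  dir.create(file.path(dir, "decoys"), showWarnings = FALSE)
  pair_seeds <- sample.int(1e6, nrow(true_pairs))
  decoy_quality <- data.frame(pair_id = character(0), best_irmsd = numeric(0))
  for (i in seq_len(nrow(true_pairs))) {
    a <- true_pairs$protein_a[i]; b <- true_pairs$protein_b[i]
    pid <- paste(a, b, sep = "-")
    ca <- monomers[[a]]; cb <- monomers[[b]]; cb$chain_id <- "B"
    native <- pack_dimer(ca, cb, seed = pair_seeds[i], label = pid)
    ds <- generate_decoy_set(native, n = config$n_decoys, seed = pair_seeds[i])
    pdir <- file.path(dir, "decoys", pid)
    write_decoy_set(ds, pdir)
    write_pdb(native, file.path(pdir, "native.pdb"))
    decoy_quality <- rbind(decoy_quality,
                           data.frame(pair_id = pid,
                                      best_irmsd = min(ds$index$irmsd)))
  }
  # candidate features: every unordered pair, 3 model ranks
  key <- function(a, b) paste(a, b, sep = "-")
  true_key <- key(true_pairs$protein_a, true_pairs$protein_b)
  cand_key <- key(all_pairs[, 1], all_pairs[, 2])
  is_true <- cand_key %in% true_key
  feat <- list()
  for (rank in 1:3) {
    fs <- as.integer((config$seed * 977 + rank) %% 2147483629)
    pos <- synth_energy_features("interacting", sum(is_true), config,
                                 seed = fs, pair_ids = cand_key[is_true],
                                 model_rank = rank)
    neg <- synth_energy_features("non_interacting", sum(!is_true), config,
                                 seed = fs + 1L, pair_ids = cand_key[!is_true],
                                 model_rank = rank)
    feat[[rank]] <- rbind(pos, neg)
  }
  features <- do.call(rbind, feat)
  features$label <- NULL   # candidate table carries no labels
  write_feature_table(features, file.path(dir, "features.tsv"))
  # labeled training set, disjoint pair ids
  ts <- as.integer((config$seed * 7919) %% 2147483629)
  train <- rbind(
    synth_energy_features("interacting", config$n_train, config, seed = ts),
    synth_energy_features("non_interacting", config$n_train, config,
                          seed = ts + 1L))
  write_feature_table(train, file.path(dir, "features_train.tsv"))
  # annotations + reference edges
  ann <- synth_annotations(ids, true_pairs, config,
                           seed = as.integer((config$seed * 104729) %% 2147483629))
  write_annotations(ann, file.path(dir, "annotations.tsv"))
  write_edge_list(true_pairs, file.path(dir, "reference_edges.tsv"))
  manifest <- list(seed = config$seed, n_proteins = n,
                   protein_ids = ids, lengths = as.integer(lens),
                   true_pairs = true_key,
                   decoy_quality = stats::setNames(as.list(decoy_quality$best_irmsd),
                                                   decoy_quality$pair_id))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Run the classification-through-network pipeline on a scenario directory
#'
#' Trains the random-forest classifier on the scenario's labeled training
#' features (10-fold cross-validation for the ROC and MCC-optimal
#' threshold), scores every candidate pair, applies the top-n decision rule
#' and the GO filter cascade, assembles the network and evaluates recovery
#' of the planted edge set.
#'
#' @param dir scenario directory from [build_scenario()].
#' @param seed integer seed for training.
#' @param rule optional `decision_rule`; by default the threshold is the
#'   cross-validated MCC-optimal one with top_n = 3.
#' @param cascade GO filter cascade (default CC then BP).
#' @return list: `cv` (cross-validation output), `threshold`, `decisions`,
#'   `retained` pairs after filters, `network`, `metrics`
#'   (`network_metrics`), `recovery` (`classification_metrics` over
#'   candidate pairs) and `overlay` summary.
#' @export
run_scenario_pipeline <- function(dir, seed = 1L, rule = NULL,
                                  cascade = c("CC", "BP")) {
  train <- read_feature_table(file.path(dir, "features_train.tsv"))
  positives <- train[train$label == 1, , drop = FALSE]
  negatives <- train[train$label == 0, , drop = FALSE]
  cv <- cross_validate(positives, negatives, k = 10L, n_trees = 200L,
                       seed = seed)
  thr <- select_threshold_max_mcc(cv$scores, cv$labels)
  if (is.null(rule)) rule <- decision_rule(thr$threshold, top_n = 3L)
  model <- train_classifier(positives, negatives, n_trees = 200L, seed = seed)
  cand <- read_feature_table(file.path(dir, "features.tsv"))
  cand$prob <- predict(model, cand)
  decisions <- decide_pairs(cand, rule)
  called <- decisions[decisions$decision, , drop = FALSE]
  split_ids <- strsplit(called$pair_id, "-", fixed = TRUE)
  called_pairs <- data.frame(
    protein_a = vapply(split_ids, `[`, character(1), 1),
    protein_b = vapply(split_ids, `[`, character(1), 2))
  ann <- load_annotations(file.path(dir, "annotations.tsv"))
  filt <- apply_filter_cascade(called_pairs, ann, cascade = cascade)
  reference <- read_edge_list(file.path(dir, "reference_edges.tsv"))
  net <- build_network(filt$retained,
                       nodes = unique(c(reference$protein_a, reference$protein_b,
                                        called_pairs$protein_a,
                                        called_pairs$protein_b)))
  ov <- overlay_reference(net, reference)
  # recovery confusion over all candidate pairs
  final_key <- if (nrow(filt$retained) > 0) {
    paste(filt$retained$protein_a, filt$retained$protein_b, sep = "-")
  } else character(0)
  ref_key <- paste(reference$protein_a, reference$protein_b, sep = "-")
  cand_key <- unique(cand$pair_id)
  pred <- cand_key %in% final_key
  truth <- cand_key %in% ref_key
  recovery <- classify_metrics(sum(pred & truth), sum(pred & !truth),
                               sum(!pred & !truth), sum(!pred & truth))
  list(cv = cv, threshold = thr$threshold, decisions = decisions,
       retained = filt$retained, stage_counts = filt$stage_counts,
       network = net, metrics = network_metrics(net),
       recovery = recovery, overlay = ov$summary)
}
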