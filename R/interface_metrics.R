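# Pairwise squared distances between two n x 3 / m x 3 coordinate matrices.
.cross_dist2 <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' Interface residues of a dimer
#'
#' A residue is interfacial when at least one of its heavy atoms lies within
#' `cutoff` of any heavy atom of the partner chain. The 10 Angstrom default
#' is the definition used for iRMSD interface selection.
#'
#' @param dimer a `dimer_structure`.
#' @param cutoff distance cutoff in Angstrom (default 10).
#' @return list of class `interface_set`: `receptor_residues`,
#'   `ligand_residues` (integer `res_seq` vectors) and `cutoff`.
#' @export
interface_residues <- function(dimer, cutoff = 10.0) {
  stopifnot(inherits(dimer, "dimer_structure"))
  if (cutoff <= 0) stop("cutoff must be positive")
  ra <- dimer$receptor$atoms; la <- dimer$ligand$atoms
  d2 <- .cross_dist2(as.matrix(ra[, c("x", "y", "z")]),
                     as.matrix(la[, c("x", "y", "z")]))
  hit <- d2 <= cutoff^2
  structure(list(
    receptor_residues = sort(unique(ra$res_seq[rowSums(hit) > 0])),
    ligand_residues = sort(unique(la$res_seq[colSums(hit) > 0])),
    cutoff = cutoff
  ), class = "interface_set")
}

#' Residue-residue contact map of a dimer
#'
#' A receptor-ligand residue pair is in contact when any heavy-atom pair
#' between the two residues lies within `cutoff` (default 5 Angstrom,
#' CAPRI-style residue contact).
#'
#' @param dimer a `dimer_structure`.
#' @param cutoff contact cutoff in Angstrom.
#' @return list of class `contact_map`: `contacts` (two-column matrix of
#'   receptor/ligand `res_seq`), `receptor_residues`, `ligand_residues`
#'   (the full universe), and `cutoff`.
#' @export
contact_map <- function(dimer, cutoff = 5.0) {
  stopifnot(inherits(dimer, "dimer_structure"))
  if (cutoff <= 0) stop("cutoff must be positive")
  ra <- dimer$receptor$atoms; la <- dimer$ligand$atoms
  d2 <- .cross_dist2(as.matrix(ra[, c("x", "y", "z")]),
                     as.matrix(la[, c("x", "y", "z")]))
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  pairs <- unique(cbind(ra$res_seq[hit[, 1]], la$res_seq[hit[, 2]]))
  if (length(pairs) == 0L) pairs <- matrix(integer(0), ncol = 2)
  colnames(pairs) <- c("receptor", "ligand")
  structure(list(
    contacts = pairs,
    receptor_residues = sort(unique(ra$res_seq)),
    ligand_residues = sort(unique(la$res_seq)),
    cutoff = cutoff
  ), class = "contact_map")
}

#' Classification metrics from confusion counts
#'
#' Computes TPR, FPR, ACC and the Matthews correlation coefficient from
#' TP/FP/TN/FN. The MCC uses its standard form
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)) and is defined as 0
#' whenever a denominator factor vanishes.
#'
#' @param tp,fp,tn,fn non-negative integer counts, not all zero.
#' @return list of class `classification_metrics`: `tpr`, `fpr`, `acc`,
#'   `mcc` plus the four input counts.
#' @export
classify_metrics <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  if (sum(counts) == 0) stop("all confusion counts are zero")
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  fpr <- if (fp + tn > 0) fp / (fp + tn) else NA_real_
  acc <- (tp + tn) / sum(counts)
  den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den2 == 0) 0 else (tp * tn - fp * fn) / sqrt(den2)
  structure(list(tpr = tpr, fpr = fpr, acc = acc, mcc = mcc,
                 tp = tp, fp = fp, tn = tn, fn = fn),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("TPR %.3f  FPR %.3f  ACC %.3f  MCC %.3f  (TP %.0f FP %.0f TN %.0f FN %.0f)\n",
              x$tpr, x$fpr, x$acc, x$mcc, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

# Match model/reference receptor CA coordinates by res_seq; returns a list of
# paired matrices. Errors list unmatched residues.
.matched_ca <- function(model_chain, ref_chain, res_subset = NULL) {
  rs_m <- chain_res_seq(model_chain); rs_r <- chain_res_seq(ref_chain)
  want <- if (is.null(res_subset)) rs_r else res_subset
  missing_m <- setdiff(want, rs_m)
  if (length(missing_m) > 0) {
    stop("model chain ", model_chain$chain_id, " is missing residues: ",
         paste(missing_m, collapse = ", "))
  }
  cm <- chain_coords(model_chain, atom_name = "CA", res_seq = want)
  cr <- chain_coords(ref_chain, atom_name = "CA", res_seq = want)
  if (nrow(cm) != nrow(cr)) stop("CA atom mismatch between model and reference")
  list(model = cm, ref = cr)
}

#' Interface RMSD (iRMSD) of a dimer model against a reference
#'
#' The receptor CA atoms of the model are superposed onto the reference
#' receptor, then the CA RMSD is computed over the ligand interface residues
#' of the reference complex (10 Angstrom interface rule, evaluated on the
#' reference).
#'
#' @param model,reference `dimer_structure` objects sharing residue
#'   numbering per chain.
#' @param interface_cutoff interface definition cutoff in Angstrom.
#' @return iRMSD in Angstrom.
#' @export
irmsd <- function(model, reference, interface_cutoff = 10.0) {
  stopifnot(inherits(model, "dimer_structure"), inherits(reference, "dimer_structure"))
  iface <- interface_residues(reference, cutoff = interface_cutoff)
  if (length(iface$ligand_residues) == 0L) {
    stop("reference ligand interface is empty at cutoff ", interface_cutoff)
  }
  rec <- .matched_ca(model$receptor, reference$receptor)
  sp <- superpose(rec$model, rec$ref)
  lig <- .matched_ca(model$ligand, reference$ligand, res_subset = iface$ligand_residues)
  rmsd_coords(apply_transform(sp$transform, lig$model), lig$ref)
}

#' Pairwise contact score (PCS)
#'
#' Matthews correlation coefficient between the residue-residue contact maps
#' of a model and a reference complex, over the full receptor x ligand
#' residue-pair universe. Ranges from about 0 (random) to 1 (identical
#' contacts).
#'
#' @param model,reference `dimer_structure` objects over the same residue
#'   universe.
#' @param contact_cutoff residue contact cutoff in Angstrom (default 5).
#' @return PCS value (unitless).
#' @export
pcs <- function(model, reference, contact_cutoff = 5.0) {
  cm_m <- contact_map(model, cutoff = contact_cutoff)
  cm_r <- contact_map(reference, cutoff = contact_cutoff)
  if (nrow(cm_r$contacts) == 0L) stop("reference complex has no contacts")
  universe <- length(cm_r$receptor_residues) * length(cm_r$ligand_residues)
  key <- function(m) paste(m[, 1], m[, 2], sep = "\r")
  km <- key(cm_m$contacts); kr <- key(cm_r$contacts)
  tp <- length(intersect(km, kr))
  fp <- length(setdiff(km, kr))
  fn <- length(setdiff(kr, km))
  tn <- universe - tp - fp - fn
  classify_metrics(tp, fp, tn, fn)$mcc
}

#' Interface-overlap MCC between two dimers
#'
#' Compares per-residue interface membership (10 Angstrom rule) of two
#' dimers whose chains are pairable by sequence position; used for
#' redundancy removal within sequence clusters. The universe is every
#' residue position of both chains.
#'
#' @param a,b `dimer_structure` objects with equal receptor lengths and
#'   equal ligand lengths.
#' @param cutoff interface cutoff in Angstrom.
#' @return MCC over interface membership (unitless).
#' @export
interface_overlap_mcc <- function(a, b, cutoff = 10.0) {
  if (chain_length(a$receptor) != chain_length(b$receptor) ||
      chain_length(a$ligand) != chain_length(b$ligand)) {
    stop("chains are not pairable: unequal lengths")
  }
  ia <- interface_residues(a, cutoff); ib <- interface_residues(b, cutoff)
  # position-indexed membership over receptor then ligand positions
  memb <- function(iface, dimer) {
    c(chain_res_seq(dimer$receptor) %in% iface$receptor_residues,
      chain_res_seq(dimer$ligand) %in% iface$ligand_residues)
  }
  ma <- memb(ia, a); mb <- memb(ib, b)
  tp <- sum(ma & mb); fp <- sum(!ma & mb); fn <- sum(ma & !mb); tn <- sum(!ma & !mb)
  classify_metrics(tp, fp, tn, fn)$mcc
}

#' Model acceptance criteria
#'
#' Thresholds deciding whether a dimer model counts as correct: iRMSD at or
#' below `irmsd_max` and PCS at or above `pcs_min`. Presets follow the
#' benchmark convention: crystal-structure targets use (2.5 Angstrom, 0.65),
#' computer-generated monomer models use (8.5 Angstrom, 0.30).
#'
#' @param source_kind "crystal" or "model", or NULL when passing explicit
#'   thresholds.
#' @param irmsd_max,pcs_min explicit thresholds (override the preset).
#' @return list of class `acceptance_criteria`.
#' @export
acceptance_criteria <- function(source_kind = c("crystal", "model"),
                                irmsd_max = NULL, pcs_min = NULL) {
  if (is.null(irmsd_max) || is.null(pcs_min)) {
    source_kind <- match.arg(source_kind)
    preset <- switch(source_kind,
                     crystal = list(irmsd_max = 2.5, pcs_min = 0.65),
                     model = list(irmsd_max = 8.5, pcs_min = 0.30))
    if (is.null(irmsd_max)) irmsd_max <- preset$irmsd_max
    if (is.null(pcs_min)) pcs_min <- preset$pcs_min
  } else {
    source_kind <- if (is.character(source_kind)) source_kind[1] else "custom"
  }
  if (irmsd_max <= 0) stop("irmsd_max must be positive")
  if (pcs_min <= 0 || pcs_min > 1) stop("pcs_min must be in (0, 1]")
  structure(list(irmsd_max = irmsd_max, pcs_min = pcs_min,
                 source_kind = source_kind),
            class = "acceptance_criteria")
}

#' Per-model quality table for one ranked decoy set
#'
#' @param models list of `dimer_structure` ordered by rank (rank 1 first).
#' @param reference the reference `dimer_structure`.
#' @param criteria an `acceptance_criteria` object.
#' @param contact_cutoff PCS contact cutoff in Angstrom.
#' @return data.frame with rank, irmsd, pcs and pass columns.
#' @export
evaluate_decoys <- function(models, reference,
                            criteria = acceptance_criteria("model"),
                            contact_cutoff = 5.0) {
  stopifnot(length(models) >= 1L)
  ir <- vapply(models, irmsd, numeric(1), reference = reference)
  pc <- vapply(models, pcs, numeric(1), reference = reference,
               contact_cutoff = contact_cutoff)
  data.frame(rank = seq_along(models), irmsd = ir, pcs = pc,
             pass = ir <= criteria$irmsd_max & pc >= criteria$pcs_min)
}

#' Docking success rate over a set of targets
#'
#' Fraction of targets for which at least one model among the top `top_k`
#' ranked decoys satisfies the acceptance criteria (iRMSD and PCS jointly).
#'
#' @param ranked_decoy_sets list of targets; each element is a list with
#'   `models` (ranked list of `dimer_structure`) and `reference`
#'   (a `dimer_structure`).
#' @param criteria an `acceptance_criteria` object.
#' @param top_k number of top-ranked models considered (default 10).
#' @return success rate as a fraction in [0, 1].
#' @export
success_rate <- function(ranked_decoy_sets,
                         criteria = acceptance_criteria("model"),
                         top_k = 10L) {
  if (length(ranked_decoy_sets) == 0L) stop("empty target list")
  hits <- vapply(ranked_decoy_sets, function(tgt) {
    stopifnot(length(tgt$models) >= 1L)
    top <- tgt$models[seq_len(min(top_k, length(tgt$models)))]
    any(evaluate_decoys(top, tgt$reference, criteria)$pass)
  }, logical(1))
  mean(hits)
}

#' Sampling/scoring failure spectrum
#'
#' For each quality threshold t, a target counts as a success when a model
#' with quality >= t sits within the top `top_k`; as a scoring failure when
#' such a model exists somewhere in the sampled pool but not in the top
#' `top_k`; and as a sampling failure when no sampled model reaches t.
#' The three fractions partition the targets at every threshold.
#'
#' @param ranked_decoy_sets list of targets as in [success_rate()].
#' @param quality_fn function(model, reference) -> numeric quality score
#'   (higher is better), e.g. negated iRMSD or PCS.
#' @param thresholds numeric vector of quality thresholds.
#' @param top_k top-of-ranking window (default 10).
#' @param pool_k maximum pool depth considered (default 2000).
#' @return data.frame of class `failure_spectrum` with columns
#'   `quality_threshold`, `success_fraction`, `scoring_failure_fraction`,
#'   `sampling_failure_fraction`.
#' @export
failure_spectrum <- function(ranked_decoy_sets, quality_fn, thresholds,
                             top_k = 10L, pool_k = 2000L) {
  if (length(thresholds) == 0L) stop("empty threshold list")
  if (length(ranked_decoy_sets) == 0L) stop("empty target list")
  qualities <- lapply(ranked_decoy_sets, function(tgt) {
    pool <- tgt$models[seq_len(min(pool_k, length(tgt$models)))]
    vapply(pool, quality_fn, numeric(1), tgt$reference)
  })
  rows <- lapply(thresholds, function(t) {
    status <- vapply(qualities, function(q) {
      in_top <- any(q[seq_len(min(top_k, length(q)))] >= t)
      in_pool <- any(q >= t)
      if (in_top) "success" else if (in_pool) "scoring" else "sampling"
    }, character(1))
    n <- length(status)
    data.frame(quality_threshold = t,
               success_fraction = sum(status == "success") / n,
               scoring_failure_fraction = sum(status == "scoring") / n,
               sampling_failure_fraction = sum(status == "sampling") / n)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("failure_spectrum", class(out))
  out
}

#' Write a per-target metric table as TSV
#' @param metrics data.frame (e.g. from [evaluate_decoys()] with a target
#'   column added).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(metrics, path) {
  utils::write.table(metrics, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
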