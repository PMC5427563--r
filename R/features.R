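#' Canonical binding-energy feature names
#'
#' The ten per-model binding-energy terms consumed by the interaction
#' classifier, in fixed column order: global energy, attractive and
#' repulsive van der Waals potentials, atomic contact energy, internal
#' energy, hydrogen bonds, partial electrostatics, disulfide bonds,
#' pi-stacking and aliphatic interactions.
#'
#' @return character vector of the ten feature column names.
#' @export
energy_feature_names <- function() {
  c("global_energy", "vdw_attractive", "vdw_repulsive", "atomic_contact_energy",
    "internal_energy", "hbond", "partial_electrostatics", "disulfide",
    "pi_stacking", "aliphatic")
}

#' Read a per-model energy feature table
#'
#' Expects a UTF-8 TSV with a header row naming at least `pair_id`,
#' `model_rank` and the ten canonical energy terms; an optional `label`
#' column (0/1) marks class membership. Extra columns are preserved.
#'
#' @param path TSV file path.
#' @return validated data.frame.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("pair_id", "model_rank", energy_feature_names())
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("feature table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in c("model_rank", energy_feature_names())) {
    v <- df[[col]]
    if (is.character(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn))
    } else {
      vn <- v
      bad <- which(!is.finite(vn))
    }
    if (length(bad) > 0 || any(!is.finite(vn))) {
      bad <- union(bad, which(!is.finite(vn)))
      stop("non-numeric or non-finite value in column '", col, "', row ",
           bad[1])
    }
    df[[col]] <- vn
  }
  key <- paste(df$pair_id, df$model_rank, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (pair_id, model_rank): ", key[duplicated(key)][1])
  }
  if ("label" %in% names(df) && !all(df$label %in% c(0, 1))) {
    stop("label column must contain only 0/1")
  }
  df
}

#' Write a feature table as TSV
#' @param df feature data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Z-score normalize energy features
#'
#' Centers and scales each canonical feature column. When `reference_stats`
#' is supplied (e.g. from the training split), those means/sds are applied;
#' otherwise they are estimated from the table and returned for reuse on
#' held-out data. Constant columns are set to zero with a warning.
#'
#' @param table feature data.frame (canonical columns present).
#' @param reference_stats optional list with `mean` and `sd` named vectors.
#' @return list with `table` (normalized copy) and `stats`.
#' @export
zscore_normalize <- function(table, reference_stats = NULL) {
  if (nrow(table) == 0L) stop("empty feature table")
  cols <- energy_feature_names()
  if (is.null(reference_stats)) {
    if (nrow(table) < 2L) stop("need >= 2 rows to estimate normalization stats")
    mu <- vapply(cols, function(c) mean(table[[c]]), numeric(1))
    sd_ <- vapply(cols, function(c) stats::sd(table[[c]]), numeric(1))
    reference_stats <- list(mean = mu, sd = sd_)
  }
  mu <- reference_stats$mean; sd_ <- reference_stats$sd
  for (c in cols) {
    if (sd_[[c]] == 0) {
      warning("constant column '", c, "' normalized to zeros")
      table[[c]] <- rep(0, nrow(table))
    } else {
      table[[c]] <- (table[[c]] - mu[[c]]) / sd_[[c]]
    }
  }
  list(table = table, stats = reference_stats)
}

#' Structure-derived surrogate energy features
#'
#' Deterministic contact-derived stand-ins for engine-computed binding
#' energies, so the classifier stages can run on structures alone. Formulas
#' (heavy-atom pair counts between receptor and ligand):
#' attractive vdW = -(pairs in 3.5-6 A), repulsive vdW = pairs < 3 A,
#' atomic contact energy = -(pairs < 4.5 A), hbond = -(N/O-N/O pairs
#' < 3.5 A), aliphatic = -(C-C pairs in 3.5-5 A), global energy = sum of the
#' above; internal energy, partial electrostatics, disulfide (S-S pairs
#' < 2.5 A) and pi-stacking are computed analogously where atom types exist
#' and are 0 otherwise.
#'
#' @param dimer a `dimer_structure`.
#' @return named numeric vector over [energy_feature_names()].
#' @export
surrogate_features <- function(dimer) {
  stopifnot(inherits(dimer, "dimer_structure"))
  ra <- dimer$receptor$atoms; la <- dimer$ligand$atoms
  d2 <- .cross_dist2(as.matrix(ra[, c("x", "y", "z")]),
                     as.matrix(la[, c("x", "y", "z")]))
  er <- ra$element; el <- la$element
  pair_count <- function(lo, hi, mask = NULL) {
    sel <- d2 >= lo^2 & d2 <= hi^2
    if (!is.null(mask)) sel <- sel & mask
    sum(sel)
  }
  polar <- outer(er %in% c("N", "O"), el %in% c("N", "O"), `&`)
  carbon <- outer(er == "C", el == "C", `&`)
  sulfur <- outer(er == "S", el == "S", `&`)
  vdw_attractive <- -pair_count(3.5, 6.0)
  vdw_repulsive <- pair_count(0, 3.0)
  ace <- -pair_count(0, 4.5)
  hbond <- -pair_count(0, 3.5, polar)
  aliphatic <- -pair_count(3.5, 5.0, carbon)
  disulfide <- -pair_count(0, 2.5, sulfur)
  out <- c(
    global_energy = vdw_attractive + vdw_repulsive + ace + hbond + aliphatic,
    vdw_attractive = vdw_attractive,
    vdw_repulsive = vdw_repulsive,
    atomic_contact_energy = ace,
    internal_energy = 0,
    hbond = hbond,
    partial_electrostatics = 0,
    disulfide = disulfide,
    pi_stacking = 0,
    aliphatic = aliphatic
  )
  out[energy_feature_names()]
}
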