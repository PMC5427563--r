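#' Dataset curation configuration
#'
#' Thresholds for benchmark-set construction: homodimer chains share at
#' least `homo_identity_min` percent sequence identity; sequence clusters
#' are formed at `cluster_identity` percent; dimers with interface-overlap
#' MCC above `interface_mcc_max` within a cluster are redundant; dimers need
#' at least `min_interface_residues` interface residues (both chains
#' combined); proteome chains are kept when their length lies in
#' [`min_length`, `max_length`].
#'
#' @param homo_identity_min,cluster_identity percent identities in (0, 100].
#' @param interface_mcc_max redundancy MCC cutoff.
#' @param min_interface_residues minimum combined interface size.
#' @param min_length,max_length residue-count bounds (inclusive).
#' @return list of class `curation_config`.
#' @export
curation_config <- function(homo_identity_min = 85, cluster_identity = 80,
                            interface_mcc_max = 0.5, min_interface_residues = 20L,
                            min_length = 50L, max_length = 600L) {
  stopifnot(homo_identity_min > 0, homo_identity_min <= 100,
            cluster_identity > 0, cluster_identity <= 100,
            min_length > 0, min_length < max_length)
  structure(list(homo_identity_min = homo_identity_min,
                 cluster_identity = cluster_identity,
                 interface_mcc_max = interface_mcc_max,
                 min_interface_residues = as.integer(min_interface_residues),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length)),
            class = "curation_config")
}

.check_aa <- function(seq) {
  if (length(seq) != 1L || !nzchar(seq)) stop("empty sequence")
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seq)) {
    stop("invalid amino-acid characters in sequence")
  }
  seq
}

#' Global pairwise sequence identity
#'
#' Needleman-Wunsch global alignment (BLOSUM62, end gaps penalized) with
#' identity defined as the number of identical aligned positions divided by
#' the alignment length, times 100.
#'
#' @param seq_a,seq_b amino-acid sequences (character scalars).
#' @return percent identity in [0, 100].
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  .check_aa(seq_a); .check_aa(seq_b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  aligned_len <- nchar(as.character(Biostrings::alignedPattern(aln)))
  100 * Biostrings::nmatch(aln) / aligned_len
}

#' Classify a dimer as homo- or hetero-dimer
#'
#' Homodimers are dimers whose chains share at least
#' `config$homo_identity_min` percent sequence identity (boundary
#' inclusive); otherwise the dimer is a heterodimer.
#'
#' @param dimer a `dimer_structure`, or a list with `receptor`/`ligand`
#'   sequences as character scalars.
#' @param config a `curation_config`.
#' @return "homo" or "hetero".
#' @export
classify_dimer <- function(dimer, config = curation_config()) {
  seqs <- if (inherits(dimer, "dimer_structure")) {
    c(chain_sequence(dimer$receptor), chain_sequence(dimer$ligand))
  } else {
    c(dimer$receptor, dimer$ligand)
  }
  id <- pairwise_identity(seqs[1], seqs[2])
  if (id >= config$homo_identity_min) "homo" else "hetero"
}

#' Greedy sequence clustering
#'
#' CD-HIT-style greedy clustering: sequences are sorted by decreasing
#' length; each joins the first cluster whose representative it matches at
#' or above the identity threshold, otherwise it founds a new cluster. The
#' representative is the (longest) founding sequence.
#'
#' @param sequences named character vector of amino-acid sequences.
#' @param identity_threshold percent identity (default 80).
#' @return data.frame: id, cluster (integer), representative (logical).
#' @export
greedy_cluster <- function(sequences, identity_threshold = 80) {
  if (length(sequences) == 0L) stop("no sequences to cluster")
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  ord <- order(-nchar(sequences), names(sequences))
  reps <- character(0)     # representative sequences
  rep_ids <- character(0)
  assignment <- integer(length(sequences)); names(assignment) <- names(sequences)
  for (i in ord) {
    s <- sequences[[i]]
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (pairwise_identity(s, reps[[k]]) >= identity_threshold) {
        assignment[names(sequences)[i]] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, s)
      rep_ids <- c(rep_ids, names(sequences)[i])
      assignment[names(sequences)[i]] <- length(reps)
    }
  }
  data.frame(id = names(sequences),
             cluster = unname(assignment),
             representative = names(sequences) %in% rep_ids)
}

#' Remove interface-redundant dimers within a cluster
#'
#' Greedy retention in input order: a dimer is dropped when its
#' interface-overlap MCC against any already retained dimer exceeds
#' `config$interface_mcc_max`.
#'
#' @param dimers list of `dimer_structure`, pairable for
#'   [interface_overlap_mcc()].
#' @param config a `curation_config`.
#' @return list of retained dimers.
#' @export
remove_redundant_interfaces <- function(dimers, config = curation_config()) {
  retained <- list()
  for (d in dimers) {
    redundant <- any(vapply(retained, function(r) {
      interface_overlap_mcc(d, r) > config$interface_mcc_max
    }, logical(1)))
    if (!redundant) retained[[length(retained) + 1L]] <- d
  }
  retained
}

#' Length and redundancy filter for proteome sequences
#'
#' Keeps sequences with `min_length <= length <= max_length` (targets
#' strictly longer than the maximum or strictly shorter than the minimum
#' are removed) and drops exact duplicate sequences, keeping the first.
#'
#' @param proteins named character vector of sequences.
#' @param config a `curation_config`.
#' @return filtered named character vector.
#' @export
proteome_filter <- function(proteins, config = curation_config()) {
  if (length(proteins) == 0L) return(proteins)
  len <- nchar(proteins)
  keep <- len >= config$min_length & len <= config$max_length
  out <- proteins[keep]
  out[!duplicated(out)]
}

#' Minimum-interface-size filter for dimers
#'
#' Keeps dimers whose total interface residue count (receptor plus ligand,
#' 10 Angstrom rule) is at least `config$min_interface_residues`.
#'
#' @param dimers list of `dimer_structure`.
#' @param config a `curation_config`.
#' @return list of retained dimers.
#' @export
min_interface_filter <- function(dimers, config = curation_config()) {
  keep <- vapply(dimers, function(d) {
    iface <- interface_residues(d, cutoff = 10.0)
    length(iface$receptor_residues) + length(iface$ligand_residues) >=
      config$min_interface_residues
  }, logical(1))
  dimers[keep]
}

#' Ligand-swap negative pair construction
#'
#' Builds putative non-interacting pairs by a seeded random derangement of
#' ligand assignments among homodimers: every receptor is paired with the
#' ligand of a different dimer, no dimer keeps its own ligand, and the
#' ligand multiset is preserved. Swaps that reproduce a known positive pair
#' are re-drawn.
#'
#' @param homo_dimers character vector (or list) of dimer identifiers; the
#'   i-th receptor is `receptor_id[i]`, its own ligand `ligand_id[i]`.
#'   Alternatively a data.frame with columns `receptor_id`, `ligand_id`.
#' @param seed integer seed.
#' @param known_pairs optional data.frame with `receptor_id`, `ligand_id`
#'   of known positive pairs to avoid.
#' @param max_tries derangement re-draw budget.
#' @return data.frame: receptor_id, ligand_id, source_dimer (index whose
#'   ligand was taken), seed.
#' @export
swap_ligands <- function(homo_dimers, seed = 1L, known_pairs = NULL,
                         max_tries = 1000L) {
  df <- if (is.data.frame(homo_dimers)) {
    homo_dimers
  } else {
    data.frame(receptor_id = as.character(homo_dimers),
               ligand_id = paste0(as.character(homo_dimers), "_ligand"))
  }
  n <- nrow(df)
  if (n < 2L) stop("need at least 2 dimers for a ligand derangement")
  forbidden <- if (is.null(known_pairs)) character(0) else
    paste(known_pairs$receptor_id, known_pairs$ligand_id, sep = "\r")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (try in seq_len(max_tries)) {
    perm <- sample.int(n)
    if (any(perm == seq_len(n))) next  # not a derangement
    key <- paste(df$receptor_id, df$ligand_id[perm], sep = "\r")
    if (any(key %in% forbidden)) next  # reproduces a known positive
    return(data.frame(receptor_id = df$receptor_id,
                      ligand_id = df$ligand_id[perm],
                      source_dimer = perm,
                      seed = seed))
  }
  stop("no admissible derangement found in ", max_tries, " draws")
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences to a FASTA file
#' @param sequences named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
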