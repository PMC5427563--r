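# 3-letter -> 1-letter amino acid codes (standard 20; unknowns map to "X")
.AA321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

#' Construct a chain structure
#'
#' A `chain_structure` holds the heavy atoms of one protein chain in PDB
#' numbering, ordered by residue number. It is the atomic unit consumed by
#' every distance-based computation in the package; hydrogens are excluded
#' by convention at parse time.
#'
#' @param chain_id single-character chain label.
#' @param atoms data.frame with columns `res_seq` (integer), `res_name`
#'   (3-letter code), `atom_name`, `element`, `x`, `y`, `z` (Angstrom).
#' @return an object of class `chain_structure`.
#' @export
chain_structure <- function(chain_id, atoms) {
  stopifnot(is.character(chain_id), length(chain_id) == 1L, nchar(chain_id) == 1L)
  req <- c("res_seq", "res_name", "atom_name", "element", "x", "y", "z")
  if (!all(req %in% names(atoms))) {
    stop("atoms must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("chain '", chain_id, "' has no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates in chain '", chain_id, "'")
  }
  if (any(!nzchar(atoms$atom_name))) stop("empty atom name in chain '", chain_id, "'")
  atoms <- atoms[order(atoms$res_seq), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(chain_id = chain_id, atoms = atoms), class = "chain_structure")
}

#' @export
print.chain_structure <- function(x, ...) {
  cat(sprintf("<chain_structure> chain %s: %d residues, %d heavy atoms\n",
              x$chain_id, chain_length(x), nrow(x$atoms)))
  invisible(x)
}

#' Number of residues in a chain
#' @param chain a `chain_structure`.
#' @return integer residue count.
#' @export
chain_length <- function(chain) {
  stopifnot(inherits(chain, "chain_structure"))
  length(unique(chain$atoms$res_seq))
}

#' One-letter sequence of a chain
#' @param chain a `chain_structure`.
#' @return character scalar; unknown residue types become "X".
#' @export
chain_sequence <- function(chain) {
  stopifnot(inherits(chain, "chain_structure"))
  a <- chain$atoms
  first <- a[!duplicated(a$res_seq), , drop = FALSE]
  one <- .AA321[first$res_name]
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}

#' Residue numbers of a chain, in order
#' @param chain a `chain_structure`.
#' @return integer vector of `res_seq` values.
#' @export
chain_res_seq <- function(chain) {
  stopifnot(inherits(chain, "chain_structure"))
  sort(unique(chain$atoms$res_seq))
}

# Coordinate matrix (n_atoms x 3) for a chain, optionally restricted to an
# atom name and/or residue set. Returns a matrix with res_seq as an attribute.
chain_coords <- function(chain, atom_name = NULL, res_seq = NULL) {
  a <- chain$atoms
  if (!is.null(atom_name)) a <- a[a$atom_name %in% atom_name, , drop = FALSE]
  if (!is.null(res_seq)) a <- a[a$res_seq %in% res_seq, , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  attr(m, "res_seq") <- a$res_seq
  m
}

#' Construct a dimer structure
#'
#' Pairs a receptor and a ligand chain into one complex. Chain roles are
#' normally assigned with [assign_roles()]; this constructor only validates.
#'
#' @param receptor,ligand `chain_structure` objects with distinct chain ids.
#' @param label identifier for the complex.
#' @return an object of class `dimer_structure`.
#' @export
dimer_structure <- function(receptor, ligand, label = "dimer") {
  stopifnot(inherits(receptor, "chain_structure"), inherits(ligand, "chain_structure"))
  if (receptor$chain_id == ligand$chain_id) {
    stop("receptor and ligand must have distinct chain ids")
  }
  structure(list(receptor = receptor, ligand = ligand, label = label),
            class = "dimer_structure")
}

#' @export
print.dimer_structure <- function(x, ...) {
  cat(sprintf("<dimer_structure> %s: receptor %s (%d res), ligand %s (%d res)\n",
              x$label, x$receptor$chain_id, chain_length(x$receptor),
              x$ligand$chain_id, chain_length(x$ligand)))
  invisible(x)
}

#' Assign receptor/ligand roles to two chains
#'
#' The larger monomer (more residues) becomes the receptor and the smaller
#' the ligand. When both chains have the same residue count the chain with
#' the lexicographically smaller chain id becomes the receptor.
#'
#' @param chain_a,chain_b `chain_structure` objects with distinct chain ids.
#' @param label identifier for the resulting dimer.
#' @return a `dimer_structure`.
#' @export
assign_roles <- function(chain_a, chain_b, label = "dimer") {
  stopifnot(inherits(chain_a, "chain_structure"), inherits(chain_b, "chain_structure"))
  if (chain_a$chain_id == chain_b$chain_id) stop("chains must have distinct chain ids")
  la <- chain_length(chain_a)
  lb <- chain_length(chain_b)
  a_is_receptor <- if (la != lb) la > lb else chain_a$chain_id < chain_b$chain_id
  if (a_is_receptor) {
    dimer_structure(chain_a, chain_b, label = label)
  } else {
    dimer_structure(chain_b, chain_a, label = label)
  }
}

#' Read protein chains from a PDB file
#'
#' Parses the ATOM-record subset of the PDB format. HETATM records, waters
#' and hydrogen atoms are skipped; alternate locations keep the first-seen
#' conformer of each atom; insertion codes are rejected.
#'
#' @param source path to a PDB file, or a character vector of PDB lines.
#' @return list of `chain_structure`, one per distinct chain id, in file order.
#' @export
read_pdb <- function(source) {
  lines <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else if (length(source) == 1L && grepl("\n", source)) {
    strsplit(source, "\n", fixed = TRUE)[[1]]
  } else if (is.character(source)) {
    source
  } else {
    stop("unreadable source: expected a path or PDB text")
  }
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "ATOM ")
  idx <- which(is_atom)
  if (length(idx) == 0L) stop("no ATOM records found (empty structure)")

  fw <- function(ln, from, to) substr(ln, from, to)
  recs <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    ln <- lines[i]
    if (nchar(ln) < 54) stop("malformed ATOM line ", i, ": shorter than 54 columns")
    atom_name <- trimws(fw(ln, 13, 16))
    altloc <- fw(ln, 17, 17)
    res_name <- trimws(fw(ln, 18, 20))
    chain_id <- fw(ln, 22, 22)
    res_seq <- suppressWarnings(as.integer(trimws(fw(ln, 23, 26))))
    icode <- fw(ln, 27, 27)
    x <- suppressWarnings(as.numeric(trimws(fw(ln, 31, 38))))
    y <- suppressWarnings(as.numeric(trimws(fw(ln, 39, 46))))
    z <- suppressWarnings(as.numeric(trimws(fw(ln, 47, 54))))
    if (is.na(res_seq) || is.na(x) || is.na(y) || is.na(z)) {
      stop("malformed ATOM line ", i, ": non-numeric fixed-width field")
    }
    if (!icode %in% c(" ", "")) {
      stop("insertion codes are not supported (ATOM line ", i, ")")
    }
    element <- trimws(fw(ln, 77, 78))
    if (!nzchar(element)) {
      # infer from atom name: first alphabetic character (PDB v2 files)
      element <- sub("^[0-9]*", "", atom_name)
      element <- toupper(substr(element, 1, 1))
    }
    recs[[k]] <- list(chain_id = chain_id, res_seq = res_seq, res_name = res_name,
                      atom_name = atom_name, element = element, altloc = altloc,
                      x = x, y = y, z = z)
  }
  df <- do.call(rbind, lapply(recs, as.data.frame, stringsAsFactors = FALSE))
  df <- df[df$element != "H" & df$element != "D", , drop = FALSE]
  df <- df[df$res_name != "HOH", , drop = FALSE]
  if (nrow(df) == 0L) stop("no heavy protein atoms found (empty structure)")
  # altloc: keep first-seen conformer per (chain, residue, atom)
  key <- paste(df$chain_id, df$res_seq, df$atom_name, sep = "\r")
  df <- df[!duplicated(key), , drop = FALSE]

  chain_ids <- unique(df$chain_id)
  lapply(chain_ids, function(cid) {
    sub <- df[df$chain_id == cid,
              c("res_seq", "res_name", "atom_name", "element", "x", "y", "z"),
              drop = FALSE]
    chain_structure(cid, sub)
  })
}

#' Write chains to a PDB file
#'
#' Emits fixed-width ATOM records with consecutive serial numbers starting
#' at 1, a TER record after each chain and a final END record.
#'
#' @param chains list of `chain_structure` (or a single one, or a
#'   `dimer_structure` whose receptor and ligand are written in order).
#' @param destination output file path.
#' @return `destination`, invisibly.
#' @export
write_pdb <- function(chains, destination) {
  if (inherits(chains, "chain_structure")) chains <- list(chains)
  if (inherits(chains, "dimer_structure")) chains <- list(chains$receptor, chains$ligand)
  if (!is.list(chains) || length(chains) == 0L) stop("empty chain list")
  stopifnot(all(vapply(chains, inherits, logical(1), "chain_structure")))
  out <- character(0)
  serial <- 0L
  for (ch in chains) {
    a <- ch$atoms
    for (i in seq_len(nrow(a))) {
      serial <- serial + 1L
      nm <- a$atom_name[i]
      # atom-name column alignment: 1/2-letter element names start in col 14
      nm_fmt <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
      out <- c(out, sprintf(
        "ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nm_fmt, a$res_name[i], ch$chain_id, a$res_seq[i],
        a$x[i], a$y[i], a$z[i], 1.0, 0.0, a$element[i]))
    }
    serial <- serial + 1L
    out <- c(out, sprintf("TER   %5d     %3s %1s%4d",
                          serial, a$res_name[nrow(a)], ch$chain_id, a$res_seq[nrow(a)]))
  }
  out <- c(out, "END")
  writeLines(out, destination)
  invisible(destination)
}
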