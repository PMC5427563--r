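.GO_ASPECTS <- c("CC", "BP", "MF")

#' Load GO-slim annotations from a TSV mapping
#'
#' Expects a tab-separated file with three columns: protein_id, aspect
#' (one of CC, BP, MF) and term_id; no header. Rows are aggregated into one
#' annotation record per protein with a term set per aspect.
#'
#' @param path TSV path (a header row "protein_id ..." is tolerated).
#' @return named list: protein_id -> list(cc_terms, bp_terms, mf_terms).
#' @export
load_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0 && grepl("^protein_id\t", lines[1])) lines <- lines[-1]
  ann <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 3L || any(!nzchar(parts))) {
      stop("malformed annotation row at line ", i)
    }
    pid <- parts[1]; aspect <- parts[2]; term <- parts[3]
    if (!aspect %in% .GO_ASPECTS) {
      stop("unknown GO aspect '", aspect, "' at line ", i)
    }
    if (is.null(ann[[pid]])) {
      ann[[pid]] <- list(cc_terms = character(0), bp_terms = character(0),
                         mf_terms = character(0))
    }
    slot <- c(CC = "cc_terms", BP = "bp_terms", MF = "mf_terms")[[aspect]]
    ann[[pid]][[slot]] <- union(ann[[pid]][[slot]], term)
  }
  ann
}

#' Shared GO-slim term test for a protein pair
#'
#' @param a,b annotation records (elements of [load_annotations()] output).
#' @param aspect "CC", "BP" or "MF".
#' @return "yes" when the term sets intersect, "no" when both are non-empty
#'   but disjoint, "unannotated" when either side has no terms in this
#'   aspect (a missing record counts as unannotated).
#' @export
shares_term <- function(a, b, aspect = c("CC", "BP", "MF")) {
  aspect <- match.arg(aspect)
  slot <- c(CC = "cc_terms", BP = "bp_terms", MF = "mf_terms")[[aspect]]
  ta <- if (is.null(a)) character(0) else a[[slot]]
  tb <- if (is.null(b)) character(0) else b[[slot]]
  if (length(ta) == 0L || length(tb) == 0L) return("unannotated")
  if (length(intersect(ta, tb)) > 0L) "yes" else "no"
}

#' Apply the GO co-annotation filter cascade
#'
#' Filters predicted pairs sequentially by aspect: a pair survives a stage
#' when both proteins share at least one slim term in that aspect. Pairs
#' with an unannotated member are dropped or kept according to
#' `unannotated_policy`. The default cascade is CC then BP; MF is available
#' but excluded by default (it does not discriminate interacting from
#' non-interacting pairs).
#'
#' @param pairs data.frame with columns `protein_a`, `protein_b`.
#' @param annotations output of [load_annotations()] (or an equivalently
#'   shaped list).
#' @param cascade character vector of aspects applied in order.
#' @param unannotated_policy "drop" (default) or "keep".
#' @return list with `retained` (filtered pairs data.frame) and
#'   `stage_counts` (data.frame: stage, n_in, n_out).
#' @export
apply_filter_cascade <- function(pairs, annotations, cascade = c("CC", "BP"),
                                 unannotated_policy = c("drop", "keep")) {
  unannotated_policy <- match.arg(unannotated_policy)
  if (!all(cascade %in% .GO_ASPECTS)) {
    stop("unknown aspect in cascade: ",
         paste(setdiff(cascade, .GO_ASPECTS), collapse = ", "))
  }
  counts <- data.frame(stage = character(0), n_in = integer(0), n_out = integer(0))
  cur <- pairs
  for (aspect in cascade) {
    n_in <- nrow(cur)
    if (n_in > 0) {
      verdict <- vapply(seq_len(n_in), function(i) {
        shares_term(annotations[[cur$protein_a[i]]],
                    annotations[[cur$protein_b[i]]], aspect)
      }, character(1))
      keep <- verdict == "yes" |
        (verdict == "unannotated" & unannotated_policy == "keep")
      cur <- cur[keep, , drop = FALSE]
    }
    counts <- rbind(counts, data.frame(stage = aspect, n_in = n_in,
                                       n_out = nrow(cur)))
  }
  rownames(cur) <- NULL
  list(retained = cur, stage_counts = counts)
}

#' Write annotations to the TSV mapping dialect
#' @param annotations list as from [load_annotations()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  rows <- character(0)
  for (pid in names(annotations)) {
    a <- annotations[[pid]]
    for (aspect in .GO_ASPECTS) {
      slot <- c(CC = "cc_terms", BP = "bp_terms", MF = "mf_terms")[[aspect]]
      for (term in a[[slot]]) {
        rows <- c(rows, paste(pid, aspect, term, sep = "\t"))
      }
    }
  }
  writeLines(rows, path)
  invisible(path)
}
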