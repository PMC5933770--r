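#' Assemble a protein record
#'
#' Bundles everything the feature extractor needs to know about one protein:
#' its sequence, the C-alpha trace of a (predicted) structural model, a
#' position-wise amino-acid frequency profile, optional per-position missense
#' pathogenicity scores, and gene-level annotations. All positions are
#' 1-based and inclusive.
#'
#' @param id protein identifier.
#' @param sequence character vector of one-letter residue codes, or a single
#'   string that is split into residues.
#' @param calpha numeric matrix with one row per residue and columns x, y, z
#'   (Angstrom).
#' @param profile numeric matrix, one row per residue, 20 columns in
#'   alphabetical one-letter amino-acid order; each row is a frequency vector
#'   summing to 1. Rows off by at most `1e-3` are renormalised; worse rows
#'   are a validation failure.
#' @param missense_scores optional numeric matrix, one row per residue, 19
#'   columns of predicted missense pathogenicity scores in `[0, 1]` (one per
#'   possible substitution).
#' @param annotations a list from [gene_annotations()].
#' @return an object of class `protein_record`.
#' @seealso [validate_protein()]
#' @export
protein_record <- function(id, sequence, calpha, profile,
                           missense_scores = NULL,
                           annotations = gene_annotations()) {
  if (length(sequence) == 1L && nchar(sequence[1L]) > 1L)
    sequence <- strsplit(sequence, "")[[1L]]
  calpha <- as.matrix(calpha)
  profile <- as.matrix(profile)
  # forgiving renormalisation for rows off by float noise (<= 1e-3)
  rs <- rowSums(profile)
  fix <- which(is.finite(rs) & rs > 0 & abs(rs - 1) <= 1e-3)
  if (length(fix)) profile[fix, ] <- profile[fix, , drop = FALSE] / rs[fix]
  structure(
    list(id = as.character(id), sequence = as.character(sequence),
         calpha = calpha, profile = profile,
         missense_scores = if (is.null(missense_scores)) NULL
                           else as.matrix(missense_scores),
         annotations = annotations),
    class = "protein_record")
}

#' Gene-level annotations for one protein
#'
#' @param essential logical; the gene is homologous to a known essential gene.
#' @param disease_genecards logical; disease involvement from the primary
#'   (GeneCards-style) source.
#' @param disease_additional logical; disease involvement from additional
#'   gene-disease association sources.
#' @param ppi_count nonnegative integer; number of known protein-protein
#'   interaction partners.
#' @param domain_ranges optional list of `c(start, end)` 1-based inclusive
#'   domain intervals.
#' @return a list of class `gene_annotations`.
#' @export
gene_annotations <- function(essential = FALSE, disease_genecards = FALSE,
                             disease_additional = FALSE, ppi_count = 0L,
                             domain_ranges = NULL) {
  structure(
    list(essential = isTRUE(as.logical(essential)),
         disease_genecards = isTRUE(as.logical(disease_genecards)),
         disease_additional = isTRUE(as.logical(disease_additional)),
         ppi_count = as.integer(ppi_count),
         domain_ranges = domain_ranges),
    class = "gene_annotations")
}

#' Validate a protein record
#'
#' Checks every structural invariant of a [protein_record()] and returns the
#' violations instead of throwing, so a cohort loader can report per-protein
#' problems: the sequence alphabet must be the 20 standard residues, the
#' C-alpha trace must have one row per residue, profile rows must sum to 1
#' (within 1e-6 after the loader's renormalisation), missense score matrices
#' must be N x 19 within `[0, 1]`, domain intervals must lie within the
#' sequence, and the interaction count must be nonnegative.
#'
#' @param record a `protein_record`.
#' @return character vector of human-readable violations; empty when the
#'   record is consistent.
#' @export
validate_protein <- function(record) {
  v <- character(0)
  n <- length(record$sequence)
  bad <- which(!(record$sequence %in% AA20))
  if (length(bad))
    v <- c(v, sprintf("sequence: non-standard residue '%s' at position %d",
                      record$sequence[bad], bad))
  if (!is.matrix(record$calpha) || ncol(record$calpha) != 3L)
    v <- c(v, "calpha: not an N x 3 matrix")
  else if (nrow(record$calpha) != n)
    v <- c(v, sprintf("calpha: length mismatch (%d rows for %d residues)",
                      nrow(record$calpha), n))
  if (!is.matrix(record$profile) || ncol(record$profile) != 20L)
    v <- c(v, "profile: not an N x 20 matrix")
  else {
    if (nrow(record$profile) != n)
      v <- c(v, sprintf("profile: length mismatch (%d rows for %d residues)",
                        nrow(record$profile), n))
    if (any(record$profile < 0))
      v <- c(v, "profile: negative frequency")
    rs <- rowSums(record$profile)
    bad <- which(abs(rs - 1) > 1e-6)
    if (length(bad))
      v <- c(v, sprintf("profile: row %d sums to %.6g, not 1", bad, rs[bad]))
  }
  if (!is.null(record$missense_scores)) {
    ms <- record$missense_scores
    if (!is.matrix(ms) || ncol(ms) != 19L)
      v <- c(v, "missense_scores: not an N x 19 matrix")
    else if (nrow(ms) != n)
      v <- c(v, sprintf("missense_scores: length mismatch (%d rows for %d residues)",
                        nrow(ms), n))
    if (any(ms < 0 | ms > 1, na.rm = TRUE))
      v <- c(v, "missense_scores: value outside [0, 1]")
  }
  ann <- record$annotations
  if (!is.null(ann)) {
    if (is.na(ann$ppi_count) || ann$ppi_count < 0L)
      v <- c(v, "annotations: ppi_count must be a nonnegative integer")
    for (d in ann$domain_ranges) {
      if (length(d) != 2L || d[1L] > d[2L] || d[1L] < 1L || d[2L] > n)
        v <- c(v, sprintf("annotations: domain interval [%s] outside [1, %d]",
                          paste(d, collapse = "-"), n))
    }
  }
  v
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s: %d residues", x$id, length(x$sequence)))
  cat(sprintf(", missense scores: %s", if (is.null(x$missense_scores)) "no" else "yes"))
  cat(sprintf(", essential=%d disease=%d/%d ppi=%d\n",
              x$annotations$essential, x$annotations$disease_genecards,
              x$annotations$disease_additional, x$annotations$ppi_count))
  invisible(x)
}

#' Construct a truncating-variant table
#'
#' @param protein_id character vector of protein identifiers.
#' @param position 1-based truncation position, counted from the N-terminus.
#' @param type `"frameshift"` or `"nonsense"`. The two are scored
#'   identically; the type is carried through for evaluation subsets only.
#' @param label `"pathogenic"`, `"neutral"` or `"unknown"`.
#' @return a data.frame with columns `protein_id`, `position`, `type`, `label`.
#' @export
truncating_variants <- function(protein_id, position, type, label = "unknown") {
  type <- match.arg(as.character(type), c("frameshift", "nonsense"),
                    several.ok = TRUE)
  label <- match.arg(as.character(label), c("pathogenic", "neutral", "unknown"),
                     several.ok = TRUE)
  out <- data.frame(protein_id = as.character(protein_id),
                    position = as.integer(position),
                    type = type, label = label,
                    stringsAsFactors = FALSE)
  if (any(out$position < 1L)) stop("positions are 1-based; found position < 1")
  out
}
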