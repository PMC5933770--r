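## Per-variant feature extraction. A truncating variant is identified by the
## protein and the 1-based truncation position k; frameshift and nonsense
## variants are featurised identically (both destroy everything C-terminal
## of k).

check_k <- function(record, k) {
  n <- length(record$sequence)
  if (length(k) != 1L || is.na(k) || k < 1L || k > n)
    stop(sprintf("position k=%s out of range [1, %d] for protein '%s'",
                 as.character(k), n, record$id))
  as.integer(k)
}

aa_composition <- function(residues) {
  out <- setNames(numeric(20L), AA20)
  if (length(residues) == 0L) return(out)
  tab <- table(factor(residues, levels = AA20))
  out[] <- as.numeric(tab) / length(residues)
  out
}

#' Wild-type residue one-hot encoding
#'
#' @param record a [protein_record()].
#' @param k 1-based truncation position.
#' @return named 20-vector with a single 1 at the wild-type residue.
#' @export
ref_aa_onehot <- function(record, k) {
  k <- check_k(record, k)
  out <- setNames(numeric(20L), AA20)
  out[record$sequence[k]] <- 1
  out
}

#' Contact composition around the truncation position
#'
#' Amino-acid composition of the structural neighbourhood: all residues
#' `j != k` whose C-alpha lies within `radius` Angstrom of position k's
#' C-alpha, counted unweighted and normalised to sum to 1. Sequence
#' neighbours are included (they are physically within the radius); the
#' position itself is excluded. A position with no contact at all (only
#' possible for pathological models) yields an all-zero block with a
#' warning.
#'
#' @inheritParams ref_aa_onehot
#' @param radius contact radius in Angstrom, default 12.
#' @return named 20-vector summing to 1 (or all zeros when contact-free).
#' @export
contact_composition <- function(record, k, radius = 12.0) {
  k <- check_k(record, k)
  xyz <- record$calpha
  if (is.null(xyz) || nrow(xyz) != length(record$sequence))
    stop(sprintf("protein '%s': missing or inconsistent C-alpha model",
                 record$id))
  d2 <- colSums((t(xyz) - xyz[k, ])^2)
  contacts <- which(d2 <= radius^2)
  contacts <- contacts[contacts != k]
  if (length(contacts) == 0L) {
    warning(sprintf("protein '%s' position %d: no C-alpha contact within %g A",
                    record$id, k, radius))
    return(setNames(numeric(20L), AA20))
  }
  aa_composition(record$sequence[contacts])
}

#' Composition of the domain containing the truncation position
#'
#' Amino-acid composition of the annotated domain interval containing k.
#' When no annotated interval covers k (or no domains are annotated), the
#' whole-protein composition is used as a fallback. This group belongs to
#' the 66-slot candidate schema only; it was eliminated by feature
#' reduction and is absent from the default 46-slot schema.
#'
#' @inheritParams ref_aa_onehot
#' @return named 20-vector summing to 1.
#' @export
domain_composition <- function(record, k) {
  k <- check_k(record, k)
  rng <- NULL
  for (d in record$annotations$domain_ranges)
    if (k >= d[1L] && k <= d[2L]) { rng <- d; break }
  residues <- if (is.null(rng)) record$sequence
              else record$sequence[rng[1L]:rng[2L]]
  aa_composition(residues)
}

per_position_entropy <- function(profile) {
  # Shannon entropy per profile row, with 0*log(0) = 0
  p <- profile
  l <- ifelse(p > 0, log(p), 0)
  -rowSums(p * l)
}

#' Mean-centred sequence entropy at the truncation position
#'
#' Shannon entropy S(k) of the position's amino-acid frequency profile,
#' minus the mean entropy over all positions of the protein. Low values mark
#' evolutionarily conserved positions.
#'
#' @inheritParams ref_aa_onehot
#' @return scalar; sums to zero over all positions of any protein.
#' @export
sequence_entropy <- function(record, k) {
  k <- check_k(record, k)
  s <- per_position_entropy(record$profile)
  unname(s[k] - mean(s))
}

#' Fraction of the protein structure lost to truncation
#'
#' `(N_r - k) / N_r` for a protein of `N_r` residues truncated at position
#' k (counted from the N-terminus).
#'
#' @param n_residues protein length `N_r`.
#' @param k 1-based truncation position.
#' @return scalar in `[0, 1)`.
#' @export
fraction_affected <- function(n_residues, k) {
  if (k < 1L || k > n_residues)
    stop(sprintf("position k=%s out of range [1, %d]", as.character(k),
                 n_residues))
  (n_residues - k) / n_residues
}

#' Mean missense pathogenicity of the lost part
#'
#' For each position strictly after k, the per-position pathogenicity is the
#' fraction of its 19 possible missense substitutions whose predicted score
#' reaches `threshold`; the feature is the mean of these fractions over all
#' lost positions. Truncation at the last residue loses nothing and returns
#' 0.
#'
#' @inheritParams ref_aa_onehot
#' @param threshold score at or above which a substitution counts as
#'   pathogenic, default 0.45.
#' @return scalar in `[0, 1]`.
#' @export
pathogenicity_affected <- function(record, k, threshold = 0.45) {
  k <- check_k(record, k)
  ms <- record$missense_scores
  if (is.null(ms))
    stop(sprintf("protein '%s': missense score matrix required for the pathogenicity feature",
                 record$id))
  n <- length(record$sequence)
  if (k == n) return(0)
  rows <- ms[(k + 1L):n, , drop = FALSE]
  mean(rowMeans(rows >= threshold))
}

#' Gene-level annotation features
#'
#' @param record a [protein_record()].
#' @return named vector `(essential, disease, ppi_count)`: essentiality
#'   indicator, disease involvement as the sum of the two source flags
#'   (0, 1 or 2), and the raw protein-protein interaction count.
#' @export
annotation_features <- function(record) {
  ann <- record$annotations
  if (is.null(ann)) {
    warning(sprintf("protein '%s': no annotations; using zeros", record$id))
    ann <- gene_annotations()
  }
  c(essential = as.numeric(ann$essential),
    disease = as.numeric(ann$disease_genecards) +
      as.numeric(ann$disease_additional),
    ppi_count = as.numeric(ann$ppi_count))
}

#' Build the feature vector for one truncating variant
#'
#' Concatenates the schema's feature groups in order. Frameshift and
#' nonsense variants at the same position yield identical vectors.
#'
#' @param record a [protein_record()].
#' @param k 1-based truncation position.
#' @param schema a [feature_schema()].
#' @param contact_radius contact radius in Angstrom.
#' @param pathogenicity_threshold missense pathogenicity call threshold.
#' @return named numeric vector with one entry per schema slot.
#' @export
build_feature_vector <- function(record, k, schema = feature_schema(),
                                 contact_radius = 12.0,
                                 pathogenicity_threshold = 0.45) {
  k <- check_k(record, k)
  ann <- annotation_features(record)
  parts <- list(
    ref_aa        = function() ref_aa_onehot(record, k),
    contact_comp  = function() contact_composition(record, k, contact_radius),
    domain_comp   = function() domain_composition(record, k),
    entropy       = function() sequence_entropy(record, k),
    frac_affected = function() fraction_affected(length(record$sequence), k),
    essential     = function() ann[["essential"]],
    pathogenicity = function() pathogenicity_affected(record, k,
                                                      pathogenicity_threshold),
    disease       = function() ann[["disease"]],
    ppi           = function() ann[["ppi_count"]])
  groups <- schema_groups(schema)
  vals <- unlist(lapply(groups, function(g) parts[[g]]()), use.names = FALSE)
  setNames(vals, schema$slot)
}

#' Build the feature matrix for a variant table
#'
#' Applies [build_feature_vector()] to every variant. Variants whose
#' features cannot be computed (missing structure, profile or missense
#' matrix) are reported in the `failures` attribute rather than aborting the
#' whole cohort.
#'
#' @param proteins named list of [protein_record()]s.
#' @param variants variant data.frame (`protein_id`, `position`, ...).
#' @param schema a [feature_schema()].
#' @param ... passed to [build_feature_vector()].
#' @return numeric matrix, one row per successfully featurised variant, with
#'   attributes `variants` (the corresponding variant rows) and `failures`
#'   (data.frame of failed rows with a `reason` column).
#' @export
build_feature_matrix <- function(proteins, variants, schema = feature_schema(),
                                 ...) {
  n <- nrow(variants)
  rows <- vector("list", n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    rec <- proteins[[variants$protein_id[i]]]
    if (is.null(rec)) { reason[i] <- "unknown protein"; next }
    rows[[i]] <- tryCatch(
      build_feature_vector(rec, variants$position[i], schema, ...),
      error = function(e) { reason[i] <<- conditionMessage(e); NULL })
  }
  ok <- is.na(reason)
  X <- do.call(rbind, rows[ok])
  if (is.null(X)) X <- matrix(numeric(0), 0L, nrow(schema),
                              dimnames = list(NULL, schema$slot))
  failures <- variants[!ok, , drop = FALSE]
  if (nrow(failures)) failures$reason <- reason[!ok]
  attr(X, "variants") <- variants[ok, , drop = FALSE]
  attr(X, "failures") <- failures
  X
}
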