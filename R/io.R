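## On-disk formats. All tabular inputs are tab-separated with a header row;
## all positions are 1-based and inclusive.
##
##  sequences      one multi-record FASTA, record names = protein ids
##  structures     <id>.pdb per protein; only C-alpha ATOM records are used,
##                 altLoc other than blank/'A' ignored, residues in file order
##  profiles       <id>.tsv per protein: pos, then A..Y (alphabetical
##                 one-letter order), rows = frequency vectors
##  missense       <id>.tsv per protein: pos, then 19 score columns in [0,1]
##  annotations    one table: protein_id, essential, disease_genecards,
##                 disease_additional, ppi_count, domains ("s1-e1;s2-e2" or "")
##  variants       one table: protein_id, position, type, label

read_tsv_checked <- function(path) {
  out <- tryCatch(read.delim(path, stringsAsFactors = FALSE, check.names = FALSE),
                  error = function(e)
                    stop(sprintf("failed to parse '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE))
  out
}

read_profile_tsv <- function(path) {
  tab <- read_tsv_checked(path)
  if (!identical(names(tab)[1L], "pos") || !all(AA20 %in% names(tab)))
    stop(sprintf("profile '%s': expected columns pos, %s", path,
                 paste(AA20, collapse = ",")), call. = FALSE)
  m <- as.matrix(tab[order(tab$pos), AA20])
  rownames(m) <- NULL
  storage.mode(m) <- "double"
  m
}

read_missense_tsv <- function(path) {
  tab <- read_tsv_checked(path)
  if (!identical(names(tab)[1L], "pos") || ncol(tab) != 20L)
    stop(sprintf("missense scores '%s': expected pos + 19 score columns", path),
         call. = FALSE)
  m <- as.matrix(tab[order(tab$pos), -1L])
  rownames(m) <- NULL
  storage.mode(m) <- "double"
  m
}

read_calpha_pdb <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop(sprintf("failed to parse PDB '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE))
  a <- pdb$atom
  keep <- a$type == "ATOM" & a$elety == "CA" &
    (is.na(a$alt) | a$alt %in% c("", "A"))
  xyz <- as.matrix(a[keep, c("x", "y", "z")])
  rownames(xyz) <- NULL
  colnames(xyz) <- c("x", "y", "z")
  xyz
}

parse_domain_ranges <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  lapply(strsplit(s, ";", fixed = TRUE)[[1L]], function(tok) {
    se <- suppressWarnings(as.integer(strsplit(tok, "-", fixed = TRUE)[[1L]]))
    if (length(se) != 2L || anyNA(se))
      stop(sprintf("malformed domain interval '%s'", tok), call. = FALSE)
    se
  })
}

#' Load a truncating-variant cohort from disk
#'
#' Reads the sequences, structural models, conservation profiles, optional
#' missense score matrices, gene annotations and the variant table, and
#' assembles per-protein records. Proteins with a missing or inconsistent
#' input (no structure, no profile, sequence/structure length mismatch, ...)
#' are not dropped silently: every variant referencing such a protein is
#' returned as a skip record with a reason, and skips plus loaded variants
#' partition the input variant table exactly.
#'
#' @param fasta_path multi-record FASTA of protein sequences.
#' @param structure_dir directory of `<id>.pdb` C-alpha models.
#' @param profile_dir directory of `<id>.tsv` frequency profiles.
#' @param annotation_table TSV of gene-level annotations.
#' @param variant_table TSV of truncating variants.
#' @param missense_dir optional directory of `<id>.tsv` missense score
#'   matrices.
#' @return a list with `proteins` (named list of [protein_record()]),
#'   `variants` (data.frame of loadable variants) and `skips` (data.frame of
#'   skipped variant rows with a `reason` column).
#' @export
read_cohort <- function(fasta_path, structure_dir, profile_dir,
                        annotation_table, variant_table, missense_dir = NULL) {
  seqs <- tryCatch(Biostrings::readAAStringSet(fasta_path),
                   error = function(e)
                     stop(sprintf("failed to parse FASTA '%s': %s", fasta_path,
                                  conditionMessage(e)), call. = FALSE))
  ids <- sub("\\s.*$", "", names(seqs))
  ann_tab <- read_tsv_checked(annotation_table)
  var_tab <- read_tsv_checked(variant_table)
  need <- c("protein_id", "position", "type", "label")
  if (!all(need %in% names(var_tab)))
    stop(sprintf("variant table '%s': required columns %s", variant_table,
                 paste(need, collapse = ", ")), call. = FALSE)
  var_tab$position <- as.integer(var_tab$position)

  proteins <- list()
  reasons <- character(0)   # per-protein failure reason, by id
  for (i in seq_along(ids)) {
    id <- ids[i]
    spath <- file.path(structure_dir, paste0(id, ".pdb"))
    ppath <- file.path(profile_dir, paste0(id, ".tsv"))
    if (!file.exists(spath)) { reasons[id] <- "no structure"; next }
    if (!file.exists(ppath)) { reasons[id] <- "no profile"; next }
    calpha <- read_calpha_pdb(spath)
    profile <- read_profile_tsv(ppath)
    ms <- NULL
    if (!is.null(missense_dir)) {
      mpath <- file.path(missense_dir, paste0(id, ".tsv"))
      if (file.exists(mpath)) ms <- read_missense_tsv(mpath)
    }
    arow <- ann_tab[ann_tab$protein_id == id, , drop = FALSE]
    ann <- if (nrow(arow) == 0L) {
      warning(sprintf("no annotation row for '%s'; using zeros", id))
      gene_annotations()
    } else {
      gene_annotations(essential = arow$essential[1L] != 0,
                       disease_genecards = arow$disease_genecards[1L] != 0,
                       disease_additional = arow$disease_additional[1L] != 0,
                       ppi_count = arow$ppi_count[1L],
                       domain_ranges = parse_domain_ranges(
                         as.character(arow$domains[1L])))
    }
    rec <- protein_record(id, as.character(seqs[[i]]), calpha, profile,
                          missense_scores = ms, annotations = ann)
    viol <- validate_protein(rec)
    if (length(viol)) {
      reasons[id] <- if (any(grepl("length mismatch", viol)))
        "length mismatch" else viol[1L]
      next
    }
    proteins[[id]] <- rec
  }

  reason_for <- function(pid) {
    if (pid %in% names(proteins)) NA_character_
    else if (pid %in% names(reasons)) reasons[[pid]]
    else "no sequence"
  }
  var_reason <- vapply(var_tab$protein_id, reason_for, character(1))
  ok <- is.na(var_reason)
  # variants referencing a loaded protein must also be inside the sequence
  n_of <- vapply(var_tab$protein_id, function(p)
    if (p %in% names(proteins)) length(proteins[[p]]$sequence) else NA_integer_,
    integer(1))
  out_of_range <- ok & (var_tab$position < 1L | var_tab$position > n_of)
  var_reason[out_of_range] <- "position out of range"
  ok <- ok & !out_of_range

  skips <- var_tab[!ok, , drop = FALSE]
  if (nrow(skips)) skips$reason <- var_reason[!ok] else skips$reason <- character(0)
  rownames(skips) <- NULL
  variants <- var_tab[ok, , drop = FALSE]
  rownames(variants) <- NULL
  list(proteins = proteins, variants = variants, skips = skips)
}

#' Write a prediction table
#'
#' One row per variant with the score (6 decimals), an optional p-value from
#' the fitted extreme-value null, and the binary call. The call threshold is
#' inclusive: `score >= cutoff` is called disease-associated.
#'
#' @param variants data.frame with `protein_id`, `position`, `type`.
#' @param scores numeric scores in `[0, 1]`, one per variant.
#' @param path output TSV path.
#' @param p_values optional numeric p-values, one per variant.
#' @param cutoff call threshold, default 0.5.
#' @return the written data.frame, invisibly.
#' @export
write_predictions <- function(variants, scores, path, p_values = NULL,
                              cutoff = 0.5) {
  n <- nrow(variants)
  if (length(scores) != n)
    stop(sprintf("%d scores for %d variants", length(scores), n))
  if (!all(is.finite(scores))) stop("scores must be finite")
  if (is.null(p_values)) p_values <- rep(NA_real_, n)
  if (length(p_values) != n)
    stop(sprintf("%d p-values for %d variants", length(p_values), n))
  out <- data.frame(protein_id = variants$protein_id,
                    position = variants$position,
                    type = variants$type,
                    score = sprintf("%.6f", scores),
                    p_value = ifelse(is.na(p_values), "NA",
                                     sprintf("%.6g", p_values)),
                    call = ifelse(scores >= cutoff, "disease-associated",
                                  "neutral"),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Read back a prediction table written by [write_predictions()]
#' @param path TSV path.
#' @return data.frame with numeric `score` and `p_value` columns.
#' @export
read_predictions <- function(path) {
  tab <- read_tsv_checked(path)
  tab$score <- as.numeric(tab$score)
  tab$p_value <- suppressWarnings(as.numeric(tab$p_value))
  tab
}
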