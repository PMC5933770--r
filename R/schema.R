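#' Feature schemas for truncating variants
#'
#' The candidate schema has 66 slots in nine contiguous groups: the
#' wild-type residue one-hot (20), the C-alpha contact composition (20), the
#' containing-domain composition (20), the mean-centred sequence entropy
#' (1), and five gene/variant-level values — fraction of the structure lost,
#' gene essentiality, mean missense pathogenicity of the lost part, disease
#' involvement (0/1/2), and the protein-protein interaction count. The final
#' schema drops the domain-composition group (eliminated by leave-one-
#' cluster-out feature reduction), leaving 46 slots.
#'
#' @param id `"final46"` (default) or `"candidate66"`.
#' @param drop_groups optional character vector of group ids to remove (used
#'   by the feature-reduction procedure); groups: `ref_aa`, `contact_comp`,
#'   `domain_comp`, `entropy`, `frac_affected`, `essential`, `pathogenicity`,
#'   `disease`, `ppi`.
#' @return an object of class `feature_schema`: a data.frame with columns
#'   `group` and `slot`, one row per feature slot, in feature order.
#' @export
feature_schema <- function(id = c("final46", "candidate66"),
                           drop_groups = NULL) {
  id <- match.arg(id)
  blocks <- list(
    ref_aa        = paste0("ref_aa_", AA20),
    contact_comp  = paste0("contact_", AA20),
    domain_comp   = paste0("domain_", AA20),
    entropy       = "entropy",
    frac_affected = "frac_affected",
    essential     = "essential",
    pathogenicity = "pathogenicity_affected",
    disease       = "disease",
    ppi           = "ppi_count")
  if (id == "final46") blocks$domain_comp <- NULL
  if (!is.null(drop_groups)) {
    bad <- setdiff(drop_groups, names(blocks))
    if (length(bad))
      stop("unknown feature group(s): ", paste(bad, collapse = ", "))
    blocks <- blocks[setdiff(names(blocks), drop_groups)]
  }
  out <- data.frame(
    group = rep(names(blocks), lengths(blocks)),
    slot = unlist(blocks, use.names = FALSE),
    stringsAsFactors = FALSE)
  structure(out, class = c("feature_schema", "data.frame"), schema_id = id)
}

#' @export
print.feature_schema <- function(x, ...) {
  cat(sprintf("<feature_schema> %s: %d slots in %d groups (%s)\n",
              attr(x, "schema_id"), nrow(x), length(unique(x$group)),
              paste(unique(x$group), collapse = ", ")))
  invisible(x)
}

schema_groups <- function(schema) unique(schema$group)
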