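test_that("wild-type one-hot marks exactly the reference residue", {
  p <- chain_protein("ACD")
  v <- ref_aa_onehot(p, 2)
  expect_equal(unname(v["C"]), 1)
  expect_equal(sum(v), 1)
  expect_equal(unname(ref_aa_onehot(p, 3)["D"]), 1)
  expect_error(ref_aa_onehot(p, 4), "out of range")
  expect_error(ref_aa_onehot(p, 0), "out of range")
})

test_that("contact composition counts neighbours within 12 A, excluding self", {
  # collinear chain at 3.8 A spacing: from residue 1, residues 2-4 lie at
  # 3.8, 7.6, 11.4 A (inside) and residue 5 at 15.2 A (outside)
  p <- chain_protein("ACDEF")
  q <- contact_composition(p, 1)
  expect_equal(unname(q[c("C", "D", "E")]), rep(1 / 3, 3))
  expect_equal(sum(q), 1)
  expect_equal(unname(q["F"]), 0)
  expect_equal(unname(q["A"]), 0)  # self excluded

  # single contact: two residues 5 A apart
  p2 <- protein_record("P2", c("C", "A"), rbind(c(0, 0, 0), c(5, 0, 0)),
                       matrix(1 / 20, 2, 20))
  expect_equal(unname(contact_composition(p2, 2)["C"]), 1)

  # no contact at all: all-zero block with a warning
  p3 <- protein_record("P3", c("A", "C"), rbind(c(0, 0, 0), c(30, 0, 0)),
                       matrix(1 / 20, 2, 20))
  expect_warning(q3 <- contact_composition(p3, 1), "no C-alpha contact")
  expect_equal(sum(q3), 0)
})

test_that("contact composition is invariant under rigid-body motion", {
  set.seed(31)
  co <- cached_cohort()
  for (rep in 1:5) {
    p <- co$proteins[[sample(length(co$proteins), 1)]]
    k <- sample(length(p$sequence), 1)
    q0 <- contact_composition(p, k)
    R <- random_rotation()
    shift <- rnorm(3, sd = 50)
    p_mov <- p
    p_mov$calpha <- sweep(p$calpha %*% R, 2, -shift)
    expect_equal(contact_composition(p_mov, k), q0, tolerance = 1e-12)
  }
})

test_that("domain composition uses the covering interval, else the whole protein", {
  p <- chain_protein("AAC")
  expect_equal(unname(domain_composition(p, 2)[c("A", "C")]), c(2 / 3, 1 / 3))

  p2 <- chain_protein("ACDD", ann = gene_annotations(
    domain_ranges = list(c(1L, 2L))))
  q <- domain_composition(p2, 1)
  expect_equal(unname(q[c("A", "C")]), c(0.5, 0.5))
  expect_equal(sum(q), 1)
  # position 4 is outside the only interval: whole-protein fallback
  expect_equal(unname(domain_composition(p2, 4)[c("A", "C", "D")]),
               c(0.25, 0.25, 0.5))
})

test_that("sequence entropy is the mean-centred Shannon entropy of the profile", {
  prof <- rbind(profile_row(c("A", "C")),        # S = ln 2
                profile_row("D"),                # S = 0
                profile_row(c("E", "F", "G", "H")))  # S = ln 4
  p <- chain_protein("ADE", profile = prof)
  s_mean <- (log(2) + 0 + log(4)) / 3
  expect_equal(sequence_entropy(p, 1), log(2) - s_mean)
  expect_equal(sequence_entropy(p, 2), 0 - s_mean)
  expect_equal(sequence_entropy(p, 3), log(4) - s_mean)

  # identical rows centre to zero everywhere
  p_flat <- chain_protein("ACDE")
  expect_equal(sequence_entropy(p_flat, 2), 0)

  # entropy sums to zero over the positions of any protein
  co <- cached_cohort()
  for (p in co$proteins[1:4]) {
    s <- vapply(seq_along(p$sequence), function(k) sequence_entropy(p, k),
                numeric(1))
    expect_equal(sum(s), 0, tolerance = 1e-9)
  }
})

test_that("fraction affected is (N_r - k) / N_r", {
  expect_equal(fraction_affected(100, 100), 0)
  expect_equal(fraction_affected(100, 1), 0.99)
  expect_equal(fraction_affected(250, 50), 0.8)
  expect_error(fraction_affected(100, 101), "out of range")
})

test_that("pathogenicity of the lost part averages positions strictly after k", {
  ms <- rbind(rep(0.1, 19), rep(0.9, 19), rep(0.1, 19))
  p <- chain_protein("ACD", missense = ms)
  # k=1: position 2 fully pathogenic (19/19), position 3 not (0/19)
  expect_equal(pathogenicity_affected(p, 1), 0.5)
  expect_equal(pathogenicity_affected(p, 2), 0)
  expect_equal(pathogenicity_affected(p, 3), 0)   # nothing lost at k = N_r

  ms_all <- matrix(0.5, 3, 19)
  p2 <- chain_protein("ACD", missense = ms_all)
  expect_equal(pathogenicity_affected(p2, 1), 1)  # all scores >= 0.45

  expect_error(pathogenicity_affected(chain_protein("ACD"), 1),
               "missense score matrix required")
})

test_that("pathogenicity is non-increasing in the threshold", {
  set.seed(8)
  ms <- matrix(runif(20 * 19), 20, 19)
  p <- chain_protein(paste(sample(truncpath:::AA20, 20, TRUE), collapse = ""),
                     missense = ms)
  vals <- vapply(seq(0.1, 0.9, by = 0.1),
                 function(t) pathogenicity_affected(p, 3, threshold = t),
                 numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that("annotation features encode essentiality, additive disease and raw PPI", {
  p <- chain_protein("ACD", ann = gene_annotations(
    essential = TRUE, disease_genecards = TRUE, disease_additional = TRUE,
    ppi_count = 37L))
  expect_equal(annotation_features(p),
               c(essential = 1, disease = 2, ppi_count = 37))
  expect_equal(annotation_features(chain_protein("ACD")),
               c(essential = 0, disease = 0, ppi_count = 0))
  p_gc <- chain_protein("ACD", ann = gene_annotations(disease_genecards = TRUE))
  expect_equal(unname(annotation_features(p_gc)["disease"]), 1)
})

test_that("feature vectors have the schema length and ignore the variant type", {
  co <- cached_cohort()
  p <- co$proteins[[1]]
  k <- 5L
  v46 <- build_feature_vector(p, k, feature_schema("final46"))
  v66 <- build_feature_vector(p, k, feature_schema("candidate66"))
  expect_length(v46, 46L)
  expect_length(v66, 66L)
  expect_identical(names(v46), feature_schema("final46")$slot)

  # frameshift and nonsense at the same position featurise identically
  vars <- truncating_variants(rep(p$id, 2), c(k, k),
                              c("frameshift", "nonsense"),
                              c("unknown", "unknown"))
  X <- build_feature_matrix(co$proteins, vars)
  expect_identical(X[1, ], X[2, ])
})

test_that("one-hot and composition blocks satisfy their sum constraints", {
  co <- cached_cohort()
  sch <- feature_schema("candidate66")
  X <- build_feature_matrix(co$proteins, co$variants[1:40, ], sch)
  for (g in c("ref_aa", "contact_comp", "domain_comp")) {
    block <- X[, sch$slot[sch$group == g], drop = FALSE]
    expect_equal(unname(rowSums(block)), rep(1, nrow(X)), tolerance = 1e-9)
  }
  expect_true(all(X[, sch$slot[sch$group == "ref_aa"]] %in% c(0, 1)))
})

test_that("feature failures are reported per variant, not thrown", {
  co <- cached_cohort()
  p_noms <- co$proteins[[2]]
  p_noms$missense_scores <- NULL
  prots <- co$proteins
  prots[[2]] <- p_noms
  vars <- truncating_variants(c(names(prots)[1], names(prots)[2], "GHOST"),
                              c(3L, 3L, 1L), "nonsense")
  X <- build_feature_matrix(prots, vars)
  expect_equal(nrow(X), 1L)
  fails <- attr(X, "failures")
  expect_equal(nrow(fails), 2L)
  expect_match(fails$reason[1], "missense")
  expect_match(fails$reason[2], "unknown protein")
})
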