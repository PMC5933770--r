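# In-code fixtures: small hand-built proteins with known geometry and
# profiles, and cached synthetic cohorts for the heavier procedures.

# Straight-chain protein: C-alphas on the x axis at 3.8 A spacing, uniform
# profile unless given, no missense scores unless given.
chain_protein <- function(seq, id = "P1", profile = NULL,
                          missense = NULL, ann = gene_annotations(),
                          spacing = 3.8) {
  seq <- if (length(seq) == 1L) strsplit(seq, "")[[1L]] else seq
  n <- length(seq)
  xyz <- cbind(x = spacing * (seq_len(n) - 1L), y = 0, z = 0)
  if (is.null(profile)) {
    profile <- matrix(1 / 20, n, 20L, dimnames = list(NULL, truncpath:::AA20))
  }
  protein_record(id, seq, xyz, profile, missense_scores = missense,
                 annotations = ann)
}

# Profile row helpers: a row concentrated on given residues with equal mass.
profile_row <- function(residues) {
  p <- setNames(numeric(20L), truncpath:::AA20)
  p[residues] <- 1 / length(residues)
  p
}

random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9L), 3L)))
}

# One moderate cohort shared by the expensive evaluation tests.
cached_cohort <- local({
  env <- new.env()
  function() {
    if (is.null(env$co)) {
      env$co <- generate_cohort(cohort_spec(n_proteins = 12L,
                                            n_variants = 120L, seed = 42L))
    }
    env$co
  }
})

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}

# Fixture for the feature-reduction experiment: proteins come in pairs with
# nearly identical amino-acid compositions but opposite unmodelled
# gene-level label tilts (+/- frailty on the logit scale). The
# domain-composition block (here the whole-protein composition: no domain
# annotations) is therefore a protein fingerprint that is marginally
# uncorrelated with the labels by symmetry, yet lets trees learn
# composition->tilt shortcuts in training that are systematically wrong
# for the held-out twin — the planted noise group the reduction step
# should discard. Conservation, lost fraction and annotations carry the
# planted signal as in generate_cohort().
reduce_fixture_cohort <- function(seed, n_pair = 10L, len = 80L, per = 40L,
                                  frailty = 1.2) {
  with_seed_local(seed, {
    aa <- truncpath:::AA20
    rdir <- function(a) { g <- rgamma(length(a), a); g / sum(g) }
    prots <- list(); wlist <- list(); tilt <- c()
    for (i in seq_len(n_pair)) {
      cc <- rdir(rep(0.4, 20))
      for (s in 1:2) {
        id <- sprintf("RP%02d%s", i, c("a", "b")[s])
        sq <- sample(aa, len, TRUE, prob = cc)
        xyz <- cbind(3.8 * seq_len(len), 0, 0)
        w <- rbeta(len, 0.8, 0.8)
        prof <- t(vapply(seq_len(len), function(j) {
          bg <- rdir(rep(0.5, 20)); p <- (1 - w[j]) * bg
          p[match(sq[j], aa)] <- p[match(sq[j], aa)] + w[j]; p
        }, numeric(20)))
        colnames(prof) <- aa
        ms <- t(vapply(seq_len(len), function(j) {
          b <- 0.12 + 0.72 * w[j]; rbeta(19, b * 10, (1 - b) * 10)
        }, numeric(19)))
        ann <- gene_annotations(runif(1) < 0.3, runif(1) < 0.4,
                                runif(1) < 0.2, rgeom(1, 1 / 21))
        prots[[id]] <- protein_record(id, sq, xyz, prof, ms, ann)
        wlist[[id]] <- w
        tilt[id] <- frailty * c(1, -1)[s]
      }
    }
    n <- length(prots) * (per %/% 2L)
    pid <- rep(names(prots), each = per %/% 2L)
    pos <- vapply(pid, function(p) sample.int(len, 1L), integer(1))
    fr <- (len - pos) / len
    cons <- mapply(function(p, k) wlist[[p]][k], pid, pos)
    anns <- vapply(prots[pid], function(p) {
      a <- p$annotations
      (a$essential + (a$disease_genecards + a$disease_additional) / 2 +
         min(a$ppi_count, 50) / 50) / 3
    }, numeric(1))
    eta <- 12 * (fr - mean(fr)) + 8 * (cons - mean(cons)) +
      6 * (anns - mean(anns)) + tilt[pid]
    icpt <- uniroot(function(b) mean(plogis(eta + b)) - 2 / 3, c(-50, 50))$root
    lab <- ifelse(runif(n) < plogis(eta + icpt), "pathogenic", "neutral")
    list(proteins = prots,
         variants = data.frame(protein_id = pid, position = pos,
                               type = "nonsense", label = lab,
                               stringsAsFactors = FALSE))
  })
}
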