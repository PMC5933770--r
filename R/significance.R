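## Extreme-value (Gumbel) calibration of classifier scores. The neutral
## score distribution is fitted with the two-parameter extreme-value law
## whose survival function
##     p(x) = 1 - exp(-exp((mu - x) / sigma))
## gives the p-value of a score x: the probability that a true neutral
## reaches x or more under the fitted null.

#' Extreme-value null parameters
#' @param mu location, in score units.
#' @param sigma scale, in score units; must be positive.
#' @return a list of class `evd_params`.
#' @export
evd_params <- function(mu, sigma) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  structure(list(mu = as.numeric(mu), sigma = as.numeric(sigma)),
            class = "evd_params")
}

#' @export
print.evd_params <- function(x, ...) {
  cat(sprintf("<evd_params> mu = %.4f, sigma = %.4f (p(0.5) = %.3f)\n",
              x$mu, x$sigma, evd_pvalue(0.5, x)))
  invisible(x)
}

#' Score p-value under the extreme-value null
#'
#' Survival function `p(x) = 1 - exp(-exp((mu - x) / sigma))`: strictly
#' decreasing in x, approaching 1 as x decreases and 0 as x increases.
#'
#' @param x score(s).
#' @param params an [evd_params()] (or a list with `mu` and `sigma`).
#' @return p-value(s) in (0, 1).
#' @export
evd_pvalue <- function(x, params) {
  if (params$sigma <= 0) stop("sigma must be > 0")
  -expm1(-exp((params$mu - x) / params$sigma))
}

#' Extreme-value null density
#' @inheritParams evd_pvalue
#' @return density value(s).
#' @export
evd_density <- function(x, params) {
  z <- (params$mu - x) / params$sigma
  exp(z) * exp(-exp(z)) / params$sigma
}

#' Fit the extreme-value null to neutral scores
#'
#' Histograms the neutral scores (density-normalised, fixed bin width on a
#' 0-anchored grid spanning the data), then finds the location and scale
#' minimising the root-mean-square deviation between the extreme-value
#' density at the bin centres and the histogram density. The optimiser is a
#' derivative-free simplex over `(mu, log sigma)` started from the moment
#' estimates (`mean = mu + gamma*sigma`, `var = pi^2 sigma^2 / 6`, gamma the
#' Euler-Mascheroni constant).
#'
#' @param scores numeric neutral scores; at least 100 recommended.
#' @param bin_width histogram bin width in score units, default 0.02.
#' @return an [evd_params()] with attributes `rmsd` (at the optimum),
#'   `rmsd_init` (at the moment start) and `histogram`.
#' @export
fit_evd <- function(scores, bin_width = 0.02) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 2L || var(scores) == 0)
    stop("need non-degenerate scores to fit the null")
  breaks <- seq(floor(min(scores) / bin_width) * bin_width,
                ceiling(max(scores) / bin_width) * bin_width,
                by = bin_width)
  if (length(breaks) < 3L) breaks <- c(breaks[1L] - bin_width, breaks)
  h <- hist(scores, breaks = breaks, plot = FALSE)
  centers <- h$mids
  dens <- h$density
  rmsd <- function(par) {
    prm <- list(mu = par[1L], sigma = exp(par[2L]))
    sqrt(mean((evd_density(centers, prm) - dens)^2))
  }
  gamma_em <- -digamma(1)
  sigma0 <- sqrt(6 * var(scores)) / pi
  mu0 <- mean(scores) - gamma_em * sigma0
  start <- c(mu0, log(sigma0))
  opt <- optim(start, rmsd, method = "Nelder-Mead",
               control = list(reltol = 1e-8, maxit = 5000))
  out <- evd_params(opt$par[1L], exp(opt$par[2L]))
  attr(out, "rmsd") <- opt$value
  attr(out, "rmsd_init") <- rmsd(start)
  attr(out, "histogram") <- data.frame(center = centers, density = dens)
  out
}

#' Exome-level false-discovery-rate estimate
#'
#' For a whole-exome screen where the truly neutral inputs are unknown, the
#' number of false positives at a cutoff is approximated by `p * N_total`
#' (p-value at the cutoff times the number of genes evaluated), so the FDR
#' estimate is `p * N_total / N_pred`, capped at 1.
#'
#' @param p p-value at the chosen score cutoff.
#' @param n_total total number of genes evaluated.
#' @param n_pred number of genes predicted disease-associated at the cutoff;
#'   must be at least 1.
#' @return estimated false discovery rate in `[0, 1]`.
#' @export
estimate_exome_fdr <- function(p, n_total, n_pred) {
  if (n_pred < 1) stop("n_pred must be >= 1: the estimate is undefined with no predictions")
  if (n_total < n_pred) stop("n_total must be >= n_pred")
  min(p * n_total / n_pred, 1.0)
}

#' Estimated FDR as a function of the score cutoff
#'
#' For each cutoff c: the null p-value p(c), the number of scores at or
#' above c, and the exome FDR estimate `p(c) * N_total / N_pred(c)`. Rows
#' where nothing is predicted are flagged undefined. The curve is typically
#' non-monotone: past some cutoff the prediction count drops faster than the
#' p-value does and the estimate rises again.
#'
#' @param scores numeric scores of the screened variants/genes.
#' @param params fitted [evd_params()].
#' @param cutoffs numeric vector of cutoffs, default `seq(0.1, 0.99, 0.01)`.
#' @return data.frame with columns `cutoff`, `p`, `n_pred`, `fdr`,
#'   `undefined`.
#' @export
fdr_vs_cutoff <- function(scores, params, cutoffs = seq(0.1, 0.99, by = 0.01)) {
  if (length(scores) == 0L) stop("no scores")
  n_total <- length(scores)
  n_pred <- vapply(cutoffs, function(c) sum(scores >= c), numeric(1))
  p <- evd_pvalue(cutoffs, params)
  fdr <- ifelse(n_pred >= 1, pmin(p * n_total / n_pred, 1.0), NA_real_)
  data.frame(cutoff = cutoffs, p = p, n_pred = as.integer(n_pred),
             fdr = fdr, undefined = n_pred == 0)
}
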