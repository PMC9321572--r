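# Sampling-completeness assessment: rarefaction, Chao2 incidence-based
# richness, and the sampling fractions fed to the diversification models.

#' Rarefaction curve of unit richness
#'
#' Accumulation-style rarefaction over accessions (sequence records): for
#' each replicate a random permutation of the accessions is drawn and
#' richness is recorded at each grid fraction along its prefixes, so every
#' replicate curve — and hence the median curve — is non-decreasing. The
#' median over replicates is reported per fraction.
#'
#' @param accession_to_unit Character (or factor) vector: the unit of each
#'   accession.
#' @param step Grid step as a fraction (default 0.05, i.e. every 5%).
#' @param reps Number of random permutations (default 100).
#' @param seed Optional integer seed.
#' @return Data frame `fraction`, `n_accessions`, `median_richness`.
#' @export
rarefaction_curve <- function(accession_to_unit, step = 0.05, reps = 100,
                              seed = NULL) {
  units <- as.character(accession_to_unit)
  n <- length(units)
  if (n < 1L) stop("at least one accession is required")
  if (!isTRUE(all.equal(1 / step, round(1 / step)))) {
    warning("step does not divide 100%; grid rounded to multiples of step")
  }
  if (!is.null(seed)) set.seed(seed)
  fracs <- unique(c(seq(step, 1, by = step), 1))
  ks <- pmax(1L, round(fracs * n))
  rich <- matrix(0L, nrow = reps, ncol = length(ks))
  for (r in seq_len(reps)) {
    perm <- sample(units)
    # richness along prefixes: position of first occurrence of each unit
    first <- !duplicated(perm)
    cum <- cumsum(first)
    rich[r, ] <- cum[ks]
  }
  data.frame(fraction = fracs, n_accessions = ks,
             median_richness = apply(rich, 2L, stats::median))
}

#' Chao2 incidence-based richness estimate
#'
#' From a binary unit-by-sample incidence matrix with `R >= 2` samples,
#' using the classic bias-corrected form when there are no duplicates:
#' \deqn{\hat S = S_{obs} + \frac{R-1}{R}\frac{Q_1^2}{2 Q_2}} when
#' \eqn{Q_2 > 0}, else \eqn{\hat S = S_{obs} + \frac{R-1}{R}
#' \frac{Q_1(Q_1-1)}{2}}, where \eqn{Q_1} and \eqn{Q_2} count units found in
#' exactly one and exactly two samples. The implied sampling fraction is
#' \eqn{f = S_{obs}/\hat S}. An approximate 95% interval uses the standard
#' log-normal transformation of the estimated variance.
#'
#' @param inc Binary incidence matrix, rows = units, columns = samples.
#' @return A list of class `"richness_estimate"`: `S_obs`, `Q1`, `Q2`, `R`,
#'   `estimate`, `fraction`, `se`, `lower`, `upper`, `estimator = "chao2"`.
#' @export
chao2_richness <- function(inc) {
  inc <- as.matrix(inc)
  if (!all(inc %in% c(0, 1))) stop("incidence entries must be 0/1")
  R <- ncol(inc)
  if (R < 2L) stop("Chao2 requires at least 2 samples (R >= 2)")
  freq <- rowSums(inc)
  if (any(freq == 0)) stop("incidence table contains empty units")
  S_obs <- nrow(inc)
  Q1 <- sum(freq == 1)
  Q2 <- sum(freq == 2)
  A <- (R - 1) / R
  if (Q2 > 0) {
    T_ <- A * Q1^2 / (2 * Q2)
    q <- Q1 / Q2
    var_ <- Q2 * (A * q^2 / 2 + A^2 * q^3 + A^2 * q^4 / 4)
  } else {
    T_ <- A * Q1 * (Q1 - 1) / 2
    var_ <- A * Q1 * (Q1 - 1) / 2 + A^2 * Q1 * (2 * Q1 - 1)^2 / 4 -
      if (S_obs > 0) A^2 * Q1^4 / (4 * (S_obs + T_)) else 0
  }
  est <- S_obs + T_
  se <- sqrt(max(var_, 0))
  if (T_ > 0 && se > 0) {
    K <- exp(1.96 * sqrt(log(1 + var_ / T_^2)))
    lower <- S_obs + T_ / K
    upper <- S_obs + T_ * K
  } else {
    lower <- upper <- est
  }
  structure(list(S_obs = S_obs, Q1 = Q1, Q2 = Q2, R = R, estimate = est,
                 fraction = S_obs / est, se = se, lower = lower,
                 upper = upper, estimator = "chao2"),
            class = "richness_estimate")
}

#' @export
print.richness_estimate <- function(x, ...) {
  cat(sprintf(
    "%s richness: S_obs = %d, estimate = %.1f (95%% CI %.1f-%.1f), f = %.0f%%\n",
    x$estimator, x$S_obs, x$estimate, x$lower, x$upper, 100 * x$fraction))
  invisible(x)
}

#' Sampling fraction from observed and estimated richness
#'
#' @param observed Observed number of units.
#' @param estimated_total Estimated total richness (>= observed).
#' @return List with `fraction` (exact ratio) and `percent` (rounded to the
#'   percent, the reporting convention of completeness tables).
#' @export
sampling_fraction <- function(observed, estimated_total) {
  stopifnot(is.numeric(observed), is.numeric(estimated_total))
  if (!(observed > 0)) stop("observed must be positive")
  if (observed > estimated_total)
    stop("observed exceeds the estimated total richness")
  f <- observed / estimated_total
  list(fraction = f, percent = round(100 * f))
}

#' Incidence table from a long occurrence table
#'
#' @param units Character vector: unit of each record.
#' @param samples Character vector: sample (e.g. study) of each record.
#' @return Binary incidence matrix, units x samples.
#' @export
incidence_table <- function(units, samples) {
  stopifnot(length(units) == length(samples))
  tab <- table(as.character(units), as.character(samples))
  (unclass(tab) > 0) * 1L
}
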