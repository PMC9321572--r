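#' Simulation configuration for the barcode diversification study
#'
#' Bundles every parameter of the simulation pipeline: a birth-death species
#' tree of fixed crown age, within-species coalescent subtrees grafted at the
#' tips, and a short alignment evolving slowly on a fraction of variable
#' sites. Defaults mirror the study conditions for an ancient fungal clade
#' sampled through an SSU-like barcode: crown age 505 Myr, 2-15 individuals
#' per species coalescing within at most 30 Myr, a 520-bp marker with 25%
#' variable sites evolving at 0.001 substitutions/site/Myr.
#'
#' @param crown_age Crown (root) age of the species tree, Myr.
#' @param lambda Speciation rate, events/lineage/Myr.
#' @param mu Extinction rate, events/lineage/Myr (`0 <= mu <= lambda`).
#' @param n_ind_range Integer range `c(lower, upper)` of individuals sampled
#'   per species for the within-species coalescent.
#' @param max_coal_age Upper bound on the age of within-species coalescent
#'   roots, Myr.
#' @param seq_length Alignment length, sites.
#' @param subst_rate Substitution rate on variable sites,
#'   substitutions/site/Myr.
#' @param p_variable Fraction of alignment columns allowed to vary.
#' @param seed Optional integer seed recorded with the configuration.
#' @return An object of class `"sim_config"` (a validated list). Derived
#'   quantities `net_rate` (\eqn{r = \lambda - \mu}) and `turnover`
#'   (\eqn{\epsilon = \mu/\lambda}) are included.
#' @seealso [sim_config_scenario()] for the pure-birth / birth-death
#'   parameterisation by net rate and turnover.
#' @export
sim_config <- function(crown_age = 505, lambda = 0.010, mu = 0,
                       n_ind_range = c(2L, 15L), max_coal_age = 30,
                       seq_length = 520L, subst_rate = 0.001,
                       p_variable = 0.25, seed = NULL) {
  stopifnot(is.numeric(crown_age), length(crown_age) == 1L, crown_age > 0)
  stopifnot(is.numeric(lambda), length(lambda) == 1L,
            is.numeric(mu), length(mu) == 1L)
  if (!(lambda >= mu && mu >= 0))
    stop("rates must satisfy lambda >= mu >= 0")
  n_ind_range <- as.integer(n_ind_range)
  if (length(n_ind_range) != 2L || any(n_ind_range < 1L) ||
      n_ind_range[1L] > n_ind_range[2L])
    stop("n_ind_range must be c(lower, upper) with 1 <= lower <= upper")
  stopifnot(max_coal_age > 0)
  seq_length <- as.integer(seq_length)
  if (seq_length <= 0L) stop("seq_length must be positive")
  if (subst_rate < 0) stop("subst_rate must be non-negative")
  if (!(p_variable > 0 && p_variable <= 1))
    stop("p_variable must be in (0, 1]")
  structure(list(
    crown_age = crown_age, lambda = lambda, mu = mu,
    net_rate = lambda - mu,
    turnover = if (lambda > 0) mu / lambda else 0,
    n_ind_range = n_ind_range, max_coal_age = max_coal_age,
    seq_length = seq_length, subst_rate = subst_rate,
    p_variable = p_variable, seed = seed
  ), class = "sim_config")
}

#' Configuration from a diversification scenario
#'
#' Parameterises [sim_config()] by net diversification rate and scenario:
#' `"pb"` (pure birth, no extinction) or `"bd"` (constant birth and death with
#' a given turnover). The study's two net rates are 0.010 and 0.015
#' events/lineage/Myr, chosen to yield extant richness comparable to the
#' empirical unit counts.
#'
#' @param scenario `"pb"` or `"bd"`.
#' @param r Net diversification rate \eqn{\lambda - \mu}, events/lineage/Myr.
#' @param turnover Turnover \eqn{\mu/\lambda} used for `"bd"` (ignored for
#'   `"pb"`). Default 0.5.
#' @param ... Further arguments passed to [sim_config()].
#' @return A `"sim_config"` object.
#' @export
sim_config_scenario <- function(scenario = c("pb", "bd"), r = 0.010,
                                turnover = 0.5, ...) {
  scenario <- match.arg(scenario)
  if (scenario == "pb") {
    cfg <- sim_config(lambda = r, mu = 0, ...)
  } else {
    if (!(turnover >= 0 && turnover < 1))
      stop("turnover must be in [0, 1)")
    lambda <- r / (1 - turnover)
    cfg <- sim_config(lambda = lambda, mu = lambda * turnover, ...)
  }
  cfg$scenario <- scenario
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  crown age:      %g Myr\n", x$crown_age))
  cat(sprintf("  lambda / mu:    %g / %g  (r = %g, turnover = %g)\n",
              x$lambda, x$mu, x$net_rate, x$turnover))
  cat(sprintf("  individuals:    %d-%d per species, coalescing within %g Myr\n",
              x$n_ind_range[1L], x$n_ind_range[2L], x$max_coal_age))
  cat(sprintf("  marker:         %d bp, %g%% variable, %g subst/site/Myr\n",
              x$seq_length, 100 * x$p_variable, x$subst_rate))
  invisible(x)
}
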