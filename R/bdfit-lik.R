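# Time-varying birth-death likelihood for reconstructed ultrametric trees
# with incomplete sampling. Notation: t is age (Myr before present),
# lambda(t) the speciation rate, mu(t) the extinction rate, f the sampling
# fraction. E(t) is the probability that a lineage alive at age t leaves no
# sampled descendant at present; it solves
#   dE/dt = mu(t) - (lambda(t) + mu(t)) E + lambda(t) E^2,  E(0) = 1 - f,
# integrated from the present into the past. Each reconstructed branch over
# (t_young, t_old] contributes -(Phi(t_old) - Phi(t_far)) to the
# log-likelihood with Phi(t) = int_0^t (lambda + mu - 2 lambda E) du, each
# branching at age t_i contributes log lambda(t_i), each sampled tip log f,
# and crown-survival conditioning subtracts 2 log(1 - E(T)).

#' Rate model specification
#'
#' Describes a parametric speciation/extinction model for [bd_loglik()],
#' [fit_bd()] and [fit_env()].
#'
#' * speciation `"constant"`: \eqn{\lambda(t) = \lambda_0};
#' * speciation `"exponential"`: \eqn{\lambda(t) = \lambda_0 e^{\alpha t}}
#'   (ages increase into the past, so \eqn{\alpha > 0} means higher rates in
#'   the past, i.e. a decline toward the present);
#' * speciation `"environmental"`: \eqn{\lambda(t) = b\, e^{a\, env(t)}},
#'   with \eqn{env} the smoothed environmental curve; \eqn{a > 0} means the
#'   environmental variable raises speciation rates.
#'
#' Extinction is `"none"`, `"constant"` (free \eqn{\mu}), or `"fixed"`
#' (\eqn{\mu} pinned at `mu_fixed`, used for robustness sweeps at imposed
#' high extinction).
#'
#' @param speciation One of `"constant"`, `"exponential"`, `"environmental"`.
#' @param extinction One of `"none"`, `"constant"`, `"fixed"`.
#' @param f Sampling fraction in (0, 1].
#' @param env An [env_curve()], required for `"environmental"`.
#' @param mu_fixed Fixed extinction rate for `extinction = "fixed"`.
#' @return A list of class `"rate_model"` with a `lambda_fn(par)` /
#'   `mu_fn(par)` factory, parameter names and transform helpers.
#' @export
rate_model <- function(speciation = c("constant", "exponential", "environmental"),
                       extinction = c("none", "constant", "fixed"),
                       f = 1, env = NULL, mu_fixed = NULL) {
  speciation <- match.arg(speciation)
  extinction <- match.arg(extinction)
  if (!(f > 0 && f <= 1)) stop("sampling fraction f must be in (0, 1]")
  env_eval <- NULL
  if (speciation == "environmental") {
    if (is.null(env)) stop("environmental model requires an env_curve")
    if (stats::var(env$value) == 0)
      stop("constant environmental curve: parameters (a, b) are not ",
           "identifiable")
    env_eval <- env_fun(env, warn_extrapolation = FALSE)
  }
  if (extinction == "fixed" && (is.null(mu_fixed) || mu_fixed < 0))
    stop("extinction = 'fixed' requires a non-negative mu_fixed")

  spec_par <- switch(speciation,
                     constant = "lambda0",
                     exponential = c("lambda0", "alpha"),
                     environmental = c("b", "a"))
  ext_par <- if (extinction == "constant") "mu" else character(0)
  lambda_fn <- switch(speciation,
    constant = function(par) { l0 <- par[["lambda0"]]; function(t) rep(l0, length(t)) },
    exponential = function(par) {
      l0 <- par[["lambda0"]]; a <- par[["alpha"]]
      function(t) l0 * exp(a * t)
    },
    environmental = function(par) {
      b <- par[["b"]]; a <- par[["a"]]
      function(t) b * exp(a * env_eval(t))
    })
  mu_fn <- switch(extinction,
    none = function(par) function(t) rep(0, length(t)),
    constant = function(par) { m <- par[["mu"]]; function(t) rep(m, length(t)) },
    fixed = function(par) function(t) rep(mu_fixed, length(t)))
  # positive parameters are optimised on the log scale; alpha/a are free
  positive <- c(lambda0 = TRUE, alpha = FALSE, b = TRUE, a = FALSE,
                mu = TRUE)[c(spec_par, ext_par)]
  structure(list(speciation = speciation, extinction = extinction, f = f,
                 mu_fixed = mu_fixed, env = env,
                 par_names = c(spec_par, ext_par), positive = positive,
                 lambda_fn = lambda_fn, mu_fn = mu_fn,
                 model_id = paste0(speciation, "+",
                                   switch(extinction, none = "mu0",
                                          constant = "muconst",
                                          fixed = sprintf("mufix%g", mu_fixed)))),
            class = "rate_model")
}

# Branch bookkeeping shared by likelihood evaluations on one tree: node
# ages, edge age intervals, branching ages.
.tree_times <- function(tree, tol = 1e-6) {
  if (!ape::is.ultrametric(tree, tol = tol))
    stop("tree must be ultrametric")
  ages <- .node_ages(tree)
  ntip <- ape::Ntip(tree)
  # snap tip ages to exactly 0 and drop sub-nanoMyr float noise, so the ODE
  # solver never sees near-duplicate output times
  ages[seq_len(ntip)] <- 0
  ages <- round(ages, 9)
  crown <- ages[ntip + 1L]
  list(ntip = ntip, crown = crown,
       branching = ages[(ntip + 1L):(ntip + tree$Nnode)],
       t_young = ages[tree$edge[, 2L]],
       t_old = ages[tree$edge[, 1L]])
}

#' Log-likelihood of a reconstructed tree under a birth-death model
#'
#' Evaluates the likelihood of an ultrametric reconstructed tree under a
#' (possibly time-varying) birth-death process with sampling fraction `f`,
#' conditioned on the survival of both crown lineages. The extinction
#' probability \eqn{E(t)} and the cumulative branch integrand
#' \eqn{\Phi(t) = \int_0^t (\lambda + \mu - 2\lambda E)\,du} are integrated
#' jointly with an adaptive solver ([deSolve::ode()], relative tolerance
#' 1e-8). The parameter-free topology constant is omitted; it is identical
#' across all models compared on the same tree.
#'
#' @param tree Ultrametric `phylo` tree.
#' @param model A [rate_model()].
#' @param par Named numeric vector of parameters (see `model$par_names`).
#' @return The log-likelihood (scalar). Attributes `E_crown` (extinction
#'   probability at the crown) are attached.
#' @export
bd_loglik <- function(tree, model, par) {
  stopifnot(inherits(model, "rate_model"))
  tt <- .tree_times(tree)
  .bd_loglik_core(tt, model, par)
}

.bd_loglik_core <- function(tt, model, par) {
  lam <- model$lambda_fn(par)
  mu <- model$mu_fn(par)
  f <- model$f
  times <- sort(unique(c(0, tt$t_young, tt$t_old, tt$crown)))
  # reject rate functions that are non-positive, non-finite or absurdly
  # large over the tree span before handing them to the solver
  lam_grid <- lam(times); mu_grid <- mu(times)
  if (any(!is.finite(lam_grid)) || any(lam_grid <= 0) ||
      any(lam_grid > 1e3) || any(!is.finite(mu_grid)) ||
      any(mu_grid < 0) || any(mu_grid > 1e3))
    return(-Inf)
  rhs <- function(t, y, parms) {
    l <- lam(t); m <- mu(t); E <- y[1L]
    list(c(m - (l + m) * E + l * E * E,
           l + m - 2 * l * E))
  }
  sol <- try(suppressWarnings(
    deSolve::ode(y = c(E = 1 - f, Phi = 0), times = times,
                 func = rhs, parms = NULL, rtol = 1e-8,
                 atol = 1e-10)), silent = TRUE)
  if (!inherits(sol, "try-error") && nrow(sol) < length(times))
    stop("ODE integration of E(t) stopped before the crown age")
  if (inherits(sol, "try-error") || any(!is.finite(sol[, "E"])))
    stop("ODE integration of E(t) failed: ",
         if (inherits(sol, "try-error")) attr(sol, "condition")$message
         else "non-finite E(t)")
  E <- sol[, "E"]; Phi <- sol[, "Phi"]
  if (any(E < -1e-6 | E > 1 + 1e-6))
    stop(sprintf("E(t) left [0,1] (range %.3g..%.3g); model mis-specified?",
                 min(E), max(E)))
  idx <- function(a) match(a, times)
  E_crown <- E[idx(tt$crown)]
  if (E_crown >= 1) return(-Inf)
  lam_branching <- lam(tt$branching)
  if (any(lam_branching <= 0)) return(-Inf)
  ll <- tt$ntip * log(f) +
    sum(log(lam_branching)) -
    sum(Phi[idx(tt$t_old)] - Phi[idx(tt$t_young)]) -
    2 * log(1 - E_crown)
  attr(ll, "E_crown") <- E_crown
  ll
}

#' Lineage-through-time curve
#'
#' Number of reconstructed lineages as a function of age: 2 just below the
#' crown, +1 at each branching, ending at the tip count at age 0.
#'
#' @param tree Ultrametric `phylo` tree.
#' @return Data frame `age` (decreasing from the crown age to 0) and
#'   `n_lineages` (count valid on the interval from that age down to the
#'   next row's age).
#' @export
compute_ltt <- function(tree) {
  tt <- .tree_times(tree)
  ages <- sort(tt$branching, decreasing = TRUE)
  data.frame(age = c(ages, 0),
             n_lineages = c(seq_along(ages) + 1L, tt$ntip))
}
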