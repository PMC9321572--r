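# Maximum-likelihood fitting of birth-death models, AICc model comparison.

# Transform between the optimiser scale (positive parameters logged) and
# the natural scale.
.to_natural <- function(theta, model) {
  par <- ifelse(model$positive, exp(theta), theta)
  names(par) <- model$par_names
  par
}
.to_theta <- function(par, model) {
  ifelse(model$positive, log(pmax(par, 1e-12)), par)
}

# Crude rate-of-accumulation initial guess: a Yule-like lambda from tip
# count and crown age.
.init_par <- function(tt, model) {
  lam0 <- max(log(max(tt$ntip, 3) / 2) / tt$crown, 1e-4)
  init <- c(lambda0 = lam0, alpha = 0, b = lam0, a = 0, mu = lam0 / 4)
  init[model$par_names]
}

#' Fit birth-death models by maximum likelihood
#'
#' Fits one or more time-dependent speciation models (constant and/or
#' exponential \eqn{\lambda_0 e^{\alpha t}}) with the requested extinction
#' treatment, by multi-start Nelder-Mead (single positive parameters by
#' Brent) on log-transformed positive parameters. When `mu_fixed` values are
#' supplied, one additional fit per value is produced with extinction pinned
#' (robustness to imposed high extinction).
#'
#' @param tree Ultrametric `phylo` tree (>= 3 tips).
#' @param models Character vector among `"constant"`, `"exponential"`.
#' @param f Sampling fraction in (0, 1].
#' @param extinction `"none"` or `"constant"`.
#' @param mu_fixed Optional numeric vector of pinned extinction rates.
#' @param n_starts Number of optimiser starts (first at a moment-based
#'   initial guess, the rest jittered).
#' @param seed Optional seed for the start jitter.
#' @return A list of `"bd_fit"` objects (one per fitted model), each with
#'   `model_id`, `par`, `logL`, `k`, `n`, `aicc`, `converged`, `lambda_at`
#'   (fitted rate function of age) and `crown_age`.
#' @export
fit_bd <- function(tree, models = c("constant", "exponential"), f = 1,
                   extinction = c("none", "constant"), mu_fixed = NULL,
                   n_starts = 10, seed = NULL) {
  extinction <- match.arg(extinction)
  if (ape::Ntip(tree) < 3L) stop("at least 3 tips are required")
  models <- match.arg(models, c("constant", "exponential"), several.ok = TRUE)
  specs <- lapply(models, function(m)
    rate_model(speciation = m, extinction = extinction, f = f))
  if (!is.null(mu_fixed))
    specs <- c(specs, unlist(lapply(models, function(m)
      lapply(mu_fixed, function(ms)
        rate_model(speciation = m, extinction = "fixed", f = f,
                   mu_fixed = ms))), recursive = FALSE))
  fits <- lapply(specs, function(sp)
    .fit_model(tree, sp, n_starts = n_starts, seed = seed))
  names(fits) <- vapply(fits, `[[`, character(1L), "model_id")
  fits
}

#' Fit an environment-dependent speciation model
#'
#' Maximum-likelihood fit of \eqn{\lambda(t) = b\, e^{a\, env(t)}} with the
#' environmental curve evaluated through its smoothing spline. A positive
#' fitted `a` means the environmental variable (e.g. temperature) raises
#' speciation rates.
#'
#' @param tree Ultrametric `phylo` tree.
#' @param env An [env_curve()]; must not be constant.
#' @param f Sampling fraction.
#' @param extinction `"none"` or `"constant"`.
#' @param n_starts,seed Optimiser controls as in [fit_bd()].
#' @return A `"bd_fit"` object.
#' @export
fit_env <- function(tree, env, f = 1, extinction = c("none", "constant"),
                    n_starts = 10, seed = NULL) {
  extinction <- match.arg(extinction)
  sp <- rate_model(speciation = "environmental", extinction = extinction,
                   f = f, env = env)
  .fit_model(tree, sp, n_starts = n_starts, seed = seed)
}

.fit_model <- function(tree, model, n_starts = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tt <- .tree_times(tree)
  negll <- function(theta) {
    par <- .to_natural(theta, model)
    ll <- try(.bd_loglik_core(tt, model, par), silent = TRUE)
    if (inherits(ll, "try-error") || !is.finite(ll)) return(1e10)
    -as.numeric(ll)
  }
  theta0 <- .to_theta(.init_par(tt, model), model)
  k <- length(theta0)
  best <- NULL
  n_try <- max(1L, n_starts)
  for (s in seq_len(n_try)) {
    th <- if (s == 1L) theta0 else theta0 + stats::rnorm(k, 0, 0.7)
    if (k == 1L) {
      op <- try(stats::optim(th, negll, method = "Brent",
                             lower = th - 12, upper = th + 8,
                             control = list(reltol = 1e-8)), silent = TRUE)
    } else {
      op <- try(stats::optim(th, negll, method = "Nelder-Mead",
                             control = list(reltol = 1e-8, maxit = 2000)),
                silent = TRUE)
    }
    if (inherits(op, "try-error")) next
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best) || best$value >= 1e10) {
    warning("optimisation failed to converge for model ", model$model_id)
    return(structure(list(model_id = model$model_id, par = NULL,
                          logL = NA_real_, k = k, n = length(tt$branching),
                          aicc = NA_real_, converged = FALSE,
                          crown_age = tt$crown, f = model$f,
                          model = model), class = "bd_fit"))
  }
  par <- .to_natural(best$par, model)
  logL <- -best$value
  n <- length(tt$branching)   # branching-time count = internal nodes
  aicc <- -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  lam <- model$lambda_fn(par)
  structure(list(model_id = model$model_id, par = par, logL = logL, k = k,
                 n = n, aicc = aicc,
                 converged = isTRUE(best$convergence == 0),
                 lambda_at = lam, crown_age = tt$crown, f = model$f,
                 model = model), class = "bd_fit")
}

#' @export
print.bd_fit <- function(x, ...) {
  cat(sprintf("Birth-death fit [%s]: logL = %.3f, k = %d, n = %d, AICc = %.3f%s\n",
              x$model_id, x$logL, x$k, x$n, x$aicc,
              if (isTRUE(x$converged)) "" else "  (NOT converged)"))
  if (!is.null(x$par)) {
    cat("  parameters: ",
        paste(sprintf("%s = %.6g", names(x$par), x$par), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Compare fitted models by AICc
#'
#' Ranks fits of the same tree (same branching-time count) by AICc. The
#' best model is flagged as supported only when every rival is at least 2
#' AICc units worse.
#'
#' @param fits List of `"bd_fit"` objects fitted to the same tree.
#' @return Data frame ordered by AICc with `model`, `logL`, `k`, `n`,
#'   `aicc`, `delta_aicc`, `supported`.
#' @export
aicc_compare <- function(fits) {
  if (inherits(fits, "bd_fit")) fits <- list(fits)
  stopifnot(all(vapply(fits, inherits, logical(1L), "bd_fit")))
  ns <- vapply(fits, `[[`, numeric(1L), "n")
  if (length(unique(ns)) != 1L)
    stop("fits come from different trees (branching-time counts differ)")
  tab <- data.frame(
    model = vapply(fits, `[[`, character(1L), "model_id"),
    logL = vapply(fits, `[[`, numeric(1L), "logL"),
    k = vapply(fits, `[[`, numeric(1L), "k"),
    n = ns,
    aicc = vapply(fits, `[[`, numeric(1L), "aicc"),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$aicc), ]
  tab$delta_aicc <- tab$aicc - tab$aicc[1L]
  tab$supported <- FALSE
  if (nrow(tab) > 1L && all(tab$delta_aicc[-1L] >= 2))
    tab$supported[1L] <- TRUE
  rownames(tab) <- NULL
  tab
}
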