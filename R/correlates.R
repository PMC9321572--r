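# Per-unit genetic diversity, niche-width PCA, and rate-trait regressions.

#' Tajima's nucleotide diversity (theta-pi) for one unit
#'
#' Mean over all unordered pairs of member sequences of the per-site
#' p-distance, counted over sites where both symbols are unambiguous bases
#' (pairwise deletion). Computed on all member sequences, duplicates
#' included, so haplotype abundance weights the estimate as in the sample
#' definition of the estimator.
#'
#' @param aln Character matrix of the unit's aligned member sequences
#'   (>= 2 rows).
#' @return Theta-pi per site (scalar).
#' @export
tajima_pi <- function(aln) {
  if (!is.matrix(aln) || nrow(aln) < 2L)
    stop("theta-pi is undefined for fewer than 2 sequences")
  d <- ape::dist.dna(ape::as.DNAbin(tolower(aln)), model = "raw",
                     pairwise.deletion = TRUE)
  if (anyNA(d)) {
    warning("pairs with no comparable site are dropped from theta-pi")
    d <- d[!is.na(d)]
  }
  mean(d)
}

#' Per-unit theta-pi over an alignment partitioned into units
#'
#' Applies [tajima_pi()] to every unit with at least `min_n` member
#' sequences; smaller units are excluded (a warning lists how many).
#'
#' @param aln Character matrix of all sequences.
#' @param units Character vector: unit of each row of `aln`.
#' @param min_n Minimum member count (conventionally 10; 15 and 20 for
#'   robustness).
#' @return Data frame `unit`, `n`, `theta_pi`.
#' @export
unit_theta_pi <- function(aln, units, min_n = 10) {
  stopifnot(is.matrix(aln), length(units) == nrow(aln))
  keep <- split(seq_len(nrow(aln)), units)
  sizes <- lengths(keep)
  small <- sum(sizes < min_n)
  if (small > 0)
    warning(sprintf("%d unit(s) below min_n = %d excluded from theta-pi",
                    small, min_n))
  keep <- keep[sizes >= min_n]
  data.frame(
    unit = names(keep),
    n = lengths(keep),
    theta_pi = vapply(keep, function(i) tajima_pi(aln[i, , drop = FALSE]),
                      numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Niche-width principal component analysis
#'
#' PCA (standardised variables) of the ten per-unit niche variables, after
#' filtering units to at least `min_n` sequences. Constant variables are
#' dropped with a warning. The sign of PC1 is fixed so that it correlates
#' positively with `nb_continent` (a unit high on PC1 occupies more
#' continents, i.e. is more generalist); remaining axes are fixed so their
#' largest-magnitude loading is positive.
#'
#' @param meta A `"unit_metadata"` object from [simulate_unit_metadata()],
#'   or a data frame with a `seq_count` column and the niche variables.
#' @param min_n Minimum sequence count per unit.
#' @param vars Niche variable names (default: the standard ten).
#' @return A list of class `"niche_pca"`: `loadings`, `scores` (with `unit`
#'   ids), `var_explained`, `n_units`, `dropped_vars`.
#' @export
niche_pca <- function(meta, min_n = 10, vars = NULL) {
  df <- if (inherits(meta, "unit_metadata")) meta$units else meta
  if (is.null(vars)) {
    vars <- if (inherits(meta, "unit_metadata")) meta$niche_vars
            else c("nb_continent", "nb_realm", "nb_ecosystems", "nb_habitats",
                   "nb_biomes", "nb_climatic", "nb_plants", "plant_pd",
                   "betweenness", "closeness")
  }
  stopifnot(all(vars %in% names(df)), "seq_count" %in% names(df))
  df <- df[df$seq_count >= min_n, , drop = FALSE]
  if (nrow(df) < 3L)
    stop("fewer than 3 units pass the min_n filter")
  X <- as.matrix(df[, vars, drop = FALSE])
  sds <- apply(X, 2L, stats::sd)
  dropped <- vars[sds == 0]
  if (length(dropped)) {
    warning("dropping constant variable(s): ", paste(dropped, collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  # deterministic sign convention
  for (j in seq_len(ncol(pc$rotation))) {
    flip <- if (j == 1L && "nb_continent" %in% rownames(pc$rotation)) {
      pc$rotation["nb_continent", 1L] < 0
    } else {
      pc$rotation[which.max(abs(pc$rotation[, j])), j] < 0
    }
    if (flip) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = pc$rotation,
                 scores = data.frame(unit = df$unit, pc$x,
                                     stringsAsFactors = FALSE),
                 var_explained = ve, n_units = nrow(df),
                 dropped_vars = dropped),
            class = "niche_pca")
}

#' @export
print.niche_pca <- function(x, ...) {
  cat(sprintf("Niche PCA over %d units: PC1 %.1f%%, PC2 %.1f%% of variance\n",
              x$n_units, 100 * x$var_explained[1L],
              100 * x$var_explained[2L]))
  invisible(x)
}

#' Regress a per-unit response on a predictor
#'
#' Three modes. `"ordinary"`: least squares with a two-sided t-test on the
#' slope. `"pgls"`: generalised least squares with a Brownian-motion
#' covariance from the tree ([nlme::gls()] + [ape::corBrownian()]); on a
#' star phylogeny this reduces exactly to ordinary least squares. `"jackknife"`:
#' latitude-balanced resampling — occurrence records are grouped into 20-degree
#' latitude bands, `n_per_band` records are drawn with replacement from each
#' non-empty band, the slope is refit, and the distribution over `n_jack`
#' resamples is summarised (two-sided p from the sign balance of the
#' replicate slopes).
#'
#' @param response Named numeric vector (per unit), or for `"jackknife"` a
#'   per-record vector aligned with `latitude`.
#' @param predictor Named numeric vector (per unit); ignored in
#'   `"jackknife"` mode where latitude is the predictor.
#' @param tree Ultrametric `phylo` whose tips match the unit names
#'   (`"pgls"` only).
#' @param mode `"ordinary"`, `"pgls"` or `"jackknife"`.
#' @param latitude Per-record latitudes (`"jackknife"` only).
#' @param n_per_band Records resampled per 20-degree band (default 1000).
#' @param n_jack Number of jackknife resamples (default 100).
#' @param log_response Log-transform the response before fitting (use for
#'   positive right-skewed responses such as speciation rates).
#' @param seed Optional seed (`"jackknife"` only).
#' @return A list of class `"rate_regression"`: `slope`, `intercept`,
#'   `p_value`, `method`, `n`, and for the jackknife `slopes` (replicate
#'   values) plus quartile summaries.
#' @export
rate_correlation <- function(response, predictor = NULL, tree = NULL,
                             mode = c("ordinary", "pgls", "jackknife"),
                             latitude = NULL, n_per_band = 1000,
                             n_jack = 100, log_response = FALSE,
                             seed = NULL) {
  mode <- match.arg(mode)
  if (log_response) {
    if (any(response <= 0))
      stop("log_response = TRUE requires a strictly positive response")
    response <- log(response)
  }
  if (mode == "jackknife") {
    stopifnot(!is.null(latitude), length(latitude) == length(response))
    if (!is.null(seed)) set.seed(seed)
    band <- cut(latitude, breaks = seq(-90, 90, by = 20),
                include.lowest = TRUE, right = FALSE)
    present <- levels(band)[tabulate(band, nlevels(band)) > 0]
    if (length(present) < nlevels(band))
      warning(sprintf("%d latitude band(s) have no occurrences and are skipped",
                      nlevels(band) - length(present)))
    idx_by_band <- split(seq_along(latitude), band, drop = TRUE)
    slopes <- vapply(seq_len(n_jack), function(r) {
      take <- unlist(lapply(idx_by_band, function(i)
        sample(i, n_per_band, replace = TRUE)), use.names = FALSE)
      stats::coef(stats::lm(response[take] ~ latitude[take]))[2L]
    }, numeric(1L))
    p_lo <- mean(slopes <= 0); p_hi <- mean(slopes >= 0)
    out <- list(slope = stats::median(slopes), intercept = NA_real_,
                p_value = min(1, 2 * min(p_lo, p_hi)),
                method = "latitude-jackknife", n = length(response),
                slopes = slopes,
                q25 = unname(stats::quantile(slopes, 0.25)),
                q75 = unname(stats::quantile(slopes, 0.75)))
    return(structure(out, class = "rate_regression"))
  }

  stopifnot(!is.null(predictor))
  common <- if (!is.null(names(response)) && !is.null(names(predictor))) {
    intersect(names(response), names(predictor))
  } else {
    stopifnot(length(response) == length(predictor))
    seq_along(response)
  }
  y <- response[common]; x <- predictor[common]
  ok <- stats::complete.cases(y, x)
  y <- y[ok]; x <- x[ok]
  if (length(y) < 4L) stop("fewer than 4 complete cases")
  if (stats::sd(x) == 0) stop("singular design: predictor is constant")
  if (stats::sd(y) == 0) {
    # degenerate flat response: no association, by convention p = 1
    return(structure(list(slope = 0, intercept = mean(y), p_value = 1,
                          method = mode, n = length(y)),
                     class = "rate_regression"))
  }

  if (mode == "ordinary") {
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)$coefficients
    out <- list(slope = sm["x", "Estimate"],
                intercept = sm["(Intercept)", "Estimate"],
                p_value = sm["x", "Pr(>|t|)"],
                method = "ordinary", n = length(y))
  } else {
    stopifnot(inherits(tree, "phylo"))
    miss <- setdiff(names(y), tree$tip.label)
    if (length(miss))
      stop("units missing from the tree: ", paste(utils::head(miss, 5L),
                                                  collapse = ", "))
    tr <- ape::keep.tip(tree, names(y))
    dat <- data.frame(y = y, x = x, unit = names(y))
    fit <- nlme::gls(y ~ x, data = dat,
                     correlation = ape::corBrownian(phy = tr, form = ~unit))
    sm <- summary(fit)$tTable
    out <- list(slope = sm["x", "Value"],
                intercept = sm["(Intercept)", "Value"],
                p_value = sm["x", "p-value"],
                method = "phylogenetic-gls", n = length(y))
  }
  structure(out, class = "rate_regression")
}

#' @export
print.rate_regression <- function(x, ...) {
  cat(sprintf("%s regression (n = %d): slope = %.6g, p = %.3g\n",
              x$method, x$n, x$slope, x$p_value))
  invisible(x)
}
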