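# Per-unit metadata generator: niche-width variables driven by a latent
# generalism factor, long-tailed abundances, and per-occurrence latitudes.

#' Simulate per-unit niche and abundance metadata
#'
#' Emulates the covariate structure of occurrence databases for mycorrhizal
#' units: ten niche-width variables (numbers of continents, realms,
#' ecosystems, habitats, biomes and climatic zones occupied; number of plant
#' partners, their phylogenetic diversity; betweenness and closeness in the
#' plant-fungus network) are generated as increasing affine transforms of a
#' shared latent "generalism" factor plus independent Gaussian noise, so that
#' PC1 of the standardised table aligns with the latent factor. Abundances
#' (sequence counts) are long-tailed negative-binomial draws; each unit also
#' receives a set of occurrence latitudes whose spread widens with
#' generalism.
#'
#' @param n_units Number of units (>= 2).
#' @param latent_generalism_sd SD of the latent generalism factor.
#' @param noise_sd SD of the variable-specific noise, on the scale of the
#'   latent factor (0 gives an exactly rank-1 variable block).
#' @param abundance_shape Negative-binomial size parameter; smaller values
#'   give a longer tail of sequence counts.
#' @param mean_abundance Mean sequence count per unit.
#' @param n_lat Latitudes drawn per unit.
#' @param seed Optional integer seed.
#' @return A list of class `"unit_metadata"`: `units` (data frame with
#'   `unit`, `seq_count`, the 10 niche variables, `latent`), and
#'   `latitudes` (data frame `unit`, `latitude`, one row per occurrence).
#' @export
simulate_unit_metadata <- function(n_units, latent_generalism_sd = 1,
                                   noise_sd = 0.3, abundance_shape = 0.5,
                                   mean_abundance = 12, n_lat = 5L,
                                   seed = NULL) {
  stopifnot(n_units >= 2L, latent_generalism_sd > 0, noise_sd >= 0,
            abundance_shape > 0, mean_abundance > 0, n_lat >= 1L)
  if (!is.null(seed)) set.seed(seed)
  g <- stats::rnorm(n_units, 0, latent_generalism_sd)
  vars <- c("nb_continent", "nb_realm", "nb_ecosystems", "nb_habitats",
            "nb_biomes", "nb_climatic", "nb_plants", "plant_pd",
            "betweenness", "closeness")
  centre <- c(3, 3, 4, 6, 5, 2.5, 20, 50, 0.1, 0.4)
  slope  <- c(1, 1, 1.5, 2, 1.5, 0.8, 8, 20, 0.05, 0.1)
  X <- sapply(seq_along(vars), function(j)
    centre[j] + slope[j] * (g + stats::rnorm(n_units, 0, noise_sd)))
  colnames(X) <- vars
  seq_count <- stats::rnbinom(n_units, size = abundance_shape,
                              mu = mean_abundance)
  units <- data.frame(unit = paste0("eu", seq_len(n_units)),
                      seq_count = seq_count, X, latent = g,
                      stringsAsFactors = FALSE)
  lat_centre <- stats::runif(n_units, -60, 60)
  lat_spread <- 5 + 10 * stats::plogis(g)
  latitudes <- data.frame(
    unit = rep(units$unit, each = n_lat),
    latitude = pmin(90, pmax(-90, stats::rnorm(
      n_units * n_lat, rep(lat_centre, each = n_lat),
      rep(lat_spread, each = n_lat)))))
  structure(list(units = units, latitudes = latitudes,
                 niche_vars = vars), class = "unit_metadata")
}
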