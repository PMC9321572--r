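# Species-tree simulation: crown-conditioned birth-death with (optionally
# time-varying) speciation, simulated forward in time by thinning, pruned to
# the reconstructed tree of extant lineages.

# Simulate one stem lineage forward from the crown, returning a newick
# fragment "subtree:brlen" and the number of extant tips. `lambda_fwd(u)` is
# the speciation rate at forward time u (u = 0 at the crown, u = TT at the
# present); `lambda_max` bounds it on [0, TT]. Extinction rate `mu` is
# constant. Recursion depth equals the number of speciation events along a
# root-to-tip path, which stays small even for old trees.
.sim_stem <- function(lambda_fwd, lambda_max, mu, TT, env) {
  total <- lambda_max + mu
  frag_of <- function(u0) {
    # simulate the fate of a single lineage born at forward time u0
    u <- u0
    repeat {
      u <- u + stats::rexp(1L, total)
      if (u >= TT) {
        env$n_extant <- env$n_extant + 1L
        env$tip <- env$tip + 1L
        return(paste0("t", env$tip, ":", TT - u0))
      }
      z <- stats::runif(1L) * total
      if (z < lambda_fwd(u)) {               # speciation
        left <- frag_of(u)
        right <- frag_of(u)
        return(paste0("(", left, ",", right, "):", u - u0))
      } else if (z < lambda_fwd(u) + mu) {   # extinction
        env$dead <- env$dead + 1L
        return(paste0("x", env$dead, ":", u - u0))
      }
      # else: thinned candidate, keep waiting
    }
  }
  frag_of(0)
}

.sim_crown_tree <- function(lambda_fwd, lambda_max, mu, crown_age,
                            max_tries = 1000L) {
  env <- new.env()
  stems <- character(2L)
  for (i in 1:2) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      env$n_extant <- 0L; env$tip <- 0L; env$dead <- 0L
      frag <- .sim_stem(lambda_fwd, lambda_max, mu, crown_age, env)
      if (env$n_extant >= 1L) { ok <- TRUE; break }
    }
    if (!ok)
      stop(sprintf(
        "crown lineage went extinct in all %d attempts (retry cap reached)",
        max_tries))
    # make labels unique across the two stems
    if (i == 2L) {
      frag <- gsub("t(\\d+):", "u\\1:", frag)
      frag <- gsub("x(\\d+):", "y\\1:", frag)
    }
    stems[i] <- frag
  }
  tre <- ape::read.tree(text = paste0("(", stems[1L], ",", stems[2L], ");"))
  extinct <- grep("^[xy]", tre$tip.label, value = TRUE)
  if (length(extinct))
    tre <- ape::drop.tip(tre, extinct)
  tre$tip.label <- paste0("t", seq_len(ape::Ntip(tre)))
  tre
}

#' Simulate a crown-conditioned birth-death species tree
#'
#' Simulates a reconstructed (extant-only) ultrametric species tree with
#' crown age exactly `cfg$crown_age`, under constant speciation and
#' extinction rates. The two crown lineages are each conditioned on leaving
#' at least one extant descendant, matching the crown-survival conditioning
#' used by the likelihoods in [bd_loglik()]. Extinct lineages are pruned.
#'
#' For a pure-birth process the expected number of extant species is
#' \eqn{2 e^{rT}} (about 312 for \eqn{r = 0.010}, \eqn{T = 505}).
#'
#' @param cfg A [sim_config()] object.
#' @param seed Optional integer seed.
#' @param max_tries Retry cap per crown lineage when extinction wipes it out.
#' @return An ultrametric `phylo` tree with tips `t1, t2, ...` at age 0 and
#'   root age `cfg$crown_age`.
#' @export
simulate_species_tree <- function(cfg, seed = NULL, max_tries = 1000L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  lam <- cfg$lambda
  .sim_crown_tree(function(u) lam, lam, cfg$mu, cfg$crown_age,
                  max_tries = max_tries)
}

#' Simulate a species tree under a time-varying speciation rate
#'
#' As [simulate_species_tree()] but with the speciation rate given as a
#' function of age (Myr before present), e.g. an exponential decline toward
#' the present or a rate driven by an environmental curve. Simulation is
#' exact via thinning against the supplied bound.
#'
#' @param lambda_fn Function of age returning the speciation rate.
#' @param mu Constant extinction rate.
#' @param crown_age Crown age, Myr.
#' @param lambda_max Upper bound for `lambda_fn` over `[0, crown_age]`;
#'   computed from a fine grid when `NULL`.
#' @param seed Optional integer seed.
#' @param max_tries Retry cap per crown lineage.
#' @return An ultrametric `phylo` tree.
#' @export
simulate_rate_tree <- function(lambda_fn, mu = 0, crown_age,
                               lambda_max = NULL, seed = NULL,
                               max_tries = 1000L) {
  stopifnot(is.function(lambda_fn), crown_age > 0, mu >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(lambda_max)) {
    grid <- seq(0, crown_age, length.out = 2048L)
    lambda_max <- max(vapply(grid, lambda_fn, numeric(1L)))
  }
  # forward time u corresponds to age crown_age - u
  .sim_crown_tree(function(u) lambda_fn(crown_age - u), lambda_max, mu,
                  crown_age, max_tries = max_tries)
}

# Ages (Myr before present) of all nodes of an ultrametric tree, indexed
# 1..(Ntip+Nnode) as in the phylo edge matrix.
.node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

#' Graft within-species coalescent subtrees onto a species tree
#'
#' Replaces every species tip by a coalescent subtree of `k` sampled
#' individuals, `k` drawn uniformly from `cfg$n_ind_range`. Individuals must
#' coalesce more recently than the species' last speciation event: the
#' subtree root age is drawn uniformly on `[0, min(pendant branch length,
#' cfg$max_coal_age)]`. Subtree topologies and relative node times follow the
#' standard exchangeable coalescent ([ape::rcoal()]) rescaled so the root sits
#' at the drawn age.
#'
#' @param tree Ultrametric species tree (`phylo`).
#' @param cfg A [sim_config()] object.
#' @param seed Optional integer seed.
#' @return An ultrametric `phylo` with tips `"<species>_<i>"`; attribute
#'   `"species_map"` is a named character vector mapping each individual tip
#'   to its species.
#' @export
graft_intraspecific <- function(tree, cfg, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  if (!ape::is.ultrametric(tree, tol = 1e-6))
    stop("tree must be ultrametric")
  ntip <- ape::Ntip(tree)
  ages <- .node_ages(tree)
  parent_of <- integer(ntip + tree$Nnode)
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  elen <- numeric(ntip + tree$Nnode)
  elen[tree$edge[, 2L]] <- tree$edge.length

  kk <- sample(seq(cfg$n_ind_range[1L], cfg$n_ind_range[2L]),
               ntip, replace = TRUE)
  frags <- character(ntip)
  for (i in seq_len(ntip)) {
    pend <- elen[i]
    if (pend <= 0) {
      warning(sprintf("tip '%s' has pendant branch 0; coalescent age 0",
                      tree$tip.label[i]))
      pend <- 0
    }
    age <- stats::runif(1L, 0, min(pend, cfg$max_coal_age))
    k <- kk[i]
    labs <- paste0(tree$tip.label[i], "_", seq_len(k))
    if (k == 1L) {
      frags[i] <- labs
    } else {
      coal <- ape::rcoal(k, tip.label = labs)
      depth <- max(ape::node.depth.edgelength(coal))
      coal$edge.length <- coal$edge.length * (age / depth)
      nw <- ape::write.tree(coal)
      frags[i] <- sub(";$", "", nw)
    }
    # pendant piece above the coalescent root keeps the tree ultrametric
    frags[i] <- paste0(frags[i], ":", pend - age)
  }

  # recursive newick assembly over the species tree, tips replaced by frags
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  build <- function(node) {
    if (node <= ntip) return(frags[node])
    inner <- paste(vapply(kids[[as.character(node)]], build, character(1L)),
                   collapse = ",")
    root <- ntip + 1L
    if (node == root) paste0("(", inner, ");")
    else paste0("(", inner, "):", elen[node])
  }
  g <- ape::read.tree(text = build(ntip + 1L))
  map <- sub("_[0-9]+$", "", g$tip.label)
  names(map) <- g$tip.label
  attr(g, "species_map") <- map
  g
}
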