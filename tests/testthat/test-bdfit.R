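# Birth-death likelihoods, fitting, AICc, slicing, decline statistics.

test_that("LTT counts match hand enumeration", {
  tr <- ape::read.tree(text = "((a:5,b:5):5,(c:5,d:5):5);")
  ltt <- compute_ltt(tr)
  expect_equal(ltt$age[1], 10)
  expect_equal(ltt$n_lineages[1], 2)           # 2 lineages below the crown
  expect_equal(ltt$n_lineages[ltt$age == 0], 4)
  tr2 <- ape::read.tree(text = "(a:3,b:3);")
  ltt2 <- compute_ltt(tr2)
  expect_equal(ltt2$n_lineages, c(2, 2))
  expect_error(compute_ltt(ape::read.tree(text = "(a:1,b:2);")),
               "ultrametric")
})

test_that("the ODE likelihood equals the closed-form Yule likelihood (f=1, mu=0)", {
  m <- rate_model("constant", "none", f = 1)
  set.seed(51)
  for (tr in list(ape::rcoal(4), ape::rcoal(10))) {
    for (lam in c(0.1, 0.5, 2)) {
      ll <- bd_loglik(tr, m, c(lambda0 = lam))
      expect_equal(as.numeric(ll), oracle_yule_loglik(tr, lam),
                   tolerance = 1e-6)
      expect_equal(attr(ll, "E_crown"), 0, tolerance = 1e-10)
    }
  }
})

test_that("the environmental model with a = 0 collapses to the constant model", {
  set.seed(52)
  tr <- ape::rcoal(8)
  env <- simulate_env_curve("sinusoid", list(mean = 2, amplitude = 1,
                                             period = 0.5),
                            age_max = max(ape::branching.times(tr)) * 1.2,
                            step = 0.01)
  me <- rate_model("environmental", "none", f = 1, env = env)
  mc <- rate_model("constant", "none", f = 1)
  for (b in c(0.2, 1)) {
    expect_equal(as.numeric(bd_loglik(tr, me, c(b = b, a = 0))),
                 as.numeric(bd_loglik(tr, mc, c(lambda0 = b))),
                 tolerance = 1e-6)
  }
})

test_that("E(t) stays in [0,1] and reflects incomplete sampling at the present", {
  set.seed(53)
  tr <- ape::rcoal(12)
  m <- rate_model("constant", "constant", f = 0.6)
  ll <- bd_loglik(tr, m, c(lambda0 = 1, mu = 0.4))
  e <- attr(ll, "E_crown")
  expect_true(e > 0 && e < 1)
  # with f = 1, mu = 0, E is identically 0 (machine tolerance)
  m0 <- rate_model("constant", "none", f = 1)
  expect_lt(abs(attr(bd_loglik(tr, m0, c(lambda0 = 1)), "E_crown")), 1e-12)
})

test_that("constant-rate ML matches a grid search of the same closed form", {
  set.seed(54)
  cfg <- sim_config(crown_age = 200, lambda = 0.015)
  tr <- simulate_species_tree(cfg)
  fit <- fit_bd(tr, "constant", f = 1)[[1]]
  grid <- seq(0.001, 0.1, by = 1e-5)
  ll <- vapply(grid, function(l) oracle_yule_loglik(tr, l), numeric(1))
  expect_equal(unname(fit$par["lambda0"]), grid[which.max(ll)],
               tolerance = 1e-3)
  expect_true(fit$converged)
})

test_that("exponential speciation dominates constant in maximized likelihood", {
  set.seed(55)
  cfg <- sim_config(crown_age = 150, lambda = 0.03)
  for (i in 1:3) {
    tr <- simulate_species_tree(cfg)
    fits <- fit_bd(tr, c("constant", "exponential"), f = 1, n_starts = 5)
    expect_gte(fits[["exponential+mu0"]]$logL,
               fits[["constant+mu0"]]$logL - 1e-4)
  }
})

test_that("AICc follows the small-sample formula and support needs delta >= 2", {
  # logL = -100, k = 2, n = 50 -> AICc = 204 + 12/47
  f1 <- structure(list(model_id = "m1", logL = -100, k = 2, n = 50,
                       aicc = -2 * -100 + 2 * 2 + 2 * 2 * 3 / (50 - 2 - 1)),
                  class = "bd_fit")
  expect_equal(f1$aicc, 204 + 12 / 47)
  f2 <- structure(list(model_id = "m2", logL = -100, k = 2, n = 50,
                       aicc = f1$aicc), class = "bd_fit")
  tab <- aicc_compare(list(f1, f2))
  expect_equal(tab$delta_aicc, c(0, 0))
  expect_false(any(tab$supported))
  f3 <- structure(list(model_id = "m3", logL = -105, k = 1, n = 50,
                       aicc = 215), class = "bd_fit")
  tab2 <- aicc_compare(list(f1, f3))
  expect_true(tab2$supported[1])
  f4 <- structure(list(model_id = "m4", logL = -1, k = 1, n = 10, aicc = 4),
                  class = "bd_fit")
  expect_error(aicc_compare(list(f1, f4)), "different trees")
})

test_that("tree slicing partitions tips among subtrees crossing the slice", {
  tr <- ape::read.tree(
    text = "(((a:10,b:10):40,(c:30,d:30):20):50,((e:20,f:20):60,g:80):20);")
  # crown 100; at age 60 three lineages cross: clades {a,b,c,d} stem to 50,
  # {e,f} stem to 20, and the unbroken branch to g
  sf <- slice_tree(tr, 60, min_tips = 3)
  expect_length(sf$subtrees, 3)
  tipsets <- lapply(sf$subtrees, function(s)
    if (inherits(s, "phylo")) s$tip.label else s)
  expect_setequal(unlist(tipsets), tr$tip.label)
  expect_identical(sort(sf$n_tips), c(1L, 2L, 4L))
  expect_identical(sum(sf$retained), 1L)       # only {a,b,c,d} > 3 tips
  # slice at 0: all singletons, none retained at min_tips = 50
  sf0 <- slice_tree(tr, 0)
  expect_identical(sf0$n_tips, rep(1L, 7))
  expect_false(any(sf0$retained))
  # slice above the crown: the whole tree
  sfT <- slice_tree(tr, 150, min_tips = 3)
  expect_length(sfT$subtrees, 1)
  expect_true(sfT$retained)
})

test_that("decline statistics are zero for constant rates and track lambda differences", {
  set.seed(56)
  cfg <- sim_config(crown_age = 200, lambda = 0.02)
  tr <- simulate_species_tree(cfg)
  fit_c <- fit_bd(tr, "constant", f = 1)[[1]]
  expect_equal(unname(decline_statistic(fit_c, c(150, 100, 50))),
               c(0, 0, 0))
  # lambda(t) = 0.02 e^{alpha t} with lambda(150) = 0.03 -> stat(150) = -0.01
  fake <- structure(list(model_id = "exp", crown_age = 200,
                         lambda_at = function(t) 0.02 * exp(log(1.5) / 150 * t)),
                    class = "bd_fit")
  expect_equal(unname(decline_statistic(fake, 150)), -0.01, tolerance = 1e-12)
  expect_error(decline_statistic(fit_c, 300), "crown age")
})

test_that("fixed high extinction leaves the sign of the time trend unchanged", {
  set.seed(57)
  lamfn <- function(t) 0.02 * exp(0.012 * t)   # genuine decline toward present
  tr <- simulate_rate_tree(lamfn, mu = 0, crown_age = 120)
  fits <- fit_bd(tr, "exponential", f = 1, mu_fixed = 0.02, n_starts = 5)
  a_free <- fits[["exponential+mu0"]]$par["alpha"]
  a_fix <- fits[["exponential+mufix0.02"]]$par["alpha"]
  expect_gt(a_free, 0)
  expect_gt(a_fix, 0)
})
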