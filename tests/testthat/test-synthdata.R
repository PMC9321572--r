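# Generators: species trees, grafted coalescents, alignments, env curves,
# metadata.

test_that("simulated species trees are ultrametric with the requested crown age", {
  cfg <- sim_config(crown_age = 50, lambda = 0.05)
  for (s in 1:5) {
    tr <- simulate_species_tree(cfg, seed = s)
    expect_true(ape::is.ultrametric(tr, tol = 1e-8))
    expect_equal(max(ape::node.depth.edgelength(tr)), 50, tolerance = 1e-9)
    expect_gte(ape::Ntip(tr), 2)
  }
})

test_that("pure-birth tip counts match the closed-form expectation 2*exp(rT)", {
  # E[N] = 2 e^{rT} for a crown pure-birth process; Monte-Carlo over 200
  # replicates at a small scale (r = 0.02, T = 100 -> E[N] ~ 14.8)
  set.seed(42)
  cfg <- sim_config(crown_age = 100, lambda = 0.02)
  n <- replicate(200, ape::Ntip(simulate_species_tree(cfg)))
  expected <- 2 * exp(0.02 * 100)
  se <- stats::sd(n) / sqrt(length(n))
  expect_lt(abs(mean(n) - expected), 4 * se + 0.5)
})

test_that("birth-death simulation prunes extinct lineages and respects conditioning", {
  cfg <- sim_config_scenario("bd", r = 0.02, turnover = 0.5, crown_age = 80)
  set.seed(11)
  for (i in 1:5) {
    tr <- simulate_species_tree(cfg)
    expect_true(ape::is.ultrametric(tr, tol = 1e-8))
    ages <- max(ape::node.depth.edgelength(tr)) -
      ape::node.depth.edgelength(tr)[seq_len(ape::Ntip(tr))]
    expect_true(all(abs(ages) < 1e-8))  # all tips extant
  }
})

test_that("total extinction beyond the retry cap fails loudly", {
  # critical birth-death at high turnover: stem survival ~ 1/(1 + lambda T)
  cfg <- sim_config(crown_age = 500, lambda = 0.2, mu = 0.2)
  expect_error(simulate_species_tree(cfg, seed = 1, max_tries = 2L),
               "retry cap")
})

test_that("grafting keeps ultrametricity, species counts and tip-count bounds", {
  cfg <- sim_config(crown_age = 100, lambda = 0.03)
  tr <- simulate_species_tree(cfg, seed = 3)
  g <- graft_intraspecific(tr, cfg, seed = 4)
  expect_true(ape::is.ultrametric(g, tol = 1e-8))
  expect_equal(max(ape::node.depth.edgelength(g)), 100, tolerance = 1e-8)
  map <- attr(g, "species_map")
  expect_setequal(unique(unname(map)), tr$tip.label)
  k <- table(map)
  expect_true(all(k >= 2 & k <= 15))
  expect_identical(ape::Ntip(g), sum(k))
  # coalescent roots must be at most min(pendant, 30 Myr) old
  ages <- max(ape::node.depth.edgelength(g)) - ape::node.depth.edgelength(g)
  for (sp in tr$tip.label) {
    tips <- names(map)[map == sp]
    mrca <- if (length(tips) > 1) ape::getMRCA(g, tips) else NA
    if (!is.na(mrca)) expect_lte(ages[mrca], 30 + 1e-9)
  }
})

test_that("coalescent subtree root age never exceeds the pendant branch", {
  # species tip with a 10-Myr pendant branch: grafted subtree root <= 10 Myr
  tr <- ape::read.tree(text = "(a:10,(b:5,c:5):5);")
  cfg <- sim_config(crown_age = 10, lambda = 0.1, n_ind_range = c(2, 4))
  set.seed(9)
  for (i in 1:10) {
    g <- graft_intraspecific(tr, cfg)
    ages <- max(ape::node.depth.edgelength(g)) - ape::node.depth.edgelength(g)
    map <- attr(g, "species_map")
    a_tips <- names(map)[map == "a"]
    expect_lte(ages[ape::getMRCA(g, a_tips)], 10)
    b_tips <- names(map)[map == "b"]
    expect_lte(ages[ape::getMRCA(g, b_tips)], 5)
  }
})

test_that("alignments have the exact variable-column count and constant invariable columns", {
  cfg <- sim_config(crown_age = 100, lambda = 0.03)
  tr <- simulate_species_tree(cfg, seed = 5)
  aln <- simulate_alignment(tr, cfg, seed = 6)
  vs <- attr(aln, "variable_sites")
  expect_length(vs, floor(0.25 * 520))
  expect_identical(ncol(aln), 520L)
  inv <- setdiff(seq_len(520), vs)
  expect_true(all(apply(aln[, inv, drop = FALSE], 2,
                        function(col) length(unique(col)) == 1)))
})

test_that("zero substitution rate gives identical sequences", {
  cfg <- sim_config(crown_age = 50, lambda = 0.05, subst_rate = 0)
  tr <- simulate_species_tree(cfg, seed = 7)
  aln <- simulate_alignment(tr, cfg, seed = 8)
  expect_identical(nrow(unique(aln)), 1L)
})

test_that("pairwise divergence follows the Jukes-Cantor expectation on variable sites", {
  # two tips at path distance 2*tau: E[p] = p_var * 3/4 * (1 - exp(-4/3 s 2 tau))
  tau <- 40; s <- 0.004
  tr <- ape::read.tree(text = sprintf("(a:%g,b:%g);", tau, tau))
  cfg <- sim_config(crown_age = tau, lambda = 0.05, seq_length = 520L,
                    subst_rate = s, p_variable = 0.25)
  set.seed(10)
  p <- replicate(300, {
    aln <- simulate_alignment(tr, cfg)
    mean(aln["a", ] != aln["b", ])
  })
  expected <- 0.25 * 0.75 * (1 - exp(-4 / 3 * s * 2 * tau))
  se <- stats::sd(p) / sqrt(length(p))
  expect_lt(abs(mean(p) - expected), 4 * se + 1e-4)
})

test_that("haplotype collapsing conserves membership and is idempotent on distinct rows", {
  aln <- rbind(a = c("A", "C"), b = c("A", "C"), c = c("A", "T"),
               d = c("A", "C"), e = c("G", "C"))
  h <- collapse_haplotypes(aln)
  expect_identical(nrow(h$alignment), 3L)
  expect_setequal(h$members[["a"]], c("a", "b", "d"))
  expect_setequal(unlist(h$members), rownames(aln))
  distinct <- rbind(x = c("A", "C"), y = c("A", "T"))
  h2 <- collapse_haplotypes(distinct)
  expect_identical(nrow(h2$alignment), 2L)
  expect_identical(lengths(h2$members), c(x = 1L, y = 1L))
  expect_error(collapse_haplotypes(matrix(character(0), nrow = 0)))
})

test_that("environmental curves evaluate as specified for simple shapes", {
  cst <- simulate_env_curve("constant", list(value = 3), age_max = 100)
  f <- env_fun(cst)
  expect_equal(f(c(0, 33.3, 100)), c(3, 3, 3))
  lin <- simulate_env_curve("linear", list(from = 0, to = 1), age_max = 500)
  fl <- env_fun(lin)
  expect_equal(fl(250), 0.5, tolerance = 1e-3)
  sin_ <- simulate_env_curve("sinusoid",
                             list(mean = 1, amplitude = 2, period = 120),
                             age_max = 505)
  fs <- env_fun(sin_)
  grid <- seq(0, 505, by = 1)
  truth <- 1 + 2 * sin(2 * pi * grid / 120)
  expect_gt(stats::cor(fs(grid), truth), 0.99)
  expect_error(env_curve(c(5, 3, 1), 1:3), "increasing")
})

test_that("metadata generator has latent rank-1 structure and long-tailed abundances", {
  meta0 <- simulate_unit_metadata(60, noise_sd = 0, seed = 21)
  pc0 <- niche_pca(meta0, min_n = 0)
  expect_gt(pc0$var_explained[1], 0.999)
  meta <- simulate_unit_metadata(120, noise_sd = 0.2, seed = 22)
  pc <- niche_pca(meta, min_n = 0)
  keep <- meta$units$unit %in% pc$scores$unit
  expect_gt(abs(stats::cor(pc$scores$PC1, meta$units$latent[keep])), 0.9)
  expect_true(any(meta$units$seq_count >= 10) && any(meta$units$seq_count < 10))
  expect_true(all(abs(meta$latitudes$latitude) <= 90))
})

test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- sim_config(crown_age = 60, lambda = 0.05)
  t1 <- simulate_species_tree(cfg, seed = 99)
  t2 <- simulate_species_tree(cfg, seed = 99)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  a1 <- simulate_alignment(t1, cfg, seed = 100)
  a2 <- simulate_alignment(t2, cfg, seed = 100)
  expect_identical(a1, a2)
})
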