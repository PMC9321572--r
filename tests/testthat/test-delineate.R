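# Similarity matrix and EU delineation.

test_that("pairwise similarity counts mismatches over comparable sites only", {
  aln <- rbind(a = strsplit("ACGTACGTAC", "")[[1]],
               b = strsplit("ACGTACGTAT", "")[[1]])
  sim <- pairwise_similarity(aln)
  expect_equal(sim["a", "b"], 0.9)
  expect_equal(diag(unclass(sim)), c(a = 1, b = 1))
  # gap excluded from numerator and denominator
  g <- rbind(a = c("A", "C", "G", "-"), b = c("A", "T", "G", "T"))
  sg <- pairwise_similarity(g)
  expect_equal(sg["a", "b"], 2 / 3)
  expect_equal(attr(sg, "n_sites")["a", "b"], 3)
  # identical sequences
  eq <- rbind(a = c("A", "C"), b = c("A", "C"))
  expect_equal(pairwise_similarity(eq)["a", "b"], 1)
})

test_that("similarity equals an independent position-by-position recount", {
  set.seed(31)
  for (rep in 1:5) {
    aln <- random_alignment(6, L = 520, alphabet = c("A", "C", "G", "T", "-"))
    sim <- pairwise_similarity(aln)
    for (i in 1:5) for (j in (i + 1):6) {
      comp <- aln[i, ] %in% c("A", "C", "G", "T") &
        aln[j, ] %in% c("A", "C", "G", "T")
      expect_equal(sim[i, j],
                   1 - sum(aln[i, comp] != aln[j, comp]) / sum(comp))
    }
  }
})

test_that("pairs with no comparable site get similarity 0 with a warning", {
  aln <- rbind(a = c("A", "-"), b = c("-", "T"), c = c("A", "T"))
  expect_warning(sim <- pairwise_similarity(aln), "no comparable site")
  expect_equal(sim["a", "b"], 0)
})

test_that("delineation reproduces the worked four-tip example", {
  # tree ((A,B),(C,D)); sim(A,B)=1, sim(C,D)=0.96, cross pairs 0.90.
  # At tau = 0.97 the root fails (mean dissim ~0.073), (A,B) collapses,
  # (C,D) fails (0.04 > 0.03) and splits: 3 EUs.
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  sim <- matrix(0.90, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                            c("A", "B", "C", "D")))
  diag(sim) <- 1
  sim["A", "B"] <- sim["B", "A"] <- 1
  sim["C", "D"] <- sim["D", "C"] <- 0.96
  part <- delineate_eus(tree, sim, 0.97)
  expect_identical(canonical_partition(part$blocks),
                   list(c("A", "B"), "C", "D"))
  # all identical sequences: one EU over the whole tree for any tau < 1
  sim1 <- matrix(1, 4, 4, dimnames = dimnames(sim))
  p1 <- delineate_eus(tree, sim1, 0.999)
  expect_length(p1$blocks, 1)
})

test_that("collapse uses a strict inequality (exact ties do not collapse)", {
  tree <- ape::read.tree(text = "(A:1,B:1);")
  sim <- matrix(c(1, 0.97, 0.97, 1), 2, 2,
                dimnames = list(c("A", "B"), c("A", "B")))
  part <- delineate_eus(tree, sim, 0.97)  # dissim 0.03 == 1 - tau: no collapse
  expect_length(part$blocks, 2)
  part2 <- delineate_eus(tree, sim, 0.9699)
  expect_length(part2$blocks, 1)
})

test_that("delineation matches the brute-force clade oracle on random instances", {
  set.seed(33)
  for (rep in 1:30) {
    inst <- random_instance(sample(4:12, 1))
    tau <- sample(c(0.3, 0.5, 0.7), 1)
    got <- delineate_eus(inst$tree, inst$sim, tau)
    expect_identical(canonical_partition(got$blocks),
                     canonical_partition(oracle_delineate(inst$tree, inst$sim, tau)))
  }
})

test_that("partitions are monophyletic, disjoint and cover all tips", {
  set.seed(34)
  inst <- random_instance(12)
  part <- delineate_eus(inst$tree, inst$sim, 0.5)
  all_tips <- unlist(part$blocks)
  expect_setequal(all_tips, inst$tree$tip.label)
  expect_identical(anyDuplicated(all_tips), 0L)
  for (b in part$blocks) {
    if (length(b) > 1)
      expect_true(ape::is.monophyletic(inst$tree, b))
  }
})

test_that("higher thresholds refine lower ones and unit counts are non-decreasing", {
  set.seed(35)
  for (rep in 1:5) {
    inst <- random_instance(12)
    taus <- c(0.3, 0.5, 0.7, 0.9)
    parts <- lapply(taus, function(tau) delineate_eus(inst$tree, inst$sim, tau))
    counts <- vapply(parts, function(p) length(p$blocks), numeric(1))
    expect_true(all(diff(counts) >= 0))
    for (k in seq_len(length(taus) - 1)) {
      coarse <- parts[[k]]$membership
      fine <- parts[[k + 1]]$membership
      joined <- merge(fine, coarse, by = "tip")
      # every fine block maps into exactly one coarse block
      split_map <- tapply(joined$eu_id.y, joined$eu_id.x,
                          function(v) length(unique(v)))
      expect_true(all(split_map == 1))
    }
  }
})

test_that("the lower-triangle similarity path matches the full-matrix path exactly", {
  set.seed(37)
  for (rep in 1:10) {
    n <- sample(4:20, 1)
    aln <- random_alignment(n, L = 60, alphabet = c("A", "C", "G"))
    tree <- ape::rcoal(n, tip.label = paste0("s", sample(n)))
    sim_m <- pairwise_similarity(aln)
    sim_d <- pairwise_similarity(aln, as_dist = TRUE)
    expect_equal(unname(as.matrix(sim_d)["s1", "s2"]), sim_m["s1", "s2"])
    for (tau in c(0.2, 0.4, 0.6)) {
      pm <- delineate_eus(tree, sim_m, tau)
      pd <- delineate_eus(tree, sim_d, tau)
      expect_identical(canonical_partition(pm$blocks),
                       canonical_partition(pd$blocks))
    }
  }
})

test_that("the gap-free counting path matches the pairwise-similarity path exactly", {
  set.seed(38)
  for (rep in 1:15) {
    n <- sample(4:25, 1)
    aln <- random_alignment(n, L = 50, alphabet = c("A", "C", "G", "T"))
    # add invariable columns to exercise the constant-column shortcut
    aln <- cbind(aln, matrix("T", n, 10))
    tree <- ape::rcoal(n, tip.label = paste0("s", sample(n)))
    sim <- pairwise_similarity(aln)
    for (tau in c(0.3, 0.5, 0.7)) {
      pm <- delineate_eus(tree, sim, tau)
      pa <- delineate_eus_aln(tree, aln, tau)
      expect_identical(canonical_partition(pm$blocks),
                       canonical_partition(pa$blocks))
    }
  }
  gap <- rbind(a = c("A", "-"), b = c("A", "T"))
  tr2 <- ape::read.tree(text = "(a:1,b:1);")
  expect_error(delineate_eus_aln(tr2, gap, 0.9), "gaps or ambiguity")
})

test_that("re-delineating the representative tree never errors or splits further", {
  set.seed(36)
  inst <- random_instance(12)
  part <- delineate_eus(inst$tree, inst$sim, 0.6)
  reps <- unname(part$representative)
  if (length(reps) >= 2) {
    rep_tree <- ape::keep.tip(inst$tree, reps)
    part2 <- delineate_eus(rep_tree, inst$sim, 0.6)
    expect_lte(length(part2$blocks), length(part$blocks))
  } else {
    succeed()
  }
})

test_that("missing tips in the similarity matrix are reported by name", {
  tree <- ape::read.tree(text = "(A:1,B:1);")
  sim <- matrix(1, 1, 1, dimnames = list("A", "A"))
  expect_error(delineate_eus(tree, sim, 0.9), "B")
})

test_that("partition summary picks the most sequence-rich representative", {
  tree <- ape::read.tree(text = "((h1:1,h2:1):1,h3:2);")
  sim <- matrix(1, 3, 3, dimnames = list(c("h1", "h2", "h3"),
                                         c("h1", "h2", "h3")))
  sim["h3", c("h1", "h2")] <- sim[c("h1", "h2"), "h3"] <- 0.5
  part <- delineate_eus(tree, sim, 0.9)
  members <- list(h1 = paste0("a", 1:5), h2 = paste0("b", 1:2), h3 = "c1")
  summ <- partition_summary(part, members)
  eu12 <- summ[summ$n_haplotypes == 2, ]
  expect_identical(eu12$representative, "h1")
  expect_identical(eu12$n_sequences, 7L)
  eu3 <- summ[summ$n_haplotypes == 1, ]
  expect_identical(eu3$representative, "h3")
  expect_identical(unname(attr(summ, "totals")["n_sequences"]), 8L)
})
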