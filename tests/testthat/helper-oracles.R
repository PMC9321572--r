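# Independent oracles and fixture builders used across the suite. These are
# deliberately naive (explicit loops, closed forms) and share no code with
# the package internals they check.

# Mean pairwise dissimilarity among a set of tip names, by explicit double
# loop over a similarity matrix.
oracle_mean_dissim <- function(tips, sim) {
  if (length(tips) < 2) return(0)
  s <- 0; np <- 0
  for (i in seq_len(length(tips) - 1)) {
    for (j in seq(i + 1, length(tips))) {
      s <- s + (1 - sim[tips[i], tips[j]])
      np <- np + 1
    }
  }
  s / np
}

# Brute-force unit delineation: test every clade from the root toward the
# tips; collapse a clade as soon as its mean pairwise dissimilarity is
# strictly below 1 - tau. Returns a list of tip-name vectors.
oracle_delineate <- function(tree, sim, tau) {
  ntip <- ape::Ntip(tree)
  children <- function(node) tree$edge[tree$edge[, 1] == node, 2]
  clade_tips <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(children(node), clade_tips))
  }
  out <- list()
  recurse <- function(node) {
    tips <- clade_tips(node)
    if (length(tips) == 1 || oracle_mean_dissim(tips, sim) < 1 - tau) {
      out[[length(out) + 1]] <<- sort(tips)
    } else {
      for (ch in children(node)) recurse(ch)
    }
  }
  recurse(ntip + 1)
  out
}

# Canonical form of a partition for comparison: sorted blocks of sorted tips.
canonical_partition <- function(blocks) {
  blocks <- lapply(unname(blocks), function(b) sort(unname(b)))
  blocks[order(vapply(blocks, `[`, character(1), 1))]
}

# Closed-form Yule log-likelihood (f = 1, mu = 0, crown-conditioned):
# one log(lambda) per branching plus -lambda * (total branch length).
oracle_yule_loglik <- function(tree, lambda) {
  (ape::Ntip(tree) - 1) * log(lambda) - lambda * sum(tree$edge.length)
}

# Exact expected rarefied richness for a subsample of k accessions without
# replacement (hypergeometric form).
oracle_rarefied_richness <- function(unit_counts, k) {
  n <- sum(unit_counts)
  sum(1 - choose(n - unit_counts, k) / choose(n, k))
}

# Random aligned sequences over a reduced alphabet so pairwise similarities
# spread over a useful range.
random_alignment <- function(n, L = 40, alphabet = c("A", "C")) {
  m <- matrix(sample(alphabet, n * L, replace = TRUE), nrow = n,
              dimnames = list(paste0("s", seq_len(n)), NULL))
  m
}

# Random tree + alignment instance for delineation oracle tests.
random_instance <- function(n) {
  tree <- ape::rcoal(n, tip.label = paste0("s", sample(n)))
  aln <- random_alignment(n)
  list(tree = tree, aln = aln, sim = pairwise_similarity(aln))
}
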