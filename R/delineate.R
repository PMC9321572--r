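# Evolutionary-unit (EU) delineation: monophyly + average pairwise
# similarity threshold, by root-to-tip traversal of a haplotype tree.

#' Pairwise similarity matrix of an alignment
#'
#' Similarity between two aligned sequences is `1 - mismatches /
#' compared_sites`, counted over columns where both symbols are unambiguous
#' bases (`A/C/G/T`); gaps and ambiguity codes are excluded from both the
#' numerator and the denominator. Distances are computed with
#' [ape::dist.dna()] (`model = "raw"`, pairwise deletion). Pairs with no
#' comparable site get similarity 0 with a warning.
#'
#' @param aln Character matrix alignment with named rows of equal length.
#' @param with_counts Attach the per-pair count of compared sites as
#'   attribute `"n_sites"` (an `n x n` matrix; disable for very large
#'   alignments to halve memory).
#' @param as_dist Return the lower-triangle [stats::dist] form instead of
#'   the full matrix (roughly a quarter of the resident memory; accepted
#'   directly by [delineate_eus()], recommended beyond a few thousand
#'   sequences). Implies `with_counts = FALSE`.
#' @return A symmetric numeric matrix of class `"similarity_matrix"` with
#'   unit diagonal (attribute `"n_sites"` holds the per-pair count of
#'   compared sites when `with_counts = TRUE`), or, with `as_dist = TRUE`,
#'   a `"similarity_dist"`/`"dist"` object of pairwise similarities.
#' @export
pairwise_similarity <- function(aln, with_counts = TRUE, as_dist = FALSE) {
  if (!is.matrix(aln) || nrow(aln) < 2L)
    stop("alignment must be a matrix with at least 2 sequences")
  if (is.null(rownames(aln))) stop("alignment rows must be named")
  dna <- ape::as.DNAbin(tolower(aln))
  d <- ape::dist.dna(dna, model = "raw", pairwise.deletion = TRUE)
  if (as_dist) {
    sim <- 1 - d
    if (anyNA(sim)) {
      warning("some pairs share no comparable site; their similarity is set to 0")
      sim[is.na(sim)] <- 0
    }
    class(sim) <- c("similarity_dist", "dist")
    return(sim)
  }
  sim <- 1 - as.matrix(d)
  diag(sim) <- 1
  if (anyNA(sim)) {
    warning("some pairs share no comparable site; their similarity is set to 0")
    sim[is.na(sim)] <- 0
  }
  if (with_counts) {
    ok <- matrix(toupper(aln) %in% c("A", "C", "G", "T"),
                 nrow = nrow(aln))
    n_sites <- tcrossprod(ok * 1L)
    dimnames(n_sites) <- dimnames(sim)
    attr(sim, "n_sites") <- n_sites
  }
  class(sim) <- c("similarity_matrix", class(sim))
  sim
}

# Cross-pair dissimilarity sum providers. Both return function(A, B) =
# sum over a in A, b in B of (1 - similarity(a, b)), with A and B given as
# integer indices into the tip ordering used by the similarity input.

# full-matrix provider: dmat is a dissimilarity matrix
.pairsum_matrix <- function(dmat) {
  function(A, B) sum(dmat[A, B])
}

# lower-triangle provider: svec is a dist object of similarities over n
# items; pair (i < j) sits at position n(i-1) - i(i-1)/2 + (j - i).
# Cross-products are chunked so transient index vectors stay bounded.
.pairsum_dist <- function(svec, n, chunk = 4e6) {
  function(A, B) {
    la <- length(A); lb <- length(B)
    s <- 0
    step <- max(1L, floor(chunk / lb))
    for (a0 in seq(1L, la, by = step)) {
      Aa <- A[a0:min(la, a0 + step - 1L)]
      I <- rep(Aa, each = lb)
      J <- rep(B, times = length(Aa))
      ii <- pmin(I, J); jj <- pmax(I, J)
      pos <- n * (ii - 1) - ii * (ii - 1) / 2 + (jj - ii)
      s <- s + sum(svec[pos])
    }
    la * lb - s        # sum of (1 - similarity)
  }
}

# Per-node mean pairwise dissimilarity among descendant tips, computed in a
# single post-order pass: the pair-sum at a node is the sum of the
# children's pair-sums plus the cross-sums between child tip sets, so the
# total work equals the number of tip pairs once.
.node_mean_dissim <- function(tree, pairsum) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  tips <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) tips[[i]] <- i
  psum <- numeric(ntip + nnode)
  po <- ape::reorder.phylo(tree, "postorder")
  kids <- split(po$edge[, 2L], po$edge[, 1L])
  for (node in unique(po$edge[, 1L])) {     # postorder: children first
    ch <- kids[[as.character(node)]]
    s <- sum(psum[ch])
    tset <- tips[ch]
    if (length(ch) > 1L) {
      for (a in seq_len(length(ch) - 1L))
        for (b in seq(a + 1L, length(ch)))
          s <- s + pairsum(tset[[a]], tset[[b]])
    }
    psum[node] <- s
    tips[[node]] <- unlist(tset, use.names = FALSE)
  }
  npairs <- vapply(tips, function(t) length(t) * (length(t) - 1) / 2,
                   numeric(1L))
  meand <- ifelse(npairs > 0, psum / npairs, 0)
  list(mean_dissim = meand, tips = tips)
}

# Shared root-to-tip collapse walk over precomputed per-node mean
# dissimilarities. nd holds mean_dissim (indexed like the edge matrix) and
# tips (tip-index sets per node).
.walk_partition <- function(tree, nd, tau) {
  labs <- tree$tip.label
  ntip <- ape::Ntip(tree)
  thr <- 1 - tau
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  blocks <- list()
  mrca <- integer(0)
  walk <- function(node) {
    if (node <= ntip || nd$mean_dissim[node] < thr) {
      blocks[[length(blocks) + 1L]] <<- labs[nd$tips[[node]]]
      mrca[length(mrca) + 1L] <<- node
    } else {
      for (ch in kids[[as.character(node)]]) walk(ch)
    }
  }
  walk(if (ntip == 1L) 1L else ntip + 1L)
  names(blocks) <- sprintf("EU%04d", seq_along(blocks))
  representative <- vapply(blocks, function(b) sort(b)[1L], character(1L))
  membership <- data.frame(
    tip = unlist(blocks, use.names = FALSE),
    eu_id = rep(names(blocks), lengths(blocks)),
    representative = rep(representative, lengths(blocks)),
    stringsAsFactors = FALSE)
  structure(list(tau = tau, blocks = blocks, mrca = mrca,
                 representative = representative, membership = membership),
            class = "eu_partition")
}

#' Delineate evolutionary units on a tree
#'
#' Traverses the tree from the root toward the tips; at every node it
#' computes the mean pairwise dissimilarity (`1 - similarity`) over all
#' unordered pairs of tips descending from the node, and collapses the whole
#' clade into a single evolutionary unit (EU) when that mean is strictly
#' below `1 - tau`. Clades that fail the test are descended further; a tip
#' reached without collapse becomes a singleton EU. Every EU is therefore
#' monophyletic, and its members are on average more similar than the
#' threshold `tau`.
#'
#' @param tree Rooted `phylo` tree of the sequences (typically a haplotype
#'   tree).
#' @param sim Similarity matrix from [pairwise_similarity()] (or any named
#'   symmetric matrix of similarities in `[0, 1]`), or the lower-triangle
#'   `"similarity_dist"` form from `pairwise_similarity(..., as_dist =
#'   TRUE)`; must cover all tips.
#' @param tau Similarity threshold in (0, 1), e.g. `0.99` for "EU99".
#' @return An object of class `"eu_partition"`: list with `tau`, `blocks`
#'   (named list, EU id -> tip names), `mrca` (node number per EU),
#'   `representative` (lexicographically smallest tip per EU), and
#'   `membership` (data frame `tip`, `eu_id`, `representative`).
#' @export
delineate_eus <- function(tree, sim, tau) {
  stopifnot(inherits(tree, "phylo"))
  if (!(is.numeric(tau) && length(tau) == 1L && tau > 0 && tau < 1))
    stop("tau must be a single number in (0, 1)")
  labs <- tree$tip.label
  sim_names <- if (inherits(sim, "dist")) attr(sim, "Labels") else rownames(sim)
  missing <- setdiff(labs, sim_names)
  if (length(missing))
    stop("tips missing from the similarity matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ...")
  if (inherits(sim, "dist")) {
    # tips indexed into the dist ordering; no n x n expansion
    idx <- match(labs, sim_names)
    pairsum <- local({
      ps <- .pairsum_dist(unclass(sim), attr(sim, "Size"))
      function(A, B) ps(idx[A], idx[B])
    })
  } else {
    dmat <- 1 - unclass(sim)[labs, labs, drop = FALSE]
    pairsum <- .pairsum_matrix(dmat)
  }
  ntip <- ape::Ntip(tree)
  nd <- if (ntip == 1L) list(mean_dissim = 0, tips = list(1L))
        else .node_mean_dissim(tree, pairsum)
  .walk_partition(tree, nd, tau)
}

#' Delineate evolutionary units from a gap-free alignment
#'
#' Equivalent to [pairwise_similarity()] + [delineate_eus()] for alignments
#' whose symbols are all unambiguous bases (`A/C/G/T`, no gaps), but
#' without materialising any pairwise matrix: the sum of pairwise
#' mismatches under a node is computed from per-column base counts
#' accumulated in one post-order pass, so memory and time are linear in
#' alignment size. This is the path of choice for very large simulated
#' haplotype sets (the simulation workbench uses it); it returns exactly
#' the same partition as the pairwise route.
#'
#' @param tree Rooted `phylo` tree whose tips are alignment rows.
#' @param aln Character matrix alignment (named rows, symbols `A/C/G/T`).
#' @param tau Similarity threshold in (0, 1).
#' @return An `"eu_partition"`, as for [delineate_eus()].
#' @export
delineate_eus_aln <- function(tree, aln, tau) {
  stopifnot(inherits(tree, "phylo"), is.matrix(aln))
  if (!(is.numeric(tau) && length(tau) == 1L && tau > 0 && tau < 1))
    stop("tau must be a single number in (0, 1)")
  labs <- tree$tip.label
  missing <- setdiff(labs, rownames(aln))
  if (length(missing))
    stop("tips missing from the alignment: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ...")
  ntip <- ape::Ntip(tree)
  if (ntip == 1L)
    return(.walk_partition(tree, list(mean_dissim = 0, tips = list(1L)), tau))
  aln <- toupper(aln[labs, , drop = FALSE])
  L <- ncol(aln)
  code <- match(aln, c("A", "C", "G", "T"))
  if (anyNA(code))
    stop("alignment contains gaps or ambiguity codes; use ",
         "pairwise_similarity() + delineate_eus() for such data")
  dim(code) <- dim(aln)
  # only columns that vary can contribute mismatches
  vc <- which(apply(code, 2L, function(col) any(col != col[1L])))
  Lv <- length(vc)
  code <- code[, vc, drop = FALSE]

  nnode <- tree$Nnode
  tips <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) tips[[i]] <- i
  # per-node base counts over variable columns, stacked as 4*Lv integers;
  # kept for internal nodes only (tips are one-hot from `code`)
  counts <- matrix(0L, nrow = nnode, ncol = max(1L, 4L * Lv))
  onehot <- function(tip) {
    v <- integer(4L * Lv)
    if (Lv) v[(seq_len(Lv) - 1L) * 4L + code[tip, ]] <- 1L
    v
  }
  mean_dissim <- numeric(ntip + nnode)
  po <- ape::reorder.phylo(tree, "postorder")
  kids <- split(po$edge[, 2L], po$edge[, 1L])
  for (node in unique(po$edge[, 1L])) {
    ch <- kids[[as.character(node)]]
    cnt <- integer(max(1L, 4L * Lv))
    tset <- tips[ch]
    for (c_ in ch) {
      cnt <- cnt + if (c_ <= ntip) onehot(c_) else counts[c_ - ntip, ]
    }
    counts[node - ntip, ] <- cnt
    tips[[node]] <- unlist(tset, use.names = FALSE)
    nv <- length(tips[[node]])
    npairs <- nv * (nv - 1) / 2
    # mismatching pairs per column = C(nv,2) - sum_b C(count_b,2)
    same <- sum(as.numeric(cnt) * (as.numeric(cnt) - 1)) / 2
    mism <- Lv * npairs - same
    mean_dissim[node] <- mism / (npairs * L)
  }
  .walk_partition(tree, list(mean_dissim = mean_dissim, tips = tips), tau)
}

#' @export
print.eu_partition <- function(x, ...) {
  cat(sprintf("EU partition at tau = %g: %d units over %d tips\n",
              x$tau, length(x$blocks), nrow(x$membership)))
  invisible(x)
}

#' Summarise an EU partition
#'
#' Per-unit haplotype and sequence counts. When a haplotype membership map
#' (from [collapse_haplotypes()]) is supplied, the sequence count of a unit
#' is the total number of underlying sequences and the representative is the
#' most sequence-rich haplotype (ties broken by the lexicographically
#' smallest name); otherwise each tip counts once.
#'
#' @param partition An `"eu_partition"`.
#' @param members Optional named list mapping haplotype name -> member
#'   sequence names.
#' @return A data frame with one row per EU (`eu_id`, `n_haplotypes`,
#'   `n_sequences`, `representative`); attribute `"totals"` holds global
#'   counts.
#' @export
partition_summary <- function(partition, members = NULL) {
  stopifnot(inherits(partition, "eu_partition"))
  counts <- function(tips) {
    if (is.null(members)) rep(1L, length(tips))
    else lengths(members[tips])
  }
  rows <- lapply(names(partition$blocks), function(id) {
    tips <- partition$blocks[[id]]
    nseq <- counts(tips)
    best <- tips[order(-nseq, tips)][1L]
    data.frame(eu_id = id, n_haplotypes = length(tips),
               n_sequences = sum(nseq), representative = best,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "totals") <- c(n_units = nrow(out),
                           n_haplotypes = sum(out$n_haplotypes),
                           n_sequences = sum(out$n_sequences))
  out
}
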