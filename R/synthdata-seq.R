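# Slow-marker sequence evolution and haplotype collapsing.

#' Simulate a short alignment on a tree
#'
#' Evolves a `cfg$seq_length`-bp alignment along `tree` (branch lengths in
#' Myr). Exactly `floor(p_variable * seq_length)` columns, chosen uniformly
#' at random once per replicate, are variable and evolve under Jukes-Cantor
#' at `cfg$subst_rate` substitutions/site/Myr (via [phangorn::simSeq()]);
#' the remaining columns are constant across all sequences. With the
#' defaults this mimics a 520-bp SSU-like barcode with 130 variable sites
#' evolving at 0.001 substitutions/site/Myr.
#'
#' @param tree A `phylo` tree with branch lengths in Myr.
#' @param cfg A [sim_config()] object.
#' @param seed Optional integer seed.
#' @return A character matrix (rows = tips, columns = sites, symbols
#'   `A/C/G/T`) with attribute `"variable_sites"` giving the variable column
#'   indices.
#' @export
simulate_alignment <- function(tree, cfg, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(cfg, "sim_config"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (!is.null(seed)) set.seed(seed)
  L <- cfg$seq_length
  nvar <- floor(cfg$p_variable * L)
  var_cols <- sort(sample.int(L, nvar))
  ntip <- ape::Ntip(tree)
  bases <- c("A", "C", "G", "T")

  aln <- matrix(rep(sample(bases, L, replace = TRUE), each = ntip),
                nrow = ntip, dimnames = list(tree$tip.label, NULL))
  if (nvar > 0L && cfg$subst_rate > 0) {
    sim <- phangorn::simSeq(tree, l = nvar, rate = cfg$subst_rate)
    m <- toupper(as.character(sim))
    aln[, var_cols] <- m[rownames(aln), , drop = FALSE]
  }
  attr(aln, "variable_sites") <- var_cols
  aln
}

#' Collapse identical sequences into haplotypes
#'
#' Keeps one representative row per distinct sequence and records which
#' input sequences each haplotype stands for. The representative is the
#' first member in input order; its name labels the haplotype.
#'
#' @param aln Character matrix alignment (rows = sequences).
#' @return A list with `alignment` (one row per haplotype) and `members`
#'   (named list: haplotype representative -> character vector of all member
#'   names, representative included).
#' @export
collapse_haplotypes <- function(aln) {
  if (!is.matrix(aln) || nrow(aln) == 0L)
    stop("alignment must be a non-empty matrix")
  if (is.null(rownames(aln))) stop("alignment rows must be named")
  key <- apply(aln, 1L, paste, collapse = "")
  groups <- split(rownames(aln), factor(key, levels = unique(key)))
  reps <- vapply(groups, `[`, character(1L), 1L)
  names(groups) <- reps
  list(alignment = aln[reps, , drop = FALSE], members = groups)
}
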