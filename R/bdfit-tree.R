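# Tree slicing and decline statistics.

#' Slice an ultrametric tree at a given age
#'
#' Returns one subtree per lineage crossing the slice age. Each subtree is
#' the crown clade descending from the lineage's first node younger than the
#' slice; the stem piece between the slice age and that node is reported as
#' `stem_length` and discarded from the subtree. Lineages that reach the
#' present without further splitting become singleton subtrees. Subtrees
#' with more than `min_tips` tips are flagged `retained` (the convention for
#' restricting diversification fits to informative slices). A slice at or
#' above the crown age returns the whole tree as a single subtree.
#'
#' @param tree Ultrametric `phylo` tree.
#' @param slice_age Age of the slice, Myr (>= 0).
#' @param min_tips Retention threshold: retained iff tip count > `min_tips`.
#' @return A list of class `"sliced_forest"`: `slice_age`, `subtrees` (list;
#'   `phylo` objects or single tip labels), `n_tips`, `stem_length`,
#'   `retained`.
#' @export
slice_tree <- function(tree, slice_age, min_tips = 50) {
  stopifnot(inherits(tree, "phylo"), slice_age >= 0)
  tt <- .tree_times(tree)
  if (slice_age >= tt$crown) {
    out <- list(slice_age = slice_age, subtrees = list(tree),
                n_tips = tt$ntip, stem_length = slice_age - tt$crown,
                retained = tt$ntip > min_tips)
    class(out) <- "sliced_forest"
    return(out)
  }
  ages <- .node_ages(tree)
  ntip <- ape::Ntip(tree)
  ages[seq_len(ntip)] <- 0
  # crossing edges: parent strictly older than the slice, child at or below
  cross <- which(ages[tree$edge[, 1L]] > slice_age &
                 ages[tree$edge[, 2L]] <= slice_age)
  sub <- vector("list", length(cross))
  n_tips <- integer(length(cross))
  stem <- numeric(length(cross))
  for (i in seq_along(cross)) {
    child <- tree$edge[cross[i], 2L]
    stem[i] <- slice_age - ages[child]
    if (child <= ntip) {
      sub[[i]] <- tree$tip.label[child]
      n_tips[i] <- 1L
    } else {
      sub[[i]] <- ape::extract.clade(tree, child)
      n_tips[i] <- ape::Ntip(sub[[i]])
    }
  }
  structure(list(slice_age = slice_age, subtrees = sub, n_tips = n_tips,
                 stem_length = stem, retained = n_tips > min_tips),
            class = "sliced_forest")
}

#' @export
print.sliced_forest <- function(x, ...) {
  cat(sprintf("Slice at %g Myr: %d subtrees (%d retained), tip counts %s\n",
              x$slice_age, length(x$subtrees), sum(x$retained),
              paste(utils::head(sort(x$n_tips, decreasing = TRUE), 10L),
                    collapse = ", ")))
  invisible(x)
}

#' Speciation-rate decline statistic
#'
#' Difference between the fitted speciation rate at present and at each
#' reference age, \eqn{\hat\lambda(0) - \hat\lambda(t_{ref})}. Negative
#' values indicate a decline in speciation rate toward the present.
#'
#' @param fit A `"bd_fit"` with an evaluable rate function.
#' @param reference_ages Ages, Myr (each must not exceed the crown age).
#' @return Named numeric vector, one statistic per reference age.
#' @export
decline_statistic <- function(fit, reference_ages = c(150, 100, 50)) {
  stopifnot(inherits(fit, "bd_fit"))
  if (is.null(fit$lambda_at)) stop("fit has no rate function (not converged?)")
  if (any(reference_ages > fit$crown_age))
    stop("reference age beyond the crown age of the fitted tree")
  out <- fit$lambda_at(0) - vapply(reference_ages, fit$lambda_at, numeric(1L))
  names(out) <- paste0("d", reference_ages)
  out
}
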