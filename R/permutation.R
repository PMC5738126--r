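#' Uniformly permute gender labels across nodes
#'
#' Draws a uniform random permutation of the label multiset over the same
#' nodes: female and male counts are conserved exactly, only the assignment
#' to nodes changes. This is the reference model for all homophily tests —
#' network topology is held fixed, labels are shuffled.
#'
#' @param labels character vector (optionally named) of `"F"`/`"M"` labels.
#' @param seed optional integer seed.
#' @return Permuted label vector with the same names.
#' @export
permute_genders <- function(labels, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- sample(labels)
  names(out) <- names(labels)
  out
}

#' z-score of an observed indicator against a permutation null
#'
#' \eqn{z = (x - \mu(\tilde{x})) / \sigma(\tilde{x})} with the n-1 sample
#' standard deviation of the null values. Expected to be zero when the
#' indicator is independent of the labels. A degenerate (constant) null is
#' flagged by returning signed infinity (0 when the observed value equals
#' the constant) rather than raising an error.
#'
#' @param observed observed indicator value.
#' @param null_values numeric vector (length >= 2) of the indicator over
#'   permuted-label realizations.
#' @return z-score.
#' @export
z_score <- function(observed, null_values) {
  if (length(null_values) < 2)
    stop("z_score needs at least 2 null values")
  mu <- mean(null_values)
  s <- stats::sd(null_values)
  if (s == 0) {
    if (observed == mu) return(0)
    return(sign(observed - mu) * Inf)
  }
  (observed - mu) / s
}

#' One-sided permutation p-value
#'
#' The number of null values strictly beyond the observed value in the
#' chosen tail, divided by the null sample size, so p = 0 is representable.
#' An optional add-one corrected mode ((k+1)/(n+1)) is available for users
#' who prefer never-zero p-values.
#'
#' @param observed observed indicator value.
#' @param null_values numeric vector of null realizations.
#' @param tail `"greater"` (null values larger than observed) or `"less"`.
#' @param correction apply the (k+1)/(n+1) correction (default `FALSE`).
#' @return p-value in `[0, 1]`.
#' @export
permutation_pvalue <- function(observed, null_values,
                               tail = c("greater", "less"),
                               correction = FALSE) {
  tail <- match.arg(tail)
  if (length(null_values) == 0) stop("empty null sample")
  k <- if (tail == "greater") sum(null_values > observed)
       else sum(null_values < observed)
  if (correction) (k + 1) / (length(null_values) + 1)
  else k / length(null_values)
}

# Vectorized homophily indicators for one label assignment.
# el: 2 x E integer endpoint matrix; tri: 3 x T triangle vertex matrix;
# deg: per-node degree; returns the full indicator vector.
homophily_indicators <- function(labels, el, tri, deg) {
  nf <- labels == "F"
  same <- nf[el[1, ]] == nf[el[2, ]]
  ff <- same & nf[el[1, ]]
  mm <- same & !nf[el[1, ]]
  nv <- length(labels)
  same_cnt <- tabulate(c(el[1, same], el[2, same]), nbins = nv)
  frac <- ifelse(deg > 0, same_cnt / deg, NA_real_)
  sgf_F <- mean(frac[nf], na.rm = TRUE)
  sgf_M <- mean(frac[!nf], na.rm = TRUE)
  tr <- c(FFF = 0, MMM = 0, mixed = 0)
  if (ncol(tri) > 0) {
    nfem <- colSums(matrix(nf[tri], nrow = 3))
    tr <- c(FFF = sum(nfem == 3), MMM = sum(nfem == 0),
            mixed = sum(nfem %in% c(1, 2)))
  }
  c(sgf_F = sgf_F, sgf_M = sgf_M,
    dyad_FF = sum(ff), dyad_MM = sum(mm), dyad_FM = sum(!same),
    triad_FFF = unname(tr["FFF"]), triad_MMM = unname(tr["MMM"]),
    triad_mixed = unname(tr["mixed"]))
}

#' Gender-homophily permutation test on a labeled network
#'
#' Holds the network topology fixed, permutes the gender labels `n_perm`
#' times (default `2E`, twice the edge count), recomputes each homophily
#' indicator per realization, and reports the observed value, the null
#' distribution, the z-score and one-sided permutation p-values.
#'
#' Indicators: mean same-gender neighbour fraction among female (`sgf_F`)
#' and male (`sgf_M`) nodes; dyad motif counts (`dyad_FF`, `dyad_MM`,
#' `dyad_FM`); closed-triangle motif counts (`triad_FFF`, `triad_MMM`,
#' `triad_mixed`).
#'
#' @param graph undirected igraph graph with vertex attribute `gender`.
#' @param n_perm number of permuted realizations; `NULL` means `2E`.
#' @param seed optional integer seed.
#' @return Object of class `permutation_ensemble_set`: list with `observed`
#'   (named vector), `null_values` (n_perm x indicator matrix), `z`,
#'   `p_greater`, `p_less` (named vectors), `n_perm`, `n_edges`.
#' @export
homophily_test <- function(graph, n_perm = NULL, seed = NULL) {
  E <- igraph::ecount(graph)
  if (E < 1) stop("homophily_test requires at least one edge")
  labels <- igraph::V(graph)$gender
  if (anyNA(labels)) stop("all nodes must carry a gender label")
  if (length(unique(labels)) < 2)
    warning("single-gender cohort: homophily indicators are degenerate")
  if (is.null(n_perm)) n_perm <- 2L * E
  if (!is.null(seed)) set.seed(seed)
  el <- t(igraph::as_edgelist(graph, names = FALSE))
  tri <- matrix(as.integer(igraph::triangles(graph)), nrow = 3)
  deg <- igraph::degree(graph)
  observed <- homophily_indicators(labels, el, tri, deg)
  null_values <- t(vapply(seq_len(n_perm), function(i)
    homophily_indicators(sample(labels), el, tri, deg),
    numeric(length(observed))))
  z <- vapply(names(observed), function(nm)
    z_score(observed[[nm]], null_values[, nm]), numeric(1))
  p_g <- vapply(names(observed), function(nm)
    permutation_pvalue(observed[[nm]], null_values[, nm], "greater"),
    numeric(1))
  p_l <- vapply(names(observed), function(nm)
    permutation_pvalue(observed[[nm]], null_values[, nm], "less"),
    numeric(1))
  structure(list(observed = observed, null_values = null_values, z = z,
                 p_greater = p_g, p_less = p_l, n_perm = n_perm,
                 n_edges = E),
            class = "permutation_ensemble_set")
}

#' @export
print.permutation_ensemble_set <- function(x, ...) {
  cat(sprintf("<homophily permutation test> %d permutations, %d edges\n",
              x$n_perm, x$n_edges))
  df <- data.frame(observed = x$observed, z = x$z,
                   p_greater = x$p_greater, p_less = x$p_less)
  print(round(df, 4))
  invisible(x)
}
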