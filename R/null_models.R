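#' Rewired null connectome preserving degree, weights, and strengths
#'
#' Generates one surrogate connectome by degree-preserving double-edge
#' swaps (Maslov-Sneppen rewiring) of the binary topology, followed by
#' rank-matched reassignment of the original weights: surrogate edges are
#' ranked by the product of their endpoints' original strengths and the
#' sorted weight multiset is assigned in matching order. The binary degree
#' sequence and the weight multiset are preserved exactly; nodal strengths
#' are preserved approximately.
#'
#' @param connectome a [node_connectome()].
#' @param swaps_per_edge rewiring budget: number of attempted swaps per
#'   edge (default 10).
#' @param seed optional integer seed for reproducibility.
#' @return A new [node_connectome()] with the same node labels.
#' @export
rewire_null <- function(connectome, swaps_per_edge = 10, seed = NULL) {
  stopifnot_connectome(connectome)
  if (!is.null(seed)) set.seed(seed)
  el <- build_edge_list(connectome)
  n <- connectome$n_nodes
  L <- nrow(el)
  if (L < 2) {
    warning("fewer than 2 edges: returning a weight-reshuffled copy")
    new_el <- el
    new_el$w <- sample(el$w)
  } else {
    g <- igraph::graph_from_edgelist(as.matrix(el[, c("i", "j")]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = swaps_per_edge * L))
    em <- igraph::as_edgelist(gr, names = FALSE)
    ii <- pmin(em[, 1], em[, 2])
    jj <- pmax(em[, 1], em[, 2])
    ord <- order(ii, jj)
    new_el <- data.frame(i = as.integer(ii[ord]), j = as.integer(jj[ord]),
                         w = NA_real_)
    # rank-matching: heavier weights go to edges whose endpoints had larger
    # original strengths, approximating the original strength sequence
    s <- connectome$strength
    score <- s[new_el$i] * s[new_el$j]
    new_el$w[order(score, decreasing = TRUE)] <-
      sort(el$w, decreasing = TRUE)
  }
  A <- matrix(0, n, n)
  A[cbind(new_el$i, new_el$j)] <- new_el$w
  A <- A + t(A)
  node_connectome(A, node_labels = connectome$node_labels,
                  absence_threshold = connectome$absence_threshold)
}

#' Nonparametric p-values against a rewiring null ensemble
#'
#' Draws `n_nulls` rewired surrogates, applies `statistic_fn` to each, and
#' compares the empirical statistic with the null distribution. The
#' p-value uses the permutation convention with a +1 pseudo-count so it is
#' never exactly 0: p = (1 + #{nulls at least as extreme}) / (1 + n_nulls)
#' on the chosen side; the two-sided p is twice the smaller one-sided p,
#' capped at 1.
#'
#' @param statistic_fn function mapping a [node_connectome()] to a numeric
#'   vector of fixed length (e.g., whole-brain eAC, per-edge eMC aligned
#'   to a fixed index).
#' @param connectome the empirical [node_connectome()] (typically the
#'   group average).
#' @param n_nulls ensemble size (default 5000).
#' @param side `"greater"` (empirical larger than null), `"less"`, or
#'   `"two-sided"`.
#' @param seed integer seed; per-null seeds are derived from it.
#' @param swaps_per_edge forwarded to [rewire_null()].
#' @return An object of class `null_ensemble`: list with `empirical_values`,
#'   `null_values` (n_nulls x M matrix), `p_values`, `side`, `n_nulls`
#'   (successful draws), `n_failed`, `seed`.
#' @export
null_pvalues <- function(statistic_fn, connectome, n_nulls = 5000,
                         side = c("greater", "less", "two-sided"),
                         seed = 1, swaps_per_edge = 10) {
  side <- match.arg(side)
  stopifnot(is.function(statistic_fn), n_nulls >= 1)
  set.seed(seed)
  null_seeds <- sample.int(.Machine$integer.max - 1L, n_nulls)
  empirical <- as.numeric(statistic_fn(connectome))
  M <- length(empirical)
  nulls <- matrix(NA_real_, n_nulls, M)
  n_failed <- 0L
  for (b in seq_len(n_nulls)) {
    stat_b <- tryCatch({
      nc <- rewire_null(connectome, swaps_per_edge, seed = null_seeds[b])
      as.numeric(statistic_fn(nc))
    }, error = function(e) NULL)
    if (is.null(stat_b) || length(stat_b) != M) n_failed <- n_failed + 1L
    else nulls[b, ] <- stat_b
  }
  if (n_failed > 0) {
    message(n_failed, " null draw(s) failed and were dropped")
    nulls <- nulls[stats::complete.cases(nulls), , drop = FALSE]
  }
  n_ok <- nrow(nulls)
  if (n_ok == 0) stop("all null draws failed")
  n_ge <- colSums(nulls >= rep(empirical, each = n_ok))
  n_le <- colSums(nulls <= rep(empirical, each = n_ok))
  p_greater <- (1 + n_ge) / (1 + n_ok)
  p_less <- (1 + n_le) / (1 + n_ok)
  p <- switch(side,
              greater = p_greater,
              less = p_less,
              `two-sided` = pmin(1, 2 * pmin(p_greater, p_less)))
  structure(list(empirical_values = empirical, null_values = nulls,
                 p_values = p, side = side, n_nulls = n_ok,
                 n_failed = n_failed, seed = seed),
            class = "null_ensemble")
}

#' @exportS3Method base::print
print.null_ensemble <- function(x, ...) {
  cat(sprintf("null_ensemble: %d nulls, %d statistic(s), side = %s\n",
              x$n_nulls, length(x$empirical_values), x$side))
  invisible(x)
}

#' Summarize a null ensemble as a per-element table
#'
#' @param ensemble a [null_pvalues()] result.
#' @param q FDR level for the adjusted column (default 0.05).
#' @return data frame with element index, empirical value, null mean/sd,
#'   p, BH-adjusted p, and the rejection flag at level `q`.
#' @export
null_table <- function(ensemble, q = 0.05) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  fdr <- fdr_bh(ensemble$p_values, q)
  data.frame(element = seq_along(ensemble$empirical_values),
             empirical = ensemble$empirical_values,
             null_mean = colMeans(ensemble$null_values),
             null_sd = apply(ensemble$null_values, 2, stats::sd),
             p = ensemble$p_values,
             p_adjusted = fdr$adjusted,
             significant = fdr$rejected)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up procedure at level `q`; rejections are the hypotheses whose
#' BH-adjusted p-value is at most `q`.
#'
#' @param p_values numeric vector in [0, 1].
#' @param q target FDR level (default 0.05).
#' @return list with `rejected` (logical mask) and `adjusted` (BH-adjusted
#'   p-values).
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) {
    return(list(rejected = logical(0), adjusted = numeric(0)))
  }
  stopifnot(all(p_values >= 0 & p_values <= 1))
  adjusted <- stats::p.adjust(p_values, method = "BH")
  list(rejected = adjusted <= q, adjusted = adjusted)
}
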