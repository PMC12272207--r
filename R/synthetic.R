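#' Specification for synthetic structural connectomes
#'
#' Describes a block-structured sparse weighted connectome emulating a
#' parcellated structural network: nodes grouped into canonical-network
#' blocks, denser within blocks than between, with heavy-tailed positive
#' (log-normal) weights mimicking quantitative-anisotropy edge strengths,
#' and the standard 0.001 absence threshold. Defaults emulate a 120-node
#' AAL2-like parcellation over 7 canonical networks.
#'
#' @param n_nodes nodes (default 120).
#' @param n_networks contiguous equal-size blocks (default 7).
#' @param within_density edge probability within a block (default 0.6).
#' @param between_density edge probability between blocks (default 0.2).
#' @param weight_meanlog,weight_sdlog log-normal weight parameters
#'   (default -2 and 0.8: median weight ~0.135, right-skewed).
#' @param subject_noise_sd multiplicative log-normal weight noise per
#'   subject in [generate_cohort()] (default 0.2).
#' @param absence_threshold weights below this are zeroed (default 0.001).
#' @param seed integer seed.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_nodes = 120, n_networks = 7,
                           within_density = 0.6, between_density = 0.2,
                           weight_meanlog = -2, weight_sdlog = 0.8,
                           subject_noise_sd = 0.2,
                           absence_threshold = 0.001, seed = 1) {
  stopifnot(n_nodes >= 2, n_networks >= 1, n_networks <= n_nodes,
            within_density >= 0, within_density <= 1,
            between_density >= 0, between_density <= 1,
            weight_sdlog >= 0, subject_noise_sd >= 0,
            absence_threshold >= 0)
  structure(list(n_nodes = n_nodes, n_networks = n_networks,
                 within_density = within_density,
                 between_density = between_density,
                 weight_meanlog = weight_meanlog,
                 weight_sdlog = weight_sdlog,
                 subject_noise_sd = subject_noise_sd,
                 absence_threshold = absence_threshold, seed = seed),
            class = "synthetic_spec")
}

#' Network-block assignment of a synthetic spec
#'
#' @param spec a [synthetic_spec()].
#' @return character vector of length `n_nodes` with labels `"net1"...`.
#' @export
synthetic_partition <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sizes <- diff(round(seq(0, spec$n_nodes, length.out = spec$n_networks + 1)))
  rep(paste0("net", seq_len(spec$n_networks)), times = sizes)
}

#' Generate one synthetic connectome
#'
#' Draws a block-structured symmetric graph: each node pair gets an edge
#' with the within- or between-block density, and present edges get
#' independent log-normal weights. Weights below the absence threshold
#' are zeroed, matching the loading convention for real connectomes.
#'
#' @param spec a [synthetic_spec()].
#' @param seed overrides `spec$seed` when given.
#' @return a [node_connectome()].
#' @export
generate_connectome <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(if (is.null(seed)) spec$seed else seed)
  n <- spec$n_nodes
  block <- as.integer(factor(synthetic_partition(spec),
                             levels = unique(synthetic_partition(spec))))
  ut <- which(upper.tri(diag(n)), arr.ind = TRUE)
  same <- block[ut[, 1]] == block[ut[, 2]]
  prob <- ifelse(same, spec$within_density, spec$between_density)
  present <- stats::runif(nrow(ut)) < prob
  w <- numeric(nrow(ut))
  w[present] <- stats::rlnorm(sum(present), spec$weight_meanlog,
                              spec$weight_sdlog)
  A <- matrix(0, n, n)
  A[ut] <- w
  A <- A + t(A)
  node_connectome(A, absence_threshold = spec$absence_threshold)
}

#' Generate a cohort sharing group topology
#'
#' All subjects share the group connectome's edge support; each subject's
#' weights are the group weights times mean-one multiplicative log-normal
#' noise (sd `subject_noise_sd` on the log scale), so the cohort mean
#' converges to the group matrix as the cohort grows.
#'
#' @param spec a [synthetic_spec()].
#' @param n_subjects cohort size.
#' @param seed overrides `spec$seed` when given.
#' @return list with `group` (the group [node_connectome()]) and
#'   `subjects` (list of per-subject connectomes).
#' @export
generate_cohort <- function(spec, n_subjects, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"), n_subjects >= 1)
  if (is.null(seed)) seed <- spec$seed
  group <- generate_connectome(spec, seed = seed)
  set.seed(seed + 1L)
  el <- build_edge_list(group)
  n <- group$n_nodes
  subjects <- vector("list", n_subjects)
  sd <- spec$subject_noise_sd
  for (s in seq_len(n_subjects)) {
    # mean-one log-normal factor: E[exp(N(0, sd^2))] = exp(sd^2/2)
    noise <- exp(stats::rnorm(nrow(el), 0, sd) - sd^2 / 2)
    A <- matrix(0, n, n)
    A[cbind(el$i, el$j)] <- el$w * noise
    A <- A + t(A)
    subjects[[s]] <- node_connectome(A,
                                     absence_threshold = spec$absence_threshold)
  }
  list(group = group, subjects = subjects)
}

#' Generate subject-by-edge feature matrices with a covarying signal set
#'
#' Emulates the across-subject structure of edge-level brain features:
#' most edges vary independently between subjects, while the edges of a
#' phenotype-relevant subnetwork covary through a shared subject-level
#' latent factor (pairwise correlation `signal_cor` among signal
#' features). All features have zero mean and unit variance.
#'
#' @param n_subjects rows of the feature matrix.
#' @param n_features columns P.
#' @param signal_edges integer column indices forming the covarying set.
#' @param signal_cor pairwise correlation among signal features
#'   (default 0.3).
#' @param seed integer seed.
#' @return n_subjects x n_features numeric matrix.
#' @export
generate_edge_features <- function(n_subjects, n_features, signal_edges,
                                   signal_cor = 0.3, seed = 1) {
  stopifnot(signal_cor >= 0, signal_cor < 1,
            all(signal_edges >= 1 & signal_edges <= n_features))
  set.seed(seed)
  X <- matrix(stats::rnorm(n_subjects * n_features), n_subjects, n_features)
  if (length(signal_edges) > 0 && signal_cor > 0) {
    g <- stats::rnorm(n_subjects)
    X[, signal_edges] <- sqrt(signal_cor) * g +
      sqrt(1 - signal_cor) * X[, signal_edges, drop = FALSE]
  }
  X
}

#' Plant a linear phenotype signal in edge features
#'
#' phenotype = linear combination of the signal-edge features plus
#' Gaussian noise scaled so the population R-squared of the signal equals
#' `r_squared`. Coefficients default to independent standard normals; a
#' fixed coefficient vector (e.g., all ones for a coherent subnetwork
#' effect) can be supplied.
#'
#' @param edge_features subjects x P numeric matrix.
#' @param signal_edges integer column indices carrying signal.
#' @param r_squared requested fraction of phenotype variance explained,
#'   in [0, 1].
#' @param seed integer seed.
#' @param coefficients optional numeric vector (length of `signal_edges`,
#'   or a scalar recycled) of signal-edge coefficients.
#' @return list with `phenotype` (length subjects), `coefficients`
#'   (length of `signal_edges`), and `signal_edges`.
#' @export
generate_phenotype <- function(edge_features, signal_edges, r_squared,
                               seed = 1, coefficients = NULL) {
  edge_features <- as.matrix(edge_features)
  n <- nrow(edge_features)
  stopifnot(r_squared >= 0, r_squared <= 1,
            all(signal_edges >= 1 & signal_edges <= ncol(edge_features)))
  set.seed(seed)
  beta <- if (is.null(coefficients)) stats::rnorm(length(signal_edges))
          else rep_len(coefficients, length(signal_edges))
  if (r_squared == 0) {
    return(list(phenotype = stats::rnorm(n), coefficients = beta * 0,
                signal_edges = as.integer(signal_edges)))
  }
  signal <- as.vector(edge_features[, signal_edges, drop = FALSE] %*% beta)
  v <- stats::var(signal)
  if (v == 0) stop("signal edges have zero variance across subjects")
  noise_sd <- sqrt(v * (1 - r_squared) / r_squared)
  list(phenotype = signal + stats::rnorm(n, 0, noise_sd),
       coefficients = beta, signal_edges = as.integer(signal_edges))
}
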