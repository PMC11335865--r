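# Degree-class attribute-shuffle null model.
#
# Chance-level homophily is estimated by permuting node attribute bundles
# among nodes with identical (in-degree, out-degree), so every replicate
# keeps the original tie structure and every degree--attribute coupling
# that operates at the level of degree classes.

#' Partition nodes into degree classes
#'
#' A degree class is the set of nodes sharing an exact
#' (in-degree, out-degree) pair. Attribute shuffling is confined to these
#' classes.
#'
#' @param network a `social_network`.
#' @return named list mapping `"in,out"` labels to integer node indices;
#'   the classes partition the node set.
#' @export
degree_class_index <- function(network) {
  split(seq_len(n_nodes(network)),
        paste(network$nodes$in_degree, network$nodes$out_degree, sep = ","))
}

# node columns that travel together as one attribute bundle; height and
# mass move with BMI so derived and raw measurements stay consistent
BUNDLE_COLS <- c("gender", "age", "height_cm", "mass_kg", "bmi")

#' Shuffle attribute bundles within degree classes
#'
#' Permutes each node's (gender, age, BMI) bundle — as an intact triple,
#' preserving the age-BMI-gender covariance — uniformly at random among the
#' nodes of its degree class. The edge structure is untouched, so degree
#' sequences, reciprocity, and the global multiset of bundles are all
#' invariant. Uses the current R random number generator state.
#'
#' @param network a `social_network`.
#' @param index optional precomputed [degree_class_index()].
#' @return a `social_network` with permuted attributes.
#' @export
shuffle_attributes <- function(network, index = NULL) {
  if (is.null(index)) index <- degree_class_index(network)
  cols <- intersect(BUNDLE_COLS, names(network$nodes))
  perm <- seq_len(n_nodes(network))
  for (cls in index) {
    if (length(cls) > 1L) perm[cls] <- cls[sample.int(length(cls))]
  }
  network$nodes[, cols] <- network$nodes[perm, cols]
  network
}

#' Null ensemble of a network statistic under degree-class shuffling
#'
#' Computes a statistic on the observed network and on `n_reps`
#' independently shuffled replicates, then asks whether the observed value
#' falls outside the 95% confidence interval of the null distribution. The
#' statistic receives the whole (shuffled) network and must itself perform
#' any subsetting (e.g. restrict to same-gender ties) so that the subsets
#' are re-derived from the shuffled attributes — this is what allows
#' chance-level same-gender assortativity to differ from zero when degree
#' and attributes are coupled.
#'
#' @param network a `social_network`.
#' @param statistic function `social_network -> number`; may return `NA`
#'   (undefined) on some replicates, which are excluded with a warning.
#' @param n_reps number of shuffled replicates (default 100).
#' @param seed optional integer seed for reproducibility.
#' @param ci_method `"normal_mean"` (mean +/- 1.96 sd/sqrt(n_reps), a 95%
#'   confidence interval for the null mean) or `"percentile"` (empirical
#'   2.5/97.5 percentiles of the replicate distribution).
#' @return object of class `shuffle_ensemble`: observed value, replicate
#'   vector, null mean, CI bounds, significance flag (observed outside the
#'   interval), n_reps, seed, ci_method.
#' @export
null_ensemble <- function(network, statistic, n_reps = 100L, seed = NULL,
                          ci_method = c("normal_mean", "percentile")) {
  ci_method <- match.arg(ci_method)
  if (!is.null(seed)) set.seed(seed)
  observed <- statistic(network)
  index <- degree_class_index(network)
  replicates <- vapply(seq_len(n_reps), function(i)
    as.numeric(statistic(shuffle_attributes(network, index))), numeric(1))
  n_na <- sum(is.na(replicates))
  if (n_na == n_reps)
    stop("null_ensemble: statistic undefined on every replicate")
  if (n_na > 0) {
    warning("null_ensemble: statistic undefined on ", n_na,
            " of ", n_reps, " replicates; excluded")
    replicates <- replicates[!is.na(replicates)]
  }
  mean_null <- mean(replicates)
  if (ci_method == "normal_mean") {
    half <- 1.96 * stats::sd(replicates) / sqrt(length(replicates))
    if (is.na(half)) half <- 0
    ci <- mean_null + c(-1, 1) * half
  } else {
    ci <- unname(stats::quantile(replicates, c(0.025, 0.975), type = 7))
  }
  structure(list(
    observed = observed,
    replicates = replicates,
    mean_null = mean_null,
    ci_low = ci[1], ci_high = ci[2],
    significant = !is.na(observed) && (observed < ci[1] || observed > ci[2]),
    n_reps = n_reps,
    seed = seed,
    ci_method = ci_method
  ), class = "shuffle_ensemble")
}

#' @export
print.shuffle_ensemble <- function(x, ...) {
  cat(sprintf(
    "<shuffle_ensemble> observed %.4f | null mean %.4f [%.4f, %.4f] (%s, %d reps)%s\n",
    x$observed, x$mean_null, x$ci_low, x$ci_high, x$ci_method,
    length(x$replicates),
    if (x$significant) " *different from chance*" else ""))
  invisible(x)
}

#' Statistic factory: same-gender assortativity
#'
#' Builds a statistic for [null_ensemble()] that restricts the (possibly
#' shuffled) network to one gender's ties and computes numeric
#' assortativity of an attribute — the subsetting happens after shuffling,
#' as required for a correct chance level.
#'
#' @param gender `"woman"` or `"man"`.
#' @param attr `"age"` or `"bmi"`.
#' @return function `social_network -> numeric`.
#' @export
same_gender_assortativity_stat <- function(gender, attr) {
  force(gender); force(attr)
  function(network) numeric_assortativity(same_gender_subnetwork(network, gender), attr)
}
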