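# Newman's numeric assortativity on directed graphs.

#' Numeric assortativity coefficient of a directed network
#'
#' The Pearson correlation between the attribute values at the two ends of
#' every directed edge: one (source value, target value) pair per stored
#' directed edge, never symmetrised, so a reciprocal pair contributes two
#' pairs. For a numeric attribute this is Newman's assortativity
#' coefficient and ranges from -1 (ties join dissimilar nodes) through 0
#' (no segregation) to 1 (ties join equal-valued nodes).
#'
#' @param network a `social_network` whose nodes all carry `attr`.
#' @param attr `"age"` or `"bmi"` (any numeric node column works).
#' @return the coefficient, or `NA` when undefined (no edges, or zero
#'   variance in either endpoint sequence).
#' @export
numeric_assortativity <- function(network, attr = "age") {
  if (!attr %in% names(network$nodes))
    stop("numeric_assortativity: unknown attribute '", attr, "'")
  v <- network$nodes[[attr]]
  e <- network$edges
  if (nrow(e) == 0) return(NA_real_)
  x <- v[e$from]
  y <- v[e$to]
  if (anyNA(x) || anyNA(y))
    stop("numeric_assortativity: attribute '", attr, "' missing on an edge endpoint")
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Default conditioning bins
#'
#' BMI bins of width 2 spanning the plausibility window 15-35; age bins of
#' width 3 years spanning the analysis window 15-32 (last bin truncated at
#' the window edge). Bin widths are plain arguments so alternative binnings
#' can be explored.
#'
#' @param attr `"age"` or `"bmi"`.
#' @param width bin width (default 3 years for age, 2 kg/m^2 for BMI).
#' @param range attribute range to span.
#' @return numeric vector of strictly increasing bin edges.
#' @export
default_bins <- function(attr = c("age", "bmi"), width = NULL, range = NULL) {
  attr <- match.arg(attr)
  if (is.null(width)) width <- if (attr == "age") 3 else 2
  if (is.null(range)) range <- if (attr == "age") c(15, 32) else c(15, 35)
  edges <- seq(range[1], range[2], by = width)
  if (edges[length(edges)] < range[2]) edges <- c(edges, range[2])
  edges
}

#' Assortativity conditioned on intervals of the other trait
#'
#' Splits the conditioning attribute into consecutive bins
#' `[e_i, e_{i+1})` (the last bin closed on the right), restricts the
#' network to each bin, and computes the numeric assortativity of the
#' target attribute inside it. This controls for a correlation between the
#' two traits: homophily in the target trait that merely reflects the
#' conditioning trait vanishes within bins. Bins with too few edges or
#' zero attribute variance are reported as undefined rather than dropped.
#'
#' @param network a `social_network`.
#' @param target_attr attribute whose assortativity is measured.
#' @param conditioning_attr attribute defining the bins.
#' @param bin_edges strictly increasing numeric vector of bin edges
#'   (default [default_bins()] for the conditioning attribute).
#' @param min_edges minimum edge count for a defined coefficient
#'   (default 10).
#' @return data.frame with one row per bin: `attribute`, `subset_lo`,
#'   `subset_hi`, `n_nodes`, `n_edges`, `r` (NA when undefined), `defined`.
#' @export
conditioned_assortativity <- function(network,
                                      target_attr = c("age", "bmi"),
                                      conditioning_attr = c("bmi", "age"),
                                      bin_edges = NULL,
                                      min_edges = 10L) {
  target_attr <- match.arg(target_attr)
  conditioning_attr <- match.arg(conditioning_attr)
  if (target_attr == conditioning_attr)
    stop("conditioned_assortativity: target and conditioning attribute coincide")
  if (is.null(bin_edges)) bin_edges <- default_bins(conditioning_attr)
  if (any(diff(bin_edges) <= 0))
    stop("conditioned_assortativity: bin_edges must be strictly increasing")
  k <- length(bin_edges) - 1L
  res <- vector("list", k)
  for (i in seq_len(k)) {
    sub <- attribute_interval_subnetwork(
      network, conditioning_attr, bin_edges[i], bin_edges[i + 1L],
      right_closed = (i == k))
    r <- if (n_edges(sub) >= min_edges) numeric_assortativity(sub, target_attr)
         else NA_real_
    res[[i]] <- data.frame(
      attribute = target_attr,
      subset_lo = bin_edges[i], subset_hi = bin_edges[i + 1L],
      n_nodes = n_nodes(sub), n_edges = n_edges(sub),
      r = r, defined = !is.na(r))
  }
  do.call(rbind, res)
}
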