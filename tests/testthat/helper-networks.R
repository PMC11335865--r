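# Shared builders and independent oracles for the test suite.

# node table with given attributes (recycled); ids "n1", "n2", ...
make_records <- function(n, gender = "woman", age = 25, bmi = 21) {
  data.frame(
    user_id = paste0("n", seq_len(n)),
    gender = factor(rep_len(gender, n), levels = c("woman", "man")),
    age = as.numeric(rep_len(age, n)),
    height_cm = 170,
    mass_kg = rep_len(bmi, n) * 1.7^2,
    bmi = as.numeric(rep_len(bmi, n)),
    stringsAsFactors = FALSE
  )
}

# edges from integer index pairs: make_edges(c(1,2), c(2,3)) => n1->n2, n2->n3
make_edges <- function(from, to) {
  data.frame(follower = paste0("n", from), followee = paste0("n", to),
             stringsAsFactors = FALSE)
}

toy_network <- function(n, from, to, ...) {
  build_network(make_records(n, ...), make_edges(from, to), quiet = TRUE)
}

# independent assortativity oracle: materialize the endpoint-pair list one
# edge at a time and compute Pearson's r from explicit sums
brute_force_assortativity <- function(network, attr) {
  pairs <- NULL
  for (i in seq_len(nrow(network$edges))) {
    e <- network$edges[i, ]
    xi <- network$nodes[[attr]][network$nodes$user_id == e$follower]
    yi <- network$nodes[[attr]][network$nodes$user_id == e$followee]
    pairs <- rbind(pairs, c(xi, yi))
  }
  if (is.null(pairs)) return(NA_real_)
  x <- pairs[, 1]; y <- pairs[, 2]
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  if (sxx == 0 || syy == 0) return(NA_real_)
  sxy / sqrt(sxx * syy)
}

# random directed graph with random numeric attributes (no self-loops,
# no duplicate ordered pairs)
random_test_network <- function(n_nodes = 8, n_edges = 20) {
  pairs <- expand.grid(from = seq_len(n_nodes), to = seq_len(n_nodes))
  pairs <- pairs[pairs$from != pairs$to, ]
  pick <- pairs[sample.int(nrow(pairs), min(n_edges, nrow(pairs))), ]
  rec <- make_records(n_nodes,
                      gender = sample(c("woman", "man"), n_nodes, TRUE),
                      age = sample(15:32, n_nodes, TRUE),
                      bmi = round(runif(n_nodes, 16, 34), 1))
  build_network(rec, make_edges(pick$from, pick$to), quiet = TRUE)
}

# hand-constructed mixed_fit from named coefficients (for slope/contrast
# algebra and closed-form checks)
manual_fit <- function(model_id, estimates, std_info = NULL,
                       family = "binomial") {
  structure(list(
    model_id = model_id,
    family = family,
    fixed_effects = data.frame(term = names(estimates),
                               estimate = unname(estimates),
                               se = 0.01, statistic = 0, p = 1,
                               stringsAsFactors = FALSE),
    random_intercept_variance = 0,
    n_obs = 0L, n_groups = 0L, converged = TRUE,
    diagnostics = character(), loglik = NA_real_,
    std_info = std_info, formula = "", model = NULL
  ), class = "mixed_fit")
}

# identity standardization (mean 0, sd 1) so raw values pass through
identity_std_info <- function(columns, min = -Inf, max = Inf) {
  data.frame(column = columns, mean = 0, sd = 1, min = min, max = max,
             stringsAsFactors = FALSE)
}

fixture_path <- function(...) {
  p <- system.file("extdata", "synthetic_pokec", ..., package = "sociomix")
  if (!nzchar(p)) stop("packaged fixture not found")
  p
}
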