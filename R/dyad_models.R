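# Long-format dyad tables, trait-similarity and reciprocity mixed models,
# per-gender simple slopes, predicted-probability contrasts, descriptives.
#
# The similarity models regress the followee's (standardized) trait on the
# follower's, with dyad gender and the signed difference in the other trait
# as covariates in a full factorial, and a random intercept per follower to
# absorb the dependence among the many dyads sharing a follower. They are
# the regression counterpart of an assortativity coefficient, but carry
# standard errors so genders can be compared. The reciprocity model is a
# binomial-logit mixed model of whether a follow is returned, as a function
# of the absolute trait differences, gender, and all interactions.

#' Build the long-format dyad table
#'
#' One row per ordered same-gender follower-followee edge (a reciprocal
#' pair yields two rows, one per direction); mixed-gender ties never enter.
#' Signed differences follow the follower-minus-followee convention.
#'
#' @param network a `social_network` with complete gender, age, and BMI.
#' @param reciprocal_only keep only rows whose unordered pair is mutual
#'   (used by the trait-similarity models).
#' @param dedupe_reciprocal represent each reciprocal pair by a single row
#'   (lower id as follower) instead of two directed rows.
#' @return data.frame with columns follower_id, followee_id, dyad_gender,
#'   follower/followee age and bmi, signed `age_diff` and `bmi_diff`,
#'   `abs_age_diff`, `abs_bmi_diff`, and logical `reciprocal`.
#' @export
build_dyad_table <- function(network, reciprocal_only = FALSE,
                             dedupe_reciprocal = FALSE) {
  nd <- network$nodes
  e <- network$edges
  same <- !is.na(nd$gender[e$from]) & !is.na(nd$gender[e$to]) &
    nd$gender[e$from] == nd$gender[e$to]
  e <- e[same, , drop = FALSE]
  d <- data.frame(
    follower_id = e$follower,
    followee_id = e$followee,
    dyad_gender = factor(as.character(nd$gender[e$from]), levels = GENDER_LEVELS),
    follower_age = nd$age[e$from],
    followee_age = nd$age[e$to],
    follower_bmi = nd$bmi[e$from],
    followee_bmi = nd$bmi[e$to],
    stringsAsFactors = FALSE
  )
  d$age_diff <- d$follower_age - d$followee_age
  d$bmi_diff <- d$follower_bmi - d$followee_bmi
  d$abs_age_diff <- abs(d$age_diff)
  d$abs_bmi_diff <- abs(d$bmi_diff)
  d$reciprocal <- e$reciprocal
  if (reciprocal_only) d <- d[d$reciprocal, , drop = FALSE]
  if (dedupe_reciprocal) {
    dup <- d$reciprocal & d$follower_id > d$followee_id
    d <- d[!dup, , drop = FALSE]
  }
  rownames(d) <- NULL
  d
}

#' Standardize columns of a table
#'
#' Z-scores each listed column using its own mean and standard deviation
#' over the table's rows; the parameters are retained so raw values can be
#' mapped to the model scale later (and back).
#'
#' @param table data.frame.
#' @param columns character vector of numeric column names.
#' @param suffix appended to each standardized column's name.
#' @return list with `table` (standardized columns added) and `info`
#'   (data.frame: column, mean, sd, observed min/max).
#' @export
standardize_columns <- function(table, columns, suffix = "_z") {
  info <- data.frame(column = columns, mean = NA_real_, sd = NA_real_,
                     min = NA_real_, max = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(columns)) {
    cl <- columns[i]
    x <- table[[cl]]
    if (!is.numeric(x)) stop("standardize_columns: '", cl, "' is not numeric")
    m <- mean(x); s <- stats::sd(x)
    if (is.na(s) || s == 0)
      stop("standardize_columns: column '", cl, "' has zero standard deviation")
    info$mean[i] <- m; info$sd[i] <- s
    info$min[i] <- min(x); info$max[i] <- max(x)
    table[[paste0(cl, suffix)]] <- (x - m) / s
  }
  list(table = table, info = info)
}

#' Map a raw value to the standardized model scale
#'
#' @param info the `info` element of [standardize_columns()].
#' @param column standardized column name.
#' @param value raw-scale value(s).
#' @return standardized value(s).
#' @export
to_standardized <- function(info, column, value) {
  i <- match(column, info$column)
  if (is.na(i)) stop("to_standardized: no standardization recorded for '",
                     column, "'")
  (value - info$mean[i]) / info$sd[i]
}

# ---- mixed-model fit container ---------------------------------------------

new_mixed_fit <- function(model_id, fit, std_info, formula_str,
                          family = "gaussian") {
  is_mer <- inherits(fit, "merMod")
  co <- if (is_mer) summary(fit)$coefficients else summary(fit)$coefficients
  stat_col <- if ("t value" %in% colnames(co)) "t value" else "z value"
  est <- co[, "Estimate"]
  se <- co[, "Std. Error"]
  stat <- co[, stat_col]
  # Wald p-values on the normal reference; with thousands of dyads the
  # difference from a t reference is negligible
  p <- 2 * stats::pnorm(-abs(stat))
  conv <- TRUE
  diag_msgs <- character()
  if (is_mer) {
    msgs <- fit@optinfo$conv$lme4$messages
    if (length(msgs)) { conv <- FALSE; diag_msgs <- unlist(msgs) }
    if (!is.null(fit@optinfo$conv$opt) && fit@optinfo$conv$opt != 0) conv <- FALSE
    vc <- as.data.frame(lme4::VarCorr(fit))
    ri_var <- vc$vcov[vc$grp == "follower_id" & vc$var1 == "(Intercept)"][1]
    n_groups <- lme4::ngrps(fit)[["follower_id"]]
    ll <- as.numeric(stats::logLik(fit))
    n_obs <- stats::nobs(fit)
  } else {
    if (!is.null(fit$converged) && !fit$converged) {
      conv <- FALSE; diag_msgs <- "IWLS did not converge"
    }
    ri_var <- 0
    n_groups <- NA_integer_
    ll <- as.numeric(stats::logLik(fit))
    n_obs <- stats::nobs(fit)
  }
  # huge coefficients or standard errors flag quasi-separation in the
  # binomial model
  if (family == "binomial" && any(abs(est) > 15 | se > 15)) {
    conv <- FALSE
    diag_msgs <- c(diag_msgs,
                   "extreme estimates/SEs: possible complete separation")
  }
  structure(list(
    model_id = model_id,
    family = family,
    fixed_effects = data.frame(term = rownames(co), estimate = unname(est),
                               se = unname(se), statistic = unname(stat),
                               p = unname(p), stringsAsFactors = FALSE),
    random_intercept_variance = ri_var,
    n_obs = n_obs,
    n_groups = n_groups,
    converged = conv,
    diagnostics = diag_msgs,
    loglik = ll,
    std_info = std_info,
    formula = formula_str,
    model = fit
  ), class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat("<mixed_fit> ", x$model_id, " (", x$family, "), n = ", x$n_obs,
      if (!is.na(x$n_groups)) paste0(", followers = ", x$n_groups), ", ",
      if (x$converged) "converged" else "NOT CONVERGED", "\n", sep = "")
  fe <- x$fixed_effects
  fe[, 2:5] <- lapply(fe[, 2:5], function(v) signif(v, 4))
  print(fe, row.names = FALSE)
  cat("random intercept variance (follower):",
      signif(x$random_intercept_variance, 4), "\n")
  invisible(x)
}

#' Fixed-effect estimate by term
#' @param fit a `mixed_fit`.
#' @param term exact term name.
#' @return named list(estimate, se, p) or error if absent.
#' @export
fixed_effect <- function(fit, term) {
  i <- match(term, fit$fixed_effects$term)
  if (is.na(i)) stop("fixed_effect: no term '", term, "' in model ",
                     fit$model_id)
  as.list(fit$fixed_effects[i, c("estimate", "se", "p")])
}

# find an interaction term irrespective of component order
match_interaction <- function(terms, parts) {
  split_terms <- strsplit(terms, ":", fixed = TRUE)
  hit <- vapply(split_terms, function(tt)
    length(tt) == length(parts) && setequal(tt, parts), logical(1))
  which(hit)[1]
}

#' Fit a trait-similarity mixed model
#'
#' Linear mixed model on reciprocal same-gender dyads: the followee's
#' standardized trait is regressed on the follower's standardized trait,
#' dyad gender, and the standardized signed difference in the other trait,
#' with all interactions (full factorial) and a random intercept per
#' follower. Outcome and continuous predictors are z-scored on the supplied
#' table before fitting; the model is estimated by maximum likelihood with
#' the bobyqa optimizer.
#'
#' @param dyads dyad table (normally `reciprocal_only = TRUE`).
#' @param trait `"age"` (the other-trait covariate is then the signed BMI
#'   difference) or `"bmi"` (covariate: signed age difference).
#' @return a `mixed_fit` (`model_id` `"age_similarity"` or
#'   `"bmi_similarity"`). Non-convergence is flagged on the fit, not
#'   raised.
#' @export
fit_trait_similarity_model <- function(dyads, trait = c("age", "bmi")) {
  trait <- match.arg(trait)
  other_diff <- if (trait == "age") "bmi_diff" else "age_diff"
  outcome <- paste0("followee_", trait)
  focal <- paste0("follower_", trait)
  std <- standardize_columns(dyads, c(outcome, focal, other_diff))
  f <- stats::as.formula(paste0(
    outcome, "_z ~ ", focal, "_z * dyad_gender * ", other_diff,
    "_z + (1 | follower_id)"))
  fit <- lme4::lmer(f, data = std$table, REML = FALSE,
                    control = lme4::lmerControl(optimizer = "bobyqa"))
  new_mixed_fit(paste0(trait, "_similarity"), fit, std$info,
                deparse1(f), family = "gaussian")
}

#' Per-gender simple slopes of a focal predictor
#'
#' With treatment coding (reference level "woman"), the women's slope is
#' the focal main effect and the men's slope adds the focal-by-gender
#' interaction; both are evaluated at 0 (the mean) of the other
#' standardized covariates. The interaction p-value tests the gender
#' difference in slope.
#'
#' @param fit a converged `mixed_fit`.
#' @param focal_term name of the focal fixed effect (e.g.
#'   `"follower_age_z"`); defaults to the follower-trait term of a
#'   similarity model or the absolute-BMI-difference term of the
#'   reciprocity model.
#' @return list(beta_women, beta_men, interaction_p, focal_term).
#' @export
gender_slopes <- function(fit, focal_term = NULL) {
  if (is.null(focal_term)) {
    focal_term <- switch(fit$model_id,
      age_similarity = "follower_age_z",
      bmi_similarity = "follower_bmi_z",
      reciprocity = "abs_bmi_diff_z",
      stop("gender_slopes: supply focal_term for model ", fit$model_id))
  }
  terms <- fit$fixed_effects$term
  i_main <- match(focal_term, terms)
  if (is.na(i_main)) stop("gender_slopes: no term '", focal_term, "'")
  i_int <- match_interaction(terms, c(focal_term, "dyad_genderman"))
  if (is.na(i_int))
    stop("gender_slopes: no gender interaction for '", focal_term, "'")
  beta_women <- fit$fixed_effects$estimate[i_main]
  beta_men <- beta_women + fit$fixed_effects$estimate[i_int]
  list(beta_women = beta_women, beta_men = beta_men,
       interaction_p = fit$fixed_effects$p[i_int], focal_term = focal_term)
}

#' Fit the tie-reciprocity model
#'
#' Binomial-logit mixed model on all ordered same-gender dyads: whether the
#' follow is reciprocated, as a function of the standardized absolute age
#' and BMI differences, dyad gender, and all interactions (including the
#' three-way term), with a random intercept per follower (Laplace
#' approximation, bobyqa optimizer). A fixed-effects-only logistic
#' regression is available for comparison via `random_intercept = FALSE`.
#'
#' @param dyads dyad table including non-reciprocal rows.
#' @param random_intercept include the per-follower random intercept.
#' @return a `mixed_fit` with `model_id` `"reciprocity"`. Possible complete
#'   separation is flagged on the fit, not raised.
#' @export
fit_reciprocity_model <- function(dyads, random_intercept = TRUE) {
  std <- standardize_columns(dyads, c("abs_age_diff", "abs_bmi_diff"))
  tab <- std$table
  tab$reciprocal <- as.integer(tab$reciprocal)
  if (random_intercept) {
    f <- reciprocal ~ abs_age_diff_z * abs_bmi_diff_z * dyad_gender +
      (1 | follower_id)
    fit <- lme4::glmer(f, data = tab, family = stats::binomial("logit"),
                       control = lme4::glmerControl(optimizer = "bobyqa"))
  } else {
    f <- reciprocal ~ abs_age_diff_z * abs_bmi_diff_z * dyad_gender
    fit <- stats::glm(f, data = tab, family = stats::binomial("logit"))
  }
  new_mixed_fit("reciprocity", fit, std$info, deparse1(f),
                family = "binomial")
}

# linear predictor of the full-factorial reciprocity model at given
# standardized difference values, random intercept at 0
reciprocity_linear_predictor <- function(fit, z_age, z_bmi, gender) {
  terms <- fit$fixed_effects$term
  est <- fit$fixed_effects$estimate
  g <- as.numeric(gender == "man")
  pick <- function(parts) {
    i <- if (length(parts) == 0) match("(Intercept)", terms)
         else if (length(parts) == 1) match(parts, terms)
         else match_interaction(terms, parts)
    if (is.na(i)) 0 else est[i]
  }
  pick(character()) +
    pick("abs_age_diff_z") * z_age +
    pick("abs_bmi_diff_z") * z_bmi +
    pick("dyad_genderman") * g +
    pick(c("abs_age_diff_z", "abs_bmi_diff_z")) * z_age * z_bmi +
    pick(c("abs_age_diff_z", "dyad_genderman")) * z_age * g +
    pick(c("abs_bmi_diff_z", "dyad_genderman")) * z_bmi * g +
    pick(c("abs_age_diff_z", "abs_bmi_diff_z", "dyad_genderman")) *
      z_age * z_bmi * g
}

#' Predicted-probability contrast of the reciprocity model
#'
#' Predicted reciprocity probability (population level: random intercept at
#' 0) at two raw-scale absolute BMI differences, holding the absolute age
#' difference at a raw value, for one gender. Raw values are mapped to the
#' standardized model scale with the standardization recorded at fit time.
#' Reports the change both in percentage points and relative to the
#' starting probability, since a "percent decrease in likelihood" can be
#' read either way.
#'
#' @param fit a `mixed_fit` from [fit_reciprocity_model()].
#' @param gender `"woman"` or `"man"`.
#' @param bmi_diff_raw length-2 raw-scale absolute BMI difference
#'   endpoints (default 0 to 10 kg/m^2).
#' @param age_diff_raw raw-scale absolute age difference held fixed
#'   (default 0 years, i.e. same-aged peers).
#' @return list(gender, p_at_start, p_at_end, abs_change_pp,
#'   rel_change_pct, bmi_diff_raw, age_diff_raw). Warns when a requested
#'   raw value lies outside the range observed at fit time.
#' @export
reciprocity_contrast <- function(fit, gender = c("woman", "man"),
                                 bmi_diff_raw = c(0, 10), age_diff_raw = 0) {
  gender <- match.arg(gender)
  stopifnot(length(bmi_diff_raw) == 2L)
  info <- fit$std_info
  ib <- match("abs_bmi_diff", info$column)
  ia <- match("abs_age_diff", info$column)
  if (is.na(ib) || is.na(ia))
    stop("reciprocity_contrast: fit lacks standardization info for the ",
         "absolute differences")
  if (!is.na(info$max[ib]) &&
      (max(bmi_diff_raw) > info$max[ib] || min(bmi_diff_raw) < info$min[ib]))
    warning("reciprocity_contrast: requested BMI difference outside the ",
            "range observed at fit time [", signif(info$min[ib], 3), ", ",
            signif(info$max[ib], 3), "]")
  z_bmi <- to_standardized(info, "abs_bmi_diff", bmi_diff_raw)
  z_age <- to_standardized(info, "abs_age_diff", age_diff_raw)
  p <- stats::plogis(reciprocity_linear_predictor(fit, z_age, z_bmi, gender))
  list(gender = gender,
       p_at_start = p[1], p_at_end = p[2],
       abs_change_pp = 100 * (p[2] - p[1]),
       rel_change_pct = 100 * (p[2] - p[1]) / p[1],
       bmi_diff_raw = bmi_diff_raw, age_diff_raw = age_diff_raw)
}

#' Cohen's d with pooled standard deviation
#'
#' @param x,y numeric vectors (difference reported as mean(x) - mean(y)).
#' @return standardized mean difference, `NA` if either group has fewer
#'   than two values.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) return(NA_real_)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  (mean(x) - mean(y)) / sp
}

#' Gender descriptives of the analysis sample
#'
#' Per-gender BMI means, the standardized BMI gender difference (Cohen's d
#' with pooled SD, men minus women), the per-gender Spearman rank
#' correlation between BMI and age (average ranks for ties), and age
#' summaries. Age mean/median/SD and the window share are computed on the
#' pre-window population with known age when one is supplied, since the
#' window is chosen from that distribution.
#'
#' @param records analysis-sample records.
#' @param full_age_records optional records before the age-window cut (with
#'   known age) for the age summaries.
#' @param age_window closed age interval for the window share.
#' @return list of class `descriptive_stats`.
#' @export
gender_descriptives <- function(records, full_age_records = NULL,
                                age_window = c(15, 32)) {
  by_gender <- function(g) records[!is.na(records$gender) &
                                     records$gender == g, , drop = FALSE]
  w <- by_gender("woman"); m <- by_gender("man")
  rho <- function(d) if (nrow(d) >= 2 && stats::sd(d$bmi) > 0 &&
                         stats::sd(d$age) > 0)
    stats::cor(d$bmi, d$age, method = "spearman") else NA_real_
  age_pop <- full_age_records %||% records
  ages <- age_pop$age[!is.na(age_pop$age)]
  structure(list(
    n_women = nrow(w), n_men = nrow(m),
    mean_bmi_women = mean(w$bmi), mean_bmi_men = mean(m$bmi),
    cohens_d_bmi = cohens_d(m$bmi, w$bmi),
    spearman_bmi_age_women = rho(w), spearman_bmi_age_men = rho(m),
    age_mean = mean(ages), age_median = stats::median(ages),
    age_sd = stats::sd(ages),
    pct_age_in_window = if (length(ages) == 0) NA_real_ else
      100 * mean(ages >= age_window[1] & ages <= age_window[2])
  ), class = "descriptive_stats")
}
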