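test_that("the dyad table enumerates ordered same-gender ties with the stated conventions", {
  # 2 reciprocal pairs + 1 one-way tie among women, 1 mixed-gender tie
  rec <- make_records(6, gender = c(rep("woman", 5), "man"),
                      age = c(20, 22, 25, 28, 30, 24),
                      bmi = c(18, 20, 22, 24, 26, 23))
  ed <- make_edges(c(1, 2, 3, 4, 5, 1), c(2, 1, 4, 3, 1, 6))
  net <- build_network(rec, ed, quiet = TRUE)
  all_rows <- build_dyad_table(net)
  expect_equal(nrow(all_rows), 5)          # mixed-gender tie never a row
  recip <- build_dyad_table(net, reciprocal_only = TRUE)
  expect_equal(nrow(recip), 4)             # two rows per reciprocal pair
  expect_true(all(recip$reciprocal))
  # sign conventions: follower minus followee
  r12 <- all_rows[all_rows$follower_id == "n1" & all_rows$followee_id == "n2", ]
  expect_equal(r12$age_diff, 20 - 22)
  expect_equal(r12$bmi_diff, 18 - 20)
  expect_equal(r12$abs_age_diff, 2)
  expect_true(all(all_rows$abs_age_diff >= 0 & all_rows$abs_bmi_diff >= 0))
  # deduping keeps one row per reciprocal pair
  dd <- build_dyad_table(net, reciprocal_only = TRUE, dedupe_reciprocal = TRUE)
  expect_equal(nrow(dd), 2)
  # empty network -> empty table
  empty <- build_network(make_records(2), make_edges(integer(), integer()),
                         quiet = TRUE)
  expect_equal(nrow(build_dyad_table(empty)), 0)
})

test_that("standardization is exact, invertible, and rejects constant columns", {
  d <- data.frame(x = rnorm(50, 10, 3), y = runif(50), k = rep(1, 50))
  std <- standardize_columns(d, c("x", "y"))
  expect_equal(mean(std$table$x_z), 0, tolerance = 1e-12)
  expect_equal(sd(std$table$x_z), 1, tolerance = 1e-12)
  i <- match("x", std$info$column)
  back <- std$table$x_z * std$info$sd[i] + std$info$mean[i]
  expect_equal(back, d$x, tolerance = 1e-12)
  expect_equal(to_standardized(std$info, "x", d$x[3]), std$table$x_z[3],
               tolerance = 1e-12)
  expect_error(standardize_columns(d, "k"), "zero standard deviation")
})

test_that("the similarity model recovers a known standardized slope and a null slope", {
  d <- simulate_similarity_dyads(8000, 800, slope = 0.6, seed = 21)
  fit <- fit_trait_similarity_model(d, "age")
  expect_true(fit$converged)
  fe <- fixed_effect(fit, "follower_age_z")
  expect_lt(abs(fe$estimate - 0.6), 2 * fe$se)
  expect_gt(fit$n_groups, 1)
  expect_equal(fit$n_obs, 8000)

  d0 <- simulate_similarity_dyads(8000, 800, slope = 0, sd_intercept = 0.3,
                                  seed = 22)
  fit0 <- fit_trait_similarity_model(d0, "age")
  fe0 <- fixed_effect(fit0, "follower_age_z")
  expect_lt(abs(fe0$estimate), 2 * fe0$se)
})

test_that("with negligible random-intercept variance the similarity model matches OLS", {
  d <- simulate_similarity_dyads(3000, 300, slope = 0.5, sd_intercept = 0,
                                 seed = 33)
  fit <- fit_trait_similarity_model(d, "age")
  std <- standardize_columns(d, c("followee_age", "follower_age", "bmi_diff"))
  ols <- lm(followee_age_z ~ follower_age_z * dyad_gender * bmi_diff_z,
            data = std$table)
  expect_equal(fit$random_intercept_variance, 0, tolerance = 1e-3)
  keep <- intersect(fit$fixed_effects$term, names(coef(ols)))
  expect_equal(fit$fixed_effects$estimate[match(keep, fit$fixed_effects$term)],
               unname(coef(ols)[keep]), tolerance = 1e-5)
})

test_that("per-gender simple slopes are the stated linear combinations", {
  fit <- manual_fit("age_similarity", c(
    "(Intercept)" = 0, "follower_age_z" = 0.5, "dyad_genderman" = 0.2,
    "bmi_diff_z" = 0.1, "follower_age_z:dyad_genderman" = 0.1,
    "follower_age_z:bmi_diff_z" = 0.05,
    "dyad_genderman:bmi_diff_z" = 0.02,
    "follower_age_z:dyad_genderman:bmi_diff_z" = 0.01),
    family = "gaussian")
  s <- gender_slopes(fit, "follower_age_z")
  expect_equal(s$beta_women, 0.5)
  expect_equal(s$beta_men, 0.6)
  # zero interaction -> equal slopes
  fit2 <- manual_fit("age_similarity", c(
    "(Intercept)" = 0, "follower_age_z" = 0.4,
    "follower_age_z:dyad_genderman" = 0), family = "gaussian")
  s2 <- gender_slopes(fit2, "follower_age_z")
  expect_equal(s2$beta_men, s2$beta_women)
  # missing interaction term errors
  fit3 <- manual_fit("x", c("(Intercept)" = 0, "follower_age_z" = 0.4))
  expect_error(gender_slopes(fit3, "follower_age_z"), "interaction")
})

test_that("the reciprocity model recovers known logistic coefficients", {
  d <- simulate_reciprocity_dyads(
    20000, 2000, coefs = list(intercept = -0.5, age = -0.19, bmi = -0.4),
    seed = 44)
  fit <- fit_reciprocity_model(d)
  expect_true(fit$converged)
  fb <- fixed_effect(fit, "abs_bmi_diff_z")
  expect_lt(abs(fb$estimate - (-0.4)), 2 * fb$se)
  f0 <- fixed_effect(fit, "(Intercept)")
  expect_lt(abs(f0$estimate - (-0.5)), 3 * f0$se)
})

test_that("with no true effects the reciprocity terms sit near zero", {
  d <- simulate_reciprocity_dyads(10000, 1000,
                                  coefs = list(intercept = -0.3), seed = 55)
  fit <- fit_reciprocity_model(d)
  fe <- fit$fixed_effects
  for (tm in setdiff(fe$term, "(Intercept)")) {
    x <- fixed_effect(fit, tm)
    expect_lt(abs(x$estimate), 3 * x$se)
  }
})

test_that("the fixed-effects-only reciprocity fallback matches glm", {
  d <- simulate_reciprocity_dyads(4000, 400,
                                  coefs = list(intercept = -0.5, bmi = -0.3),
                                  sd_intercept = 0, seed = 66)
  fit <- fit_reciprocity_model(d, random_intercept = FALSE)
  std <- standardize_columns(d, c("abs_age_diff", "abs_bmi_diff"))
  ref <- glm(reciprocal ~ abs_age_diff_z * abs_bmi_diff_z * dyad_gender,
             data = std$table, family = binomial())
  expect_equal(fit$fixed_effects$estimate, unname(coef(ref)),
               tolerance = 1e-8)
  expect_equal(fit$random_intercept_variance, 0)
})

test_that("predicted-probability contrasts follow the closed-form logistic", {
  # raw-scale logit p = plogis(0 - 0.1 * dBMI): p(0) = 0.5, p(10) = 0.26894
  fit <- manual_fit("reciprocity",
                    c("(Intercept)" = 0, "abs_bmi_diff_z" = -0.1,
                      "abs_age_diff_z" = 0),
                    std_info = identity_std_info(
                      c("abs_age_diff", "abs_bmi_diff"), min = 0, max = 20))
  ct <- reciprocity_contrast(fit, "woman", bmi_diff_raw = c(0, 10),
                             age_diff_raw = 0)
  expect_equal(ct$p_at_start, 0.5, tolerance = 1e-6)
  expect_equal(ct$p_at_end, plogis(-1), tolerance = 1e-6)
  expect_equal(ct$abs_change_pp, 100 * (plogis(-1) - 0.5), tolerance = 1e-4)
  # identical endpoints -> exactly zero change
  ct0 <- reciprocity_contrast(fit, "woman", bmi_diff_raw = c(3, 3))
  expect_identical(ct0$abs_change_pp, 0)
  # all-zero slopes -> no change anywhere
  flat <- manual_fit("reciprocity", c("(Intercept)" = 0.7),
                     std_info = identity_std_info(
                       c("abs_age_diff", "abs_bmi_diff"), min = 0, max = 20))
  expect_equal(reciprocity_contrast(flat, "man")$abs_change_pp, 0)
  # values beyond the observed range warn
  narrow <- manual_fit("reciprocity", c("(Intercept)" = 0),
                       std_info = identity_std_info(
                         c("abs_age_diff", "abs_bmi_diff"), min = 0, max = 5))
  expect_warning(reciprocity_contrast(narrow, "woman", c(0, 10)), "range")
})

test_that("predicted probabilities are monotone in each coefficient's direction", {
  fit <- manual_fit("reciprocity",
                    c("(Intercept)" = 0.2, "abs_bmi_diff_z" = -0.3,
                      "abs_age_diff_z" = -0.1, "dyad_genderman" = 0.1),
                    std_info = identity_std_info(
                      c("abs_age_diff", "abs_bmi_diff"), min = 0, max = 30))
  p <- vapply(c(0, 5, 10, 20), function(b)
    reciprocity_contrast(fit, "woman", bmi_diff_raw = c(0, b))$p_at_end,
    numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("similarity slope and assortativity agree on covariate-free reciprocal networks", {
  # both are standardized regressions of followee trait on follower trait
  set.seed(77)
  n <- 400
  age <- sample(15:32, n, TRUE)
  rec <- make_records(n, gender = "woman", age = age,
                      bmi = round(runif(n, 17, 30), 1))
  # mutual ties between age-similar users
  from <- integer(); to <- integer()
  for (i in seq_len(n)) {
    cand <- which(abs(age - age[i]) <= 4)
    cand <- setdiff(cand, i)
    k <- min(3, length(cand))
    if (k > 0) {
      tgt <- sample(cand, k)
      from <- c(from, rep(i, k), tgt)
      to <- c(to, tgt, rep(i, k))
    }
  }
  net <- build_network(rec, make_edges(from, to), quiet = TRUE)
  r <- numeric_assortativity(net, "age")
  d <- build_dyad_table(net, reciprocal_only = TRUE)
  d$dyad_gender <- factor(rep(c("woman", "man"), length.out = nrow(d)),
                          levels = c("woman", "man"))  # synthetic split
  fit <- fit_trait_similarity_model(d, "age")
  pooled <- mean(c(gender_slopes(fit)$beta_women, gender_slopes(fit)$beta_men))
  expect_lt(abs(pooled - r), 0.1)
})

test_that("Cohen's d and the descriptives match hand computations", {
  expect_equal(cohens_d(c(3, 4), c(1, 2)), 2 / sqrt(0.5), tolerance = 1e-3)
  expect_equal(cohens_d(c(1, 2), c(1, 2)), 0)
  expect_true(is.na(cohens_d(1, c(2, 3))))

  rec <- make_records(8, gender = rep(c("woman", "man"), each = 4),
                      age = c(20, 22, 24, 26, 20, 22, 24, 26),
                      bmi = c(18, 19, 20, 21, 23, 24, 25, 26))
  ds <- gender_descriptives(rec)
  expect_equal(ds$mean_bmi_women, 19.5)
  expect_equal(ds$mean_bmi_men, 24.5)
  expect_equal(ds$cohens_d_bmi,
               (24.5 - 19.5) / sqrt((3 * var(c(18, 19, 20, 21)) +
                                       3 * var(c(23, 24, 25, 26))) / 6))
  # bmi strictly increasing with age in both genders -> rho = 1
  expect_equal(ds$spearman_bmi_age_women, 1)
  expect_equal(ds$spearman_bmi_age_men, 1)
  expect_equal(ds$age_mean, 23)
  expect_equal(ds$age_median, 23)
  # age summaries use the pre-window population when supplied
  full <- make_records(4, age = c(10, 20, 30, 60))
  ds2 <- gender_descriptives(rec, full_age_records = full)
  expect_equal(ds2$age_mean, 30)
  expect_equal(ds2$pct_age_in_window, 50)  # 20 and 30 of the four
})
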