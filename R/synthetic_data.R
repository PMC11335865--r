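# Synthetic directed social networks with known gender/age/BMI structure.
#
# The generator emulates the joint structure the analysis assumes in real
# data: two gender groups with different BMI distributions, a BMI-age
# association that is stronger in men, tie probability decaying with trait
# distance (homophilous tie formation), and reciprocation probability
# decaying with the absolute trait differences. Every stage is a pure
# function of (config, RNG state), so runs are bit-reproducible.

#' Synthetic-network configuration
#'
#' Defaults emulate the population structure of a young-adult online
#' social network: women's mean BMI 19.6 and men's 23 kg/m^2 at the centre
#' of the 15-32 age window, BMI rising with age roughly 0.30 kg/m^2 per
#' year for men and 0.12 for women, and residual spread chosen so the
#' BMI-age rank correlation is about 0.5 for men and 0.25 for women.
#' Tie-formation decays are negative for homophilous regimes (the linear
#' predictor is theta0 + theta_gender*same_gender + theta_age*|dAge| +
#' theta_bmi*|dBMI|, so a negative coefficient means fewer ties between
#' dissimilar users). Reciprocation coefficients act on standardized
#' absolute differences with treatment coding for gender (woman is the
#' reference); defaults give women a steeper BMI-difference decay than men.
#'
#' @param n_nodes number of users.
#' @param p_man probability a user is a man.
#' @param age_range closed integer age range.
#' @param age_dist `"uniform"` over the range, or `"skew"` (discretized
#'   skew-normal, right-skewed like self-reported ages on such platforms;
#'   clipped to `age_clip`).
#' @param age_skew list(xi, omega, alpha) for the skew-normal option.
#' @param age_clip clip range for the skew option.
#' @param bmi_intercept named per-gender mean BMI at the mid-age.
#' @param bmi_age_slope named per-gender BMI change per year of age.
#' @param bmi_sd named per-gender residual SD of BMI.
#' @param bmi_clip BMI values clipped into this plausibility window.
#' @param height_mean,height_sd per-gender height distribution (cm), used
#'   only to back-solve plausible height/mass pairs for fixtures.
#' @param theta0 tie-formation baseline logit.
#' @param theta_gender additive logit bonus for a same-gender pair.
#' @param theta_age,theta_bmi decay per year of |age difference| / per
#'   kg/m^2 of |BMI difference| (negative = homophily).
#' @param mean_out_degree target mean number of followees per user.
#' @param gamma0 reciprocation baseline logit.
#' @param gamma_age,gamma_bmi reciprocation slopes per SD of standardized
#'   absolute age / BMI difference (reference gender: woman).
#' @param gamma_gender_man additive logit for man-man dyads.
#' @param gamma_age_man,gamma_bmi_man slope modifiers for man-man dyads.
#' @param gamma_age_bmi two-way interaction of the standardized absolute
#'   differences.
#' @param gamma_3way three-way interaction (difference of the two-way term
#'   between genders).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_nodes = 2000,
                         p_man = 0.5,
                         age_range = c(15, 32),
                         age_dist = c("uniform", "skew"),
                         age_skew = list(xi = 14.2, omega = 13.6, alpha = 5),
                         age_clip = c(12, 59),
                         bmi_intercept = c(woman = 19.6, man = 23),
                         bmi_age_slope = c(woman = 0.12, man = 0.30),
                         bmi_sd = c(woman = 2.6, man = 2.3),
                         bmi_clip = c(15, 35),
                         height_mean = c(woman = 166, man = 179),
                         height_sd = c(woman = 5, man = 6),
                         theta0 = -3,
                         theta_gender = 1,
                         theta_age = -0.25,
                         theta_bmi = -0.25,
                         mean_out_degree = 8,
                         gamma0 = -0.5,
                         gamma_age = -0.19,
                         gamma_bmi = -0.08,
                         gamma_gender_man = 0,
                         gamma_age_man = 0.02,
                         gamma_bmi_man = 0.04,
                         gamma_age_bmi = 0.02,
                         gamma_3way = -0.04) {
  age_dist <- match.arg(age_dist)
  if (n_nodes < 2) stop("synth_config: n_nodes must be at least 2")
  if (age_range[1] > age_range[2]) stop("synth_config: empty age range")
  cfg <- as.list(environment())
  structure(cfg, class = "synth_config")
}

# skew-normal deviates via the delta-convolution representation
rskewnorm <- function(n, xi, omega, alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  u1 <- abs(stats::rnorm(n))
  u2 <- stats::rnorm(n)
  xi + omega * (delta * u1 + sqrt(1 - delta^2) * u2)
}

#' Generate synthetic user records
#'
#' Gender is i.i.d. Bernoulli; age follows the configured distribution;
#' BMI is a per-gender linear function of (age - mid-age) plus Gaussian
#' noise, clipped into the plausibility window. Height is drawn per gender
#' and mass back-solved from BMI so the free-text body-field path of the
#' Pokec dialect can be exercised round-trip.
#'
#' @param config a [synth_config()].
#' @param seed optional integer seed (otherwise the current RNG state is
#'   used).
#' @return user-record data.frame as produced by [parse_profiles()].
#' @export
generate_users <- function(config = synth_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_nodes
  gender <- factor(ifelse(stats::runif(n) < config$p_man, "man", "woman"),
                   levels = GENDER_LEVELS)
  age <- if (config$age_dist == "uniform") {
    sample(seq(config$age_range[1], config$age_range[2]), n, replace = TRUE)
  } else {
    a <- round(rskewnorm(n, config$age_skew$xi, config$age_skew$omega,
                         config$age_skew$alpha))
    pmin(pmax(a, config$age_clip[1]), config$age_clip[2])
  }
  mid <- mean(config$age_range)
  g <- as.character(gender)
  bmi <- config$bmi_intercept[g] + config$bmi_age_slope[g] * (age - mid) +
    stats::rnorm(n, 0, config$bmi_sd[g])
  bmi <- pmin(pmax(bmi, config$bmi_clip[1]), config$bmi_clip[2])
  height <- round(pmin(pmax(
    stats::rnorm(n, config$height_mean[g], config$height_sd[g]), 141), 199))
  mass <- round(bmi * (height / 100)^2, 1)
  data.frame(
    user_id = as.character(seq_len(n)),
    gender = gender,
    age = as.numeric(age),
    height_cm = as.numeric(height),
    mass_kg = mass,
    bmi = compute_bmi(height, mass),
    stringsAsFactors = FALSE
  )
}

#' Generate a directed edge list with trait-distance-dependent ties
#'
#' Samples ordered candidate pairs and realises each as an edge with
#' probability `plogis(theta0 + theta_gender*same_gender +
#' theta_age*|dAge| + theta_bmi*|dBMI|)`. The number of candidates is
#' calibrated from a pilot sample of pairs so the realised mean out-degree
#' is close to `mean_out_degree` without enumerating all n^2 pairs.
#'
#' @param records from [generate_users()].
#' @param config a [synth_config()].
#' @param seed optional integer seed.
#' @return data.frame(follower, followee) of unique directed edges, no
#'   self-loops.
#' @export
generate_following <- function(records, config = synth_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(records)
  tie_prob <- function(i, j) {
    same <- records$gender[i] == records$gender[j]
    stats::plogis(config$theta0 + config$theta_gender * as.numeric(same) +
                    config$theta_age * abs(records$age[i] - records$age[j]) +
                    config$theta_bmi * abs(records$bmi[i] - records$bmi[j]))
  }
  pilot_n <- min(20000L, n * (n - 1L))
  pi_ <- sample.int(n, pilot_n, replace = TRUE)
  pj <- sample.int(n, pilot_n, replace = TRUE)
  ok <- pi_ != pj
  phat <- mean(tie_prob(pi_[ok], pj[ok]))
  target_edges <- n * config$mean_out_degree
  # memory cap for near-impossible tie regimes; the realised degree then
  # simply falls short of target (a near-empty edge list, as intended)
  cap <- 500 * target_edges
  n_cand <- if (phat <= 0) cap else min(ceiling(target_edges / phat), cap)
  ci <- sample.int(n, n_cand, replace = TRUE)
  cj <- sample.int(n, n_cand, replace = TRUE)
  keep <- ci != cj
  ci <- ci[keep]; cj <- cj[keep]
  accept <- stats::runif(length(ci)) < tie_prob(ci, cj)
  ed <- data.frame(follower = records$user_id[ci[accept]],
                   followee = records$user_id[cj[accept]],
                   stringsAsFactors = FALSE)
  ed[!duplicated(paste(ed$follower, ed$followee, sep = "\r")), , drop = FALSE]
}

#' Add reciprocated edges with difference-dependent probability
#'
#' For each one-directional edge, the reverse edge is added with
#' probability `plogis(eta)` where `eta` is the full-factorial linear
#' predictor in the standardized absolute age and BMI differences and
#' gender (man-man dyads via the `_man` modifiers); standardization uses
#' the mean/SD of the one-directional edge set. Pairs already mutual are
#' left as they are. The generating coefficients and the standardization
#' are attached as attributes for recovery tests.
#'
#' @param edges from [generate_following()].
#' @param records user records.
#' @param config a [synth_config()].
#' @param seed optional integer seed.
#' @return the union edge list (original plus added reverse edges) with
#'   attributes `recip_coefficients` and `recip_standardization`.
#' @export
generate_reciprocation <- function(edges, records, config = synth_config(),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  key <- paste(edges$follower, edges$followee, sep = "\r")
  rev_key <- paste(edges$followee, edges$follower, sep = "\r")
  one_way <- !(rev_key %in% key)
  ow <- edges[one_way, , drop = FALSE]
  if (nrow(ow) == 0) return(edges)
  fi <- match(ow$follower, records$user_id)
  ti <- match(ow$followee, records$user_id)
  ada <- abs(records$age[fi] - records$age[ti])
  adb <- abs(records$bmi[fi] - records$bmi[ti])
  za <- (ada - mean(ada)) / stats::sd(ada)
  zb <- (adb - mean(adb)) / stats::sd(adb)
  man <- as.numeric(records$gender[fi] == "man" & records$gender[ti] == "man")
  eta <- config$gamma0 + config$gamma_age * za + config$gamma_bmi * zb +
    config$gamma_age_bmi * za * zb +
    man * (config$gamma_gender_man + config$gamma_age_man * za +
             config$gamma_bmi_man * zb + config$gamma_3way * za * zb)
  add <- stats::runif(nrow(ow)) < stats::plogis(eta)
  out <- rbind(edges,
               data.frame(follower = ow$followee[add],
                          followee = ow$follower[add],
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  attr(out, "recip_coefficients") <- list(
    gamma0 = config$gamma0, gamma_age = config$gamma_age,
    gamma_bmi = config$gamma_bmi, gamma_gender_man = config$gamma_gender_man,
    gamma_age_man = config$gamma_age_man, gamma_bmi_man = config$gamma_bmi_man,
    gamma_age_bmi = config$gamma_age_bmi, gamma_3way = config$gamma_3way)
  attr(out, "recip_standardization") <- data.frame(
    column = c("abs_age_diff", "abs_bmi_diff"),
    mean = c(mean(ada), mean(adb)), sd = c(stats::sd(ada), stats::sd(adb)))
  out
}

#' Generate a full synthetic network
#'
#' Convenience chain: users, trait-dependent following, difference-
#' dependent reciprocation, network construction.
#'
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @return list(records, edges, network).
#' @export
generate_network <- function(config = synth_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  records <- generate_users(config)
  edges <- generate_following(records, config)
  edges <- generate_reciprocation(edges, records, config)
  list(records = records, edges = edges,
       network = build_network(records, edges, quiet = TRUE))
}

#' Write a synthetic fixture to disk
#'
#' Emits the profile and relationship files either in the Pokec snapshot
#' dialect (tab-separated, no header, body rendered as
#' `"<height> cm, <mass> kg"` so the free-text extraction path is
#' exercised) or as generic TSV with a header. Round-trips through
#' [parse_profiles()] / [parse_edges()] without loss of the modeled
#' fields.
#'
#' @param records user records.
#' @param edges edge list.
#' @param directory destination directory (created if needed).
#' @param dialect `"pokec"` or `"generic"`.
#' @return named character vector of the files written.
#' @export
write_fixture <- function(records, edges, directory,
                          dialect = c("pokec", "generic")) {
  dialect <- match.arg(dialect)
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("write_fixture: cannot create directory ", directory)
  if (dialect == "pokec") {
    prof <- file.path(directory, "synthetic-pokec-profiles.txt")
    rel <- file.path(directory, "synthetic-pokec-relationships.txt")
    body <- ifelse(is.na(records$height_cm) | is.na(records$mass_kg), "",
                   paste0(records$height_cm, " cm, ", records$mass_kg, " kg"))
    gflag <- ifelse(is.na(records$gender), "null",
                    ifelse(records$gender == "man", "1", "0"))
    age <- ifelse(is.na(records$age), "0", format(records$age, trim = TRUE))
    # columns: user_id, public, completion%, gender, region, last_login,
    # registration, age, body — the positions the parser reads
    rows <- paste(records$user_id, "1", "100", gflag, "synthetic-region",
                  "2012-01-01", "2010-01-01", age, body, sep = "\t")
    writeLines(rows, prof)
    writeLines(paste(edges$follower, edges$followee, sep = "\t"), rel)
  } else {
    prof <- file.path(directory, "synthetic-profiles.tsv")
    rel <- file.path(directory, "synthetic-edges.tsv")
    utils::write.table(
      records[, c("user_id", "gender", "age", "height_cm", "mass_kg")],
      prof, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    utils::write.table(edges[, c("follower", "followee")], rel, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  }
  c(profiles = prof, relationships = rel)
}

#' Simulate dyad tables with known model coefficients
#'
#' Direct dyad-level simulators for parameter-recovery testing of the
#' similarity and reciprocity models, bypassing network generation so the
#' generating coefficients are exactly the quantities the models estimate.
#'
#' `simulate_similarity_dyads` draws follower traits, assigns each
#' follower several followees, and sets the followee trait to
#' `slope * follower trait` (on the standardized scale) plus a follower
#' random intercept and residual noise scaled so the outcome has unit
#' variance — the standardized slope recovered by
#' [fit_trait_similarity_model()] is then `slope`.
#'
#' @param n_dyads number of dyad rows.
#' @param n_followers number of distinct followers.
#' @param slope standardized follower-trait slope.
#' @param sd_intercept SD of the follower random intercept (standardized
#'   outcome scale).
#' @param trait `"age"` or `"bmi"` (controls column naming).
#' @param p_man share of man-man dyads.
#' @param seed optional integer seed.
#' @return dyad table suitable for the corresponding fitting function.
#' @export
simulate_similarity_dyads <- function(n_dyads = 20000, n_followers = 2000,
                                      slope = 0.6, sd_intercept = 0.3,
                                      trait = c("age", "bmi"), p_man = 0.5,
                                      seed = NULL) {
  trait <- match.arg(trait)
  if (!is.null(seed)) set.seed(seed)
  if (slope^2 + sd_intercept^2 >= 1)
    stop("simulate_similarity_dyads: slope^2 + sd_intercept^2 must be < 1 ",
         "for a unit-variance outcome")
  fid <- sample.int(n_followers, n_dyads, replace = TRUE)
  gender_f <- factor(ifelse(stats::runif(n_followers) < p_man, "man", "woman"),
                     levels = GENDER_LEVELS)
  z_follower <- stats::rnorm(n_followers)[fid]
  b <- stats::rnorm(n_followers, 0, sd_intercept)[fid]
  sd_resid <- sqrt(1 - slope^2 - sd_intercept^2)
  z_followee <- slope * z_follower + b + stats::rnorm(n_dyads, 0, sd_resid)
  # map to a plausible raw scale; slope is scale-invariant
  raw <- function(z) if (trait == "age") 24 + 5 * z else 21 + 2.5 * z
  d <- data.frame(
    follower_id = as.character(fid),
    followee_id = as.character(n_followers + seq_len(n_dyads)),
    dyad_gender = gender_f[fid],
    stringsAsFactors = FALSE
  )
  d[[paste0("follower_", trait)]] <- raw(z_follower)
  d[[paste0("followee_", trait)]] <- raw(z_followee)
  other <- if (trait == "age") "bmi_diff" else "age_diff"
  d[[other]] <- stats::rnorm(n_dyads)
  d$reciprocal <- TRUE
  d
}

#' @rdname simulate_similarity_dyads
#'
#' @details `simulate_reciprocity_dyads` draws absolute age and BMI
#' differences, standardizes them within the sample, and draws the
#' reciprocity outcome from a Bernoulli with logit equal to the
#' full-factorial predictor plus a follower random intercept; the
#' coefficients recovered by [fit_reciprocity_model()] estimate `coefs`.
#'
#' @param coefs named list of generating coefficients on the standardized
#'   scale: intercept, age, bmi, gender_man, age_bmi, age_man, bmi_man,
#'   threeway (absent entries are 0).
#' @export
simulate_reciprocity_dyads <- function(n_dyads = 20000, n_followers = 2000,
                                       coefs = list(intercept = -0.5,
                                                    age = -0.19, bmi = -0.4),
                                       sd_intercept = 0.5, p_man = 0.5,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cf <- function(nm) coefs[[nm]] %||% 0
  fid <- sample.int(n_followers, n_dyads, replace = TRUE)
  gender_f <- factor(ifelse(stats::runif(n_followers) < p_man, "man", "woman"),
                     levels = GENDER_LEVELS)
  g <- gender_f[fid]
  man <- as.numeric(g == "man")
  ada <- abs(stats::rnorm(n_dyads, 0, 4))
  adb <- abs(stats::rnorm(n_dyads, 0, 3))
  za <- (ada - mean(ada)) / stats::sd(ada)
  zb <- (adb - mean(adb)) / stats::sd(adb)
  b <- stats::rnorm(n_followers, 0, sd_intercept)[fid]
  eta <- cf("intercept") + cf("age") * za + cf("bmi") * zb +
    cf("gender_man") * man + cf("age_bmi") * za * zb +
    cf("age_man") * za * man + cf("bmi_man") * zb * man +
    cf("threeway") * za * zb * man + b
  data.frame(
    follower_id = as.character(fid),
    followee_id = as.character(n_followers + seq_len(n_dyads)),
    dyad_gender = g,
    abs_age_diff = ada,
    abs_bmi_diff = adb,
    reciprocal = stats::runif(n_dyads) < stats::plogis(eta),
    stringsAsFactors = FALSE
  )
}
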