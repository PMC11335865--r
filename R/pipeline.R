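# End-to-end orchestration: clean -> sample -> subnetworks -> descriptives
# -> assortativity (full + conditioned) -> null ensembles -> dyad tables ->
# models -> slopes -> contrasts, with a machine-readable report.

#' Analysis configuration
#'
#' Collects every knob of the full pipeline. Inputs may be file paths
#' (`profiles`, `relationships`) or in-memory tables (`records`, `edges`).
#'
#' @param profiles path to the profile file (or `NULL` when `records` is
#'   given).
#' @param relationships path to the edge-list file (or `NULL` when `edges`
#'   is given).
#' @param records,edges in-memory alternatives to the file inputs.
#' @param dialect `"pokec"` or `"generic"`.
#' @param cleaning a [cleaning_config()].
#' @param age_bin_width,bmi_bin_width conditioning bin widths.
#' @param min_edges minimum edges for a defined assortativity bin.
#' @param n_reps null-ensemble replicates (default 100).
#' @param ci_method null-ensemble interval type.
#' @param seed top-level seed; every stochastic stage draws its own seed
#'   deterministically from it.
#' @param reciprocity_random_intercept random intercept in the reciprocity
#'   model (a plain logistic fit when `FALSE`).
#' @param dedupe_reciprocal one row per reciprocal pair instead of two.
#' @param contrast_bmi_diff,contrast_age_diff raw-scale contrast settings.
#' @param out optional output directory for `report.json` and `tables/`.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(profiles = NULL, relationships = NULL,
                            records = NULL, edges = NULL,
                            dialect = c("generic", "pokec"),
                            cleaning = cleaning_config(),
                            age_bin_width = 3, bmi_bin_width = 2,
                            min_edges = 10L,
                            n_reps = 100L,
                            ci_method = c("normal_mean", "percentile"),
                            seed = 1L,
                            reciprocity_random_intercept = TRUE,
                            dedupe_reciprocal = FALSE,
                            contrast_bmi_diff = c(0, 10),
                            contrast_age_diff = 0,
                            out = NULL) {
  dialect <- match.arg(dialect)
  ci_method <- match.arg(ci_method)
  if (is.null(profiles) && is.null(records))
    stop("analysis_config: supply 'profiles' or 'records'")
  if (is.null(relationships) && is.null(edges))
    stop("analysis_config: supply 'relationships' or 'edges'")
  structure(as.list(environment()), class = "analysis_config")
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment; values that look
#' numeric are coerced; `true`/`false` become logical; two-number values
#' may be written `lo,hi`. Keys mirror the arguments of
#' [analysis_config()] (cleaning bounds as e.g. `age_plausible = 12,59`).
#'
#' @param path configuration file path.
#' @return an `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- quiet_num(parts)
    kv[[key]] <- if (!anyNA(num)) num
      else if (length(parts) == 1 && tolower(parts) %in% c("true", "false"))
        tolower(parts) == "true"
      else val
  }
  clean_keys <- intersect(names(kv), names(formals(cleaning_config)))
  cleaning <- do.call(cleaning_config, kv[clean_keys])
  kv <- kv[setdiff(names(kv), clean_keys)]
  kv <- kv[names(kv) %in% names(formals(analysis_config))]
  kv$cleaning <- cleaning
  do.call(analysis_config, kv)
}

log_stage <- function(...) message("[sociomix] ", ...)

#' Run the full homophily analysis
#'
#' Executes the whole chain on one dataset and returns (and optionally
#' writes) a structured report: cleaning summary, gender descriptives,
#' plain and interval-conditioned assortativity per gender, degree-class
#' shuffle null ensembles for the four (gender, attribute) combinations,
#' the two trait-similarity mixed models and the reciprocity model with
#' per-gender slopes and the predicted-probability BMI contrast.
#' Deterministic given the config and its seed: all stage seeds are drawn
#' once from the top-level seed. Model non-convergence is flagged in the
#' report rather than raised; missing inputs or an invalid config fail
#' before any computation.
#'
#' @param config an [analysis_config()] (or path to a flat key = value
#'   file).
#' @param dry_run validate the config and log the planned stages without
#'   computing.
#' @param quiet suppress stage logging.
#' @return list of class `analysis_report` (see the elements named in the
#'   description), with provenance (seed, config echo, input checksums,
#'   timestamp).
#' @export
run_full_analysis <- function(config, dry_run = FALSE, quiet = FALSE) {
  if (is.character(config)) config <- read_analysis_config(config)
  stopifnot(inherits(config, "analysis_config"))
  say <- if (quiet) function(...) invisible() else log_stage
  for (f in c(config$profiles, config$relationships))
    if (!is.null(f) && !file.exists(f))
      stop("run_full_analysis: input file not found: ", f)
  stages <- c("clean", "sample", "descriptives", "assortativity",
              "null ensembles", "dyad tables", "models", "contrasts")
  if (dry_run) {
    say("dry run; planned stages: ", paste(stages, collapse = " -> "))
    return(invisible(stages))
  }
  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 8L)

  say("clean: parsing inputs")
  records <- config$records %||%
    parse_profiles(config$profiles, dialect = config$dialect)
  edges <- if (!is.null(config$edges)) parse_edges(config$edges)
           else parse_edges(config$relationships)
  filt <- apply_plausibility_filters(records, config$cleaning)
  say("clean: ", filt$report$n_total, " users, ",
      round(filt$report$pct_complete, 1), "% complete")

  sample_rec <- select_analysis_sample(filt$records, config$cleaning)
  say("sample: ", nrow(sample_rec), " users in the age window")
  network <- build_network(sample_rec, edges, quiet = TRUE)
  say("network: ", n_edges(network), " edges (",
      network$n_dropped_edges, " dropped)")

  complete_age <- filt$records[!is.na(filt$records$age), , drop = FALSE]
  descriptives <- gender_descriptives(
    sample_rec, full_age_records = complete_age,
    age_window = config$cleaning$analysis_age_window)

  say("assortativity: full and conditioned, per gender")
  win <- config$cleaning$analysis_age_window
  age_bins <- default_bins("age", config$age_bin_width, win)
  bmi_bins <- default_bins("bmi", config$bmi_bin_width,
                           config$cleaning$bmi_plausible)
  assort <- list()
  subnets <- list()
  for (gd in GENDER_LEVELS) {
    sub <- same_gender_subnetwork(network, gd)
    subnets[[gd]] <- sub
    assort[[gd]] <- list(
      n_edges = n_edges(sub),
      age_full = numeric_assortativity(sub, "age"),
      bmi_full = numeric_assortativity(sub, "bmi"),
      age_by_bmi = conditioned_assortativity(sub, "age", "bmi", bmi_bins,
                                             config$min_edges),
      bmi_by_age = conditioned_assortativity(sub, "bmi", "age", age_bins,
                                             config$min_edges))
  }

  say("null ensembles: ", config$n_reps, " degree-class shuffles each")
  nulls <- list()
  k <- 0
  for (gd in GENDER_LEVELS) {
    for (at in c("age", "bmi")) {
      k <- k + 1
      nulls[[paste(gd, at, sep = "_")]] <- null_ensemble(
        network, same_gender_assortativity_stat(gd, at),
        n_reps = config$n_reps, seed = stage_seeds[k],
        ci_method = config$ci_method)
    }
  }

  say("dyad tables and models")
  dyads_all <- build_dyad_table(network, reciprocal_only = FALSE,
                                dedupe_reciprocal = config$dedupe_reciprocal)
  dyads_recip <- dyads_all[dyads_all$reciprocal, , drop = FALSE]
  fits <- list(); slopes <- list(); contrasts <- list()
  enough <- function(d) nrow(d) >= 50 && length(unique(d$dyad_gender)) == 2
  if (enough(dyads_recip)) {
    fits$age_similarity <- fit_trait_similarity_model(dyads_recip, "age")
    fits$bmi_similarity <- fit_trait_similarity_model(dyads_recip, "bmi")
    slopes$age_similarity <- gender_slopes(fits$age_similarity)
    slopes$bmi_similarity <- gender_slopes(fits$bmi_similarity)
  } else {
    say("models 1-2 skipped: too few reciprocal dyads")
  }
  if (enough(dyads_all)) {
    fits$reciprocity <- fit_reciprocity_model(
      dyads_all, random_intercept = config$reciprocity_random_intercept)
    slopes$reciprocity <- gender_slopes(fits$reciprocity)
    for (gd in GENDER_LEVELS) {
      contrasts[[gd]] <- reciprocity_contrast(
        fits$reciprocity, gd, bmi_diff_raw = config$contrast_bmi_diff,
        age_diff_raw = config$contrast_age_diff)
    }
  } else {
    say("model 3 skipped: too few dyads")
  }

  checksum <- function(p) if (is.null(p)) NA_character_ else
    unname(tools::md5sum(p))
  report <- structure(list(
    cleaning = filt$report,
    descriptives = descriptives,
    assortativity = assort,
    nulls = nulls,
    model_fits = fits,
    slopes = slopes,
    contrasts = contrasts,
    provenance = list(
      seed = config$seed,
      stage_seeds = stage_seeds,
      n_reps = config$n_reps,
      ci_method = config$ci_method,
      input_md5 = list(profiles = checksum(config$profiles),
                       relationships = checksum(config$relationships)),
      timestamp = format(Sys.time(), tz = "UTC"))
  ), class = "analysis_report")
  if (!is.null(config$out)) write_report(report, config$out)
  report
}

# strip non-serialisable / volatile parts for JSON output and comparisons
report_body <- function(report) {
  body <- unclass(report)
  body$provenance$timestamp <- NULL
  body$model_fits <- lapply(body$model_fits, function(f) {
    f <- unclass(f)
    f$model <- NULL
    f
  })
  body$nulls <- lapply(body$nulls, unclass)
  body$cleaning <- unclass(body$cleaning)
  body$descriptives <- unclass(body$descriptives)
  body
}

#' Write an analysis report to disk
#'
#' `report.json` holds the full report (minus fitted model objects and the
#' timestamp); `tables/` holds the assortativity and null-summary TSVs.
#'
#' @param report an `analysis_report`.
#' @param directory destination directory.
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, directory) {
  dir.create(file.path(directory, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  json_path <- file.path(directory, "report.json")
  jsonlite::write_json(report_body(report), json_path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  tsv <- function(df, name) {
    p <- file.path(directory, "tables", name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  cond <- do.call(rbind, lapply(GENDER_LEVELS, function(gd) {
    a <- report$assortativity[[gd]]
    rbind(cbind(gender = gd, conditioning = "bmi", a$age_by_bmi),
          cbind(gender = gd, conditioning = "age", a$bmi_by_age))
  }))
  full <- do.call(rbind, lapply(GENDER_LEVELS, function(gd) {
    a <- report$assortativity[[gd]]
    data.frame(gender = gd, attribute = c("age", "bmi"),
               n_edges = a$n_edges, r = c(a$age_full, a$bmi_full))
  }))
  nulls <- do.call(rbind, lapply(names(report$nulls), function(nm) {
    e <- report$nulls[[nm]]
    data.frame(statistic = nm, observed = e$observed, mean_null = e$mean_null,
               ci_low = e$ci_low, ci_high = e$ci_high,
               significant = e$significant, n_reps = e$n_reps)
  }))
  paths <- c(json_path,
             tsv(full, "assortativity_full.tsv"),
             tsv(cond, "assortativity_conditioned.tsv"),
             tsv(nulls, "null_ensembles.tsv"))
  invisible(paths)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat("  users:", x$cleaning$n_total, "| complete:",
      sprintf("%.1f%%", x$cleaning$pct_complete), "\n")
  for (gd in GENDER_LEVELS) {
    a <- x$assortativity[[gd]]
    cat(sprintf("  %s: r_age = %.3f, r_bmi = %.3f (%d edges)\n",
                gd, a$age_full, a$bmi_full, a$n_edges))
  }
  for (nm in names(x$nulls)) {
    e <- x$nulls[[nm]]
    cat(sprintf("  null %s: mean %.3f [%.3f, %.3f]%s\n", nm, e$mean_null,
                e$ci_low, e$ci_high,
                if (e$significant) " (observed differs)" else ""))
  }
  for (nm in names(x$slopes)) {
    s <- x$slopes[[nm]]
    cat(sprintf("  %s slopes: women %.3f, men %.3f (interaction p = %.3g)\n",
                nm, s$beta_women, s$beta_men, s$interaction_p))
  }
  for (nm in names(x$contrasts)) {
    ct <- x$contrasts[[nm]]
    cat(sprintf("  reciprocity contrast (%s): %.3f -> %.3f (%.1f pp)\n",
                nm, ct$p_at_start, ct$p_at_end, ct$abs_change_pp))
  }
  invisible(x)
}
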