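# Profile parsing, plausibility filtering, and directed-network construction.

#' Cleaning configuration
#'
#' Plausibility bounds applied to self-reported attributes and the age
#' window defining the analysis sample. All intervals are closed: values
#' strictly outside an interval are set missing, boundary values are kept.
#'
#' @param age_plausible kept range for age in years.
#' @param height_plausible_cm kept range for height in centimeters.
#' @param mass_plausible_kg kept range for body mass in kilograms.
#' @param bmi_plausible kept range for BMI in kg/m^2 (applied after BMI is
#'   recomputed from the surviving height and mass).
#' @param analysis_age_window closed age interval selecting the young-adult
#'   analysis sample.
#' @return a list of class `cleaning_config`.
#' @export
cleaning_config <- function(age_plausible = c(12, 59),
                            height_plausible_cm = c(140, 200),
                            mass_plausible_kg = c(10, 200),
                            bmi_plausible = c(15, 35),
                            analysis_age_window = c(15, 32)) {
  cfg <- list(
    age_plausible = age_plausible,
    height_plausible_cm = height_plausible_cm,
    mass_plausible_kg = mass_plausible_kg,
    bmi_plausible = bmi_plausible,
    analysis_age_window = analysis_age_window
  )
  for (nm in names(cfg)) {
    iv <- cfg[[nm]]
    if (length(iv) != 2L || anyNA(iv) || iv[1] > iv[2])
      stop("cleaning_config: '", nm, "' must be a valid interval lo <= hi")
  }
  structure(cfg, class = "cleaning_config")
}

#' Extract height and mass from a free-text body description
#'
#' Height is the first number immediately followed by an optional space and
#' "cm"; mass is the first number followed by an optional space and "kg".
#' Decimal commas are accepted as decimal points. A pattern that does not
#' occur yields a missing value; the function never errors.
#'
#' @param text character vector of body descriptions.
#' @return data.frame with numeric columns `height_cm` and `mass_kg`.
#' @examples
#' parse_body_field("163cm, 49kg")
#' parse_body_field("55,5 kg 170cm")
#' @export
parse_body_field <- function(text) {
  text <- as.character(text)
  grab <- function(unit) {
    pat <- paste0("([0-9]+(?:[.,][0-9]+)?) ?", unit, "\\b")
    m <- regexpr(pat, text, perl = TRUE, ignore.case = TRUE)
    val <- rep(NA_character_, length(text))
    hit <- m > 0 & !is.na(text)
    val[hit] <- regmatches(text, m)[seq_len(sum(hit))]
    # keep only the numeric part, normalise decimal comma
    num <- sub(paste0(" ?", unit, "\\b.*$"), "", val, ignore.case = TRUE)
    quiet_num(gsub(",", ".", num, fixed = TRUE))
  }
  data.frame(height_cm = grab("cm"), mass_kg = grab("kg"))
}

#' Body mass index from height and mass
#'
#' @param height_cm height in centimeters.
#' @param mass_kg mass in kilograms.
#' @return BMI in kg/m^2; missing where either input is missing or
#'   non-positive.
#' @export
compute_bmi <- function(height_cm, mass_kg) {
  bmi <- mass_kg / (height_cm / 100)^2
  bmi[!is.na(height_cm) & height_cm <= 0] <- NA_real_
  bmi[!is.na(mass_kg) & mass_kg <= 0] <- NA_real_
  bmi
}

# Pokec profile dump: tab-separated, no header. The columns used are
# 1 user_id, 4 gender flag, 8 age (0 = unset), 9 free-text body field.
POKEC_MIN_COLS <- 9L

#' Parse a user-profile table
#'
#' Reads either the Pokec snapshot dialect (tab-separated, no header, fixed
#' column order with a free-text body field from which height and mass are
#' extracted) or a generic delimited table with a header row naming id,
#' gender, age, height, and mass columns. Unparseable fields become missing
#' values, never errors, so the row count is always preserved.
#'
#' @param file path to the profile file, or a character vector of lines.
#' @param dialect `"pokec"` or `"generic"`.
#' @param gender_map named character vector mapping the Pokec raw gender
#'   flag to labels; the default reads flag 1 as "man" and 0 as "woman",
#'   and is configurable because the snapshot does not document the coding.
#' @param sep field separator for the generic dialect (`"\t"` or `","`;
#'   guessed from the header line when `NULL`).
#' @return data.frame of user records with columns `user_id`, `gender`,
#'   `age`, `height_cm`, `mass_kg`, `bmi` (BMI is derived, one row per
#'   input row).
#' @export
parse_profiles <- function(file, dialect = c("generic", "pokec"),
                           gender_map = c("1" = "man", "0" = "woman"),
                           sep = NULL) {
  dialect <- match.arg(dialect)
  lines <- if (length(file) == 1L && file.exists(file)) {
    readLines(file, warn = FALSE, encoding = "UTF-8")
  } else {
    as.character(file)
  }
  lines <- lines[nzchar(lines)]
  if (dialect == "pokec") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    head_n <- utils::head(fields, 100L)
    bad <- vapply(head_n, function(f) length(f) < POKEC_MIN_COLS, logical(1))
    if (length(bad) && mean(bad) > 0.5) {
      stop("parse_profiles: stream does not look like the pokec dialect ",
           "(fewer than ", POKEC_MIN_COLS, " tab-separated columns in most ",
           "of the first rows; first offending line: ",
           which(bad)[1], ")")
    }
    get_col <- function(i) vapply(fields, function(f)
      if (length(f) >= i) f[[i]] else NA_character_, character(1))
    raw_gender <- get_col(4L)
    gender <- factor(unname(gender_map[raw_gender]), levels = GENDER_LEVELS)
    age <- quiet_num(get_col(8L))
    age[!is.na(age) & age == 0] <- NA_real_  # 0 encodes "not set"
    body <- parse_body_field(get_col(9L))
    rec <- data.frame(
      user_id = get_col(1L),
      gender = gender,
      age = age,
      height_cm = body$height_cm,
      mass_kg = body$mass_kg,
      stringsAsFactors = FALSE
    )
  } else {
    if (is.null(sep)) sep <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
    tab <- utils::read.table(text = lines, sep = sep, header = TRUE,
                             colClasses = "character", quote = "",
                             comment.char = "", check.names = FALSE)
    find_col <- function(cands) {
      hit <- match(cands, tolower(names(tab)))
      hit <- hit[!is.na(hit)]
      if (!length(hit)) stop("parse_profiles: no column matching any of: ",
                             paste(cands, collapse = ", "))
      hit[1]
    }
    rec <- data.frame(
      user_id = tab[[find_col(c("user_id", "id"))]],
      gender = normalize_gender(tab[[find_col(c("gender", "sex"))]]),
      age = quiet_num(tab[[find_col(c("age"))]]),
      height_cm = quiet_num(tab[[find_col(c("height_cm", "height"))]]),
      mass_kg = quiet_num(tab[[find_col(c("mass_kg", "mass", "weight"))]]),
      stringsAsFactors = FALSE
    )
  }
  rec$bmi <- compute_bmi(rec$height_cm, rec$mass_kg)
  rec
}

#' Parse a directed edge list
#'
#' Two tab-separated columns, follower then followee, no header (the Pokec
#' relationship format). Also accepts a two-column data.frame or matrix.
#'
#' @param file path, character vector of lines, or two-column table.
#' @return data.frame with character columns `follower` and `followee`.
#' @export
parse_edges <- function(file) {
  if (is.data.frame(file) || is.matrix(file)) {
    ed <- as.data.frame(file, stringsAsFactors = FALSE)[, 1:2]
  } else {
    lines <- if (length(file) == 1L && file.exists(file)) {
      readLines(file, warn = FALSE)
    } else as.character(file)
    lines <- lines[nzchar(lines)]
    if (length(lines) && grepl("^follower[\t ]+followee$", lines[1],
                               ignore.case = TRUE))
      lines <- lines[-1]  # optional header row
    parts <- strsplit(lines, "[\t ]+")
    ed <- data.frame(
      follower = vapply(parts, `[`, character(1), 1L),
      followee = vapply(parts, `[`, character(1), 2L),
      stringsAsFactors = FALSE
    )
  }
  names(ed) <- c("follower", "followee")
  ed$follower <- as.character(ed$follower)
  ed$followee <- as.character(ed$followee)
  ed
}

#' Apply plausibility filters to parsed records
#'
#' Sets age, height, and mass outside their plausible closed intervals to
#' missing, recomputes BMI from the surviving height and mass only, then
#' sets implausible BMI missing as well. The cleaning report is computed on
#' the full node set. Filtering is idempotent.
#'
#' @param records data.frame from [parse_profiles()].
#' @param config a [cleaning_config()].
#' @return list with elements `records` (filtered data.frame) and `report`
#'   (a `cleaning_report` list: n_total, percent missing per attribute,
#'   n/percent complete, n/percent of complete users in the age window).
#' @export
apply_plausibility_filters <- function(records, config = cleaning_config()) {
  stopifnot(inherits(config, "cleaning_config"))
  out_of <- function(x, iv) !is.na(x) & (x < iv[1] | x > iv[2])
  records$age[out_of(records$age, config$age_plausible)] <- NA_real_
  records$height_cm[out_of(records$height_cm, config$height_plausible_cm)] <- NA_real_
  records$mass_kg[out_of(records$mass_kg, config$mass_plausible_kg)] <- NA_real_
  records$bmi <- compute_bmi(records$height_cm, records$mass_kg)
  records$bmi[out_of(records$bmi, config$bmi_plausible)] <- NA_real_
  list(records = records, report = cleaning_report(records, config))
}

#' Summarise missingness after filtering
#'
#' @param records filtered records.
#' @param config a [cleaning_config()] (for the age window).
#' @return a `cleaning_report` list.
#' @export
cleaning_report <- function(records, config = cleaning_config()) {
  n <- nrow(records)
  pct <- function(k) if (n == 0) 0 else 100 * k / n
  complete <- !is.na(records$gender) & !is.na(records$age) & !is.na(records$bmi)
  win <- config$analysis_age_window
  in_win <- complete & records$age >= win[1] & records$age <= win[2]
  structure(list(
    n_total = n,
    pct_missing_gender = pct(sum(is.na(records$gender))),
    pct_missing_age = pct(sum(is.na(records$age))),
    pct_missing_bmi = pct(sum(is.na(records$bmi))),
    n_complete = sum(complete),
    pct_complete = pct(sum(complete)),
    n_in_age_window = sum(in_win),
    pct_in_age_window = if (sum(complete) == 0) 0 else
      100 * sum(in_win) / sum(complete)
  ), class = "cleaning_report")
}

#' Select the analysis sample
#'
#' Keeps records with known gender, age, and BMI whose age lies inside the
#' closed analysis window.
#'
#' @inheritParams apply_plausibility_filters
#' @return filtered data.frame (warns if empty).
#' @export
select_analysis_sample <- function(records, config = cleaning_config()) {
  win <- config$analysis_age_window
  keep <- !is.na(records$gender) & !is.na(records$age) & !is.na(records$bmi) &
    records$age >= win[1] & records$age <= win[2]
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) warning("select_analysis_sample: empty analysis sample")
  out
}

# internal constructor: assumes edges already reference existing nodes and
# contain no self-loops or duplicates
new_social_network <- function(nodes, edges, n_dropped = 0L) {
  from <- match(edges$follower, nodes$user_id)
  to <- match(edges$followee, nodes$user_id)
  key <- paste(from, to)
  rev_key <- paste(to, from)
  reciprocal <- rev_key %in% key
  nodes$in_degree <- tabulate(to, nbins = nrow(nodes))
  nodes$out_degree <- tabulate(from, nbins = nrow(nodes))
  structure(list(
    nodes = nodes,
    edges = data.frame(follower = edges$follower, followee = edges$followee,
                       from = from, to = to, reciprocal = reciprocal,
                       stringsAsFactors = FALSE),
    n_dropped_edges = n_dropped
  ), class = "social_network")
}

#' Build a directed network from records and an edge list
#'
#' Keeps exactly the supplied nodes and the edges whose both endpoints are
#' among them; self-loops and duplicate ordered pairs are removed, edges
#' referencing unknown ids are dropped and counted. Per-node in/out degrees
#' and per-edge reciprocity flags are computed.
#'
#' @param records node table (typically the analysis sample).
#' @param edges edge list from [parse_edges()] (or any two-column table).
#' @param quiet suppress the dropped-edge message.
#' @return an object of class `social_network`: list with `nodes` (records
#'   plus `in_degree`, `out_degree`), `edges` (follower, followee, node
#'   indices, reciprocal flag), and `n_dropped_edges`.
#' @export
build_network <- function(records, edges, quiet = FALSE) {
  stopifnot(nrow(records) == length(unique(records$user_id)))
  edges <- parse_edges(edges)
  n_raw <- nrow(edges)
  known <- edges$follower %in% records$user_id & edges$followee %in% records$user_id
  edges <- edges[known & edges$follower != edges$followee, , drop = FALSE]
  edges <- edges[!duplicated(paste(edges$follower, edges$followee, sep = "\r")), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  dropped <- n_raw - nrow(edges)
  if (!quiet && dropped > 0)
    message("build_network: dropped ", dropped,
            " edge(s) (self-loop, duplicate, or unknown endpoint)")
  new_social_network(records, edges, n_dropped = dropped)
}

#' @export
print.social_network <- function(x, ...) {
  cat("<social_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " directed edges (", sum(x$edges$reciprocal), " in reciprocal pairs)\n",
      sep = "")
  invisible(x)
}

#' Number of nodes / edges of a network
#' @param network a `social_network`.
#' @return integer count.
#' @export
n_nodes <- function(network) nrow(network$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(network) nrow(network$edges)

#' Reciprocal unordered pairs of a network
#'
#' @param network a `social_network`.
#' @return data.frame of unordered id pairs each following the other.
#' @export
reciprocal_pairs <- function(network) {
  e <- network$edges[network$edges$reciprocal, , drop = FALSE]
  if (nrow(e) == 0)
    return(data.frame(id_a = character(), id_b = character()))
  a <- pmin(e$follower, e$followee)
  b <- pmax(e$follower, e$followee)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  data.frame(id_a = a[keep], id_b = b[keep], stringsAsFactors = FALSE)
}

# induced subnetwork on a logical/integer node index
induce_subnetwork <- function(network, keep) {
  nodes <- network$nodes[keep, , drop = FALSE]
  rownames(nodes) <- NULL
  e <- network$edges
  ke <- e$follower %in% nodes$user_id & e$followee %in% nodes$user_id
  new_social_network(nodes[, setdiff(names(nodes), c("in_degree", "out_degree")),
                           drop = FALSE],
                     e[ke, c("follower", "followee"), drop = FALSE])
}

#' Same-gender subnetwork
#'
#' Restricts the network to nodes of one gender and the ties among them;
#' mixed-gender ties are absent from both subnetworks. Degrees are
#' recomputed on the subnetwork.
#'
#' @param network a `social_network`.
#' @param gender `"woman"` or `"man"`.
#' @return a `social_network`.
#' @export
same_gender_subnetwork <- function(network, gender = c("woman", "man")) {
  gender <- match.arg(gender)
  induce_subnetwork(network, !is.na(network$nodes$gender) &
                      network$nodes$gender == gender)
}

#' Subnetwork of nodes inside an attribute interval
#'
#' @param network a `social_network`.
#' @param attr `"age"` or `"bmi"`.
#' @param lo,hi closed interval bounds (`lo <= hi`).
#' @param right_closed if `FALSE`, the upper bound is exclusive (used for
#'   all but the last bin when conditioning on consecutive intervals).
#' @return induced `social_network`.
#' @export
attribute_interval_subnetwork <- function(network, attr = c("age", "bmi"),
                                          lo, hi, right_closed = TRUE) {
  attr <- match.arg(attr)
  if (lo > hi) stop("attribute_interval_subnetwork: lo > hi")
  v <- network$nodes[[attr]]
  keep <- !is.na(v) & v >= lo & (if (right_closed) v <= hi else v < hi)
  induce_subnetwork(network, keep)
}

#' Write the cleaned node table and cleaning report
#'
#' @param records cleaned node table.
#' @param report a `cleaning_report`.
#' @param node_path TSV destination for the node table.
#' @param report_path JSON destination for the report (optional).
#' @return invisibly, the paths written.
#' @export
write_clean_nodes <- function(records, report = NULL, node_path,
                              report_path = NULL) {
  utils::write.table(
    records[, c("user_id", "gender", "age", "height_cm", "mass_kg", "bmi")],
    node_path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  if (!is.null(report) && !is.null(report_path)) {
    jsonlite::write_json(unclass(report), report_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(c(node_path, report_path))
}
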