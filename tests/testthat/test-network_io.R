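test_that("parse_body_field extracts height and mass with flexible spacing and decimal commas", {
  out <- parse_body_field(c("163cm, 49kg", "vyska 180 cm", "55,5 kg 170cm",
                            "", NA, "just text"))
  expect_equal(out$height_cm, c(163, 180, 170, NA, NA, NA))
  expect_equal(out$mass_kg, c(49, NA, 55.5, NA, NA, NA))
})

test_that("compute_bmi follows mass/(height/100)^2 and propagates missing", {
  expect_equal(compute_bmi(200, 100), 25)
  expect_equal(compute_bmi(160, 51.2), 20)
  expect_true(is.na(compute_bmi(NA, 70)))
  expect_true(is.na(compute_bmi(170, NA)))
  expect_true(is.na(compute_bmi(0, 70)))
  expect_true(is.na(compute_bmi(-170, 70)))
})

test_that("generic dialect maps header columns and keeps unparseable fields as missing", {
  lines <- c("id\tgender\tage\theight\tmass",
             "7\twoman\t25\t165\t55",
             "8\tman\tabc\t180\t80",    # malformed age
             "9\twoman\t30\t\t60",      # empty height
             "10\tother\t22\t170\txx")  # unknown gender, malformed mass
  rec <- parse_profiles(lines, dialect = "generic")
  expect_equal(nrow(rec), 4)
  expect_equal(rec$age, c(25, NA, 30, 22))
  expect_equal(as.character(rec$gender), c("woman", "man", "woman", NA))
  expect_equal(rec$height_cm, c(165, 180, NA, 170))
  expect_equal(rec$mass_kg, c(55, 80, 60, NA))
  expect_equal(rec$bmi[1], 55 / 1.65^2)
})

test_that("a fixture with malformed fields keeps every row, only the fields go missing", {
  good <- function(id, age) sprintf("%d\twoman\t%s\t165\t55", id, age)
  lines <- c("id\tgender\tage\theight\tmass",
             good(1, "20"), good(2, "??"), good(3, "21"), good(4, "22"),
             good(5, "twenty"), good(6, "23"), good(7, "24"), good(8, "25"),
             good(9, "26"), good(10, "27"))
  rec <- parse_profiles(lines, dialect = "generic")
  expect_equal(nrow(rec), 10)
  expect_equal(sum(is.na(rec$age)), 2)
})

test_that("pokec dialect reads fixed columns, treats age 0 as unset, maps the gender flag", {
  rows <- c("1\t1\t100\t1\tr\tl\tg\t25\t170 cm, 60 kg",
            "2\t1\t100\t0\tr\tl\tg\t0\t",
            "3\t1\t100\t1\tr\tl\tg\t30\tno body info")
  rec <- parse_profiles(rows, dialect = "pokec")
  expect_equal(as.character(rec$gender), c("man", "woman", "man"))
  expect_equal(rec$age, c(25, NA, 30))
  expect_equal(rec$height_cm, c(170, NA, NA))
  # the flag mapping is configurable
  rec2 <- parse_profiles(rows, dialect = "pokec",
                         gender_map = c("1" = "woman", "0" = "man"))
  expect_equal(as.character(rec2$gender), c("woman", "man", "woman"))
})

test_that("a stream that is mostly not tab-separated is rejected as the wrong dialect", {
  expect_error(parse_profiles(c("a,b,c", "d,e,f", "g,h,i"), dialect = "pokec"),
               "dialect")
})

test_that("plausibility filters blank implausible values and are idempotent", {
  rec <- make_records(6)
  rec$age <- c(11, 60, 25, 25, 25, 25)
  rec$height_cm <- c(170, 170, 139, 170, 170, 170)
  rec$mass_kg <- c(60, 60, 60, 205, 60, 36)
  # last record: bmi 36/1.7^2 would be fine, force bmi out of range instead
  rec$mass_kg[6] <- 36 * 1.7^2  # bmi exactly 36 -> implausible
  once <- apply_plausibility_filters(rec)
  expect_true(is.na(once$records$age[1]))   # below 12
  expect_true(is.na(once$records$age[2]))   # above 59
  expect_true(is.na(once$records$height_cm[3]))
  expect_true(is.na(once$records$bmi[3]))   # bmi needs height
  expect_true(is.na(once$records$mass_kg[4]))
  expect_true(is.na(once$records$bmi[6]))   # bmi 36 out of [15, 35]
  expect_false(is.na(once$records$bmi[5]))  # all-in-range row untouched
  twice <- apply_plausibility_filters(once$records)
  expect_identical(twice$records, once$records)
})

test_that("boundary values of the closed plausibility intervals are kept", {
  rec <- make_records(4)
  rec$age <- c(12, 59, 15, 32)
  out <- apply_plausibility_filters(rec)$records
  expect_false(anyNA(out$age))
})

test_that("the cleaning report recomputes exactly from the returned records", {
  rec <- make_records(10)
  rec$age[1:3] <- c(11, NA, 70)       # 3 missing after filtering
  rec$gender[4] <- NA
  rec$mass_kg[5] <- 300               # bmi missing
  filt <- apply_plausibility_filters(rec)
  r <- filt$report
  rr <- filt$records
  expect_equal(r$n_total, 10)
  expect_equal(r$pct_missing_age, 100 * sum(is.na(rr$age)) / 10)
  expect_equal(r$pct_missing_gender, 100 * sum(is.na(rr$gender)) / 10)
  expect_equal(r$pct_missing_bmi, 100 * sum(is.na(rr$bmi)) / 10)
  complete <- !is.na(rr$gender) & !is.na(rr$age) & !is.na(rr$bmi)
  expect_equal(r$n_complete, sum(complete))
  expect_true(r$n_complete <= r$n_total)
})

test_that("the analysis sample keeps complete records inside the closed age window", {
  rec <- make_records(5)
  rec$age <- c(33, 15, 32, 25, 14)
  rec$bmi[4] <- NA
  out <- select_analysis_sample(rec)
  expect_setequal(out$user_id, c("n2", "n3"))  # 15 and 32 inclusive; 33/14 out
})

test_that("an empty analysis sample warns rather than errors", {
  rec <- make_records(2)
  rec$age <- c(40, 50)
  expect_warning(select_analysis_sample(rec), "empty")
})

test_that("build_network drops self-loops, duplicates, and dangling edges with a count", {
  rec <- make_records(5)
  # 7 raw edges: one duplicate ordered pair and one dangling endpoint
  ed <- rbind(make_edges(c(1, 2, 1, 1, 3, 4), c(2, 1, 3, 3, 4, 5)),
              data.frame(follower = "n1", followee = "ghost"))
  expect_message(net <- build_network(rec, ed), "dropped 2")
  expect_equal(n_edges(net), 5)
  expect_message(net2 <- build_network(rec, make_edges(c(2, 2), c(2, 3))),
                 "dropped 1")  # self-loop removed
  expect_equal(n_edges(net2), 1)
  expect_equal(sum(net$nodes$in_degree), n_edges(net))
  expect_equal(sum(net$nodes$out_degree), n_edges(net))
})

test_that("reciprocal pairs are exactly the mutually following pairs", {
  net <- toy_network(3, c(1, 2, 1), c(2, 1, 3))
  rp <- reciprocal_pairs(net)
  expect_equal(nrow(rp), 1)
  expect_setequal(unlist(rp[1, ]), c("n1", "n2"))
  expect_equal(sum(net$edges$reciprocal), 2)
})

test_that("gender subnetworks contain only same-gender ties", {
  rec <- make_records(6, gender = c("woman", "woman", "woman", "man", "man", "man"))
  # 3 woman-woman, 2 man-man, 4 cross
  ed <- make_edges(c(1, 2, 3, 4, 5, 1, 4, 2, 6),
                   c(2, 3, 1, 5, 6, 4, 1, 5, 2))
  net <- build_network(rec, ed, quiet = TRUE)
  w <- same_gender_subnetwork(net, "woman")
  m <- same_gender_subnetwork(net, "man")
  expect_equal(n_edges(w), 3)
  expect_equal(n_edges(m), 2)
  expect_true(all(w$nodes$gender == "woman"))
  # an all-women network is unchanged for gender = woman
  allw <- toy_network(3, c(1, 2), c(2, 3))
  expect_equal(same_gender_subnetwork(allw, "woman")$edges$follower,
               allw$edges$follower)
})

test_that("attribute-interval subnetworks induce the hand-counted node and edge sets", {
  net <- toy_network(5, c(1, 2, 3, 4, 1), c(2, 3, 4, 5, 3),
                     bmi = c(19, 20, 21, 25, 30))
  full <- attribute_interval_subnetwork(net, "bmi", 15, 35)
  expect_equal(n_edges(full), n_edges(net))
  empty <- attribute_interval_subnetwork(net, "bmi", 33, 34)
  expect_equal(n_nodes(empty), 0)
  expect_equal(n_edges(empty), 0)
  sub <- attribute_interval_subnetwork(net, "bmi", 19, 21)
  expect_setequal(sub$nodes$user_id, c("n1", "n2", "n3"))
  expect_equal(n_edges(sub), 3)  # 1->2, 2->3, 1->3
})

test_that("networks built from the analysis sample never have a missing-attribute endpoint", {
  rec <- make_records(6)
  rec$age[2] <- 40          # out of window
  rec$bmi[3] <- NA
  sample_rec <- select_analysis_sample(apply_plausibility_filters(rec)$records)
  net <- build_network(sample_rec, make_edges(c(1, 2, 3, 4), c(2, 3, 4, 5)),
                       quiet = TRUE)
  nd <- net$nodes
  expect_false(anyNA(nd$age[net$edges$from]))
  expect_false(anyNA(nd$bmi[net$edges$to]))
})

test_that("the packaged fixture round-trips through the pokec parser", {
  rec <- parse_profiles(fixture_path("synthetic-pokec-profiles.txt"),
                        dialect = "pokec")
  ed <- parse_edges(fixture_path("synthetic-pokec-relationships.txt"))
  expect_equal(nrow(rec), 200)
  expect_false(anyNA(rec$gender))
  expect_false(anyNA(rec$bmi))
  expect_true(all(rec$age >= 15 & rec$age <= 32))
  net <- build_network(select_analysis_sample(
    apply_plausibility_filters(rec)$records), ed, quiet = TRUE)
  expect_gt(n_edges(net), 500)
})
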