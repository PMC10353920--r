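test_that("reader accepts minimal well-formed input and passes values through", {
  path <- write_fixture_csv(data.frame(
    study_id = c("a", "b", "c"), vital_rate = c("sa", "CS", "HS"),
    value = c(0.9, 4.6, 0.61), n = c(50, 120, NA)))
  db <- read_vital_rate_db(path)
  expect_s3_class(db, "vital_rate_db")
  expect_equal(nrow(db), 3)
  expect_true(all(is.na(db$se)))
  expect_true(all(is.na(db$variance)))
  expect_equal(db$value[db$vital_rate == "CS"], 4.6)
  expect_equal(db$n[db$vital_rate == "CS"], 120)
})

test_that("rows violating a rate's legal domain are rejected with diagnostics", {
  path <- write_fixture_csv(data.frame(
    study_id = c("a", "b"), vital_rate = c("sa", "sa"),
    value = c(1.3, 0.9)))
  expect_warning(db <- read_vital_rate_db(path), "row 1.*domain")
  expect_equal(nrow(db), 1)
  expect_equal(nrow(attr(db, "rejected")), 1)
  expect_error(read_vital_rate_db(path, strict = TRUE), "domain")
})

test_that("missing mandatory columns give a schema error naming the column", {
  path <- write_fixture_csv(data.frame(study_id = "a", value = 0.5))
  expect_error(read_vital_rate_db(path), "vital_rate")
})

test_that("column_map adapts external headers", {
  path <- write_fixture_csv(data.frame(
    Study = "a", Rate = "sa", Estimate = 0.85))
  db <- read_vital_rate_db(path, column_map = c(
    study_id = "Study", vital_rate = "Rate", value = "Estimate"))
  expect_equal(db$value, 0.85)
})

test_that("when se and variance disagree the standard error wins", {
  path <- write_fixture_csv(data.frame(
    study_id = "a", vital_rate = "sa", value = 0.85,
    se = 0.1, variance = 0.5))
  expect_warning(db <- read_vital_rate_db(path), "se\\^2")
  expect_equal(db$variance, 0.01)
})

test_that("default screening drops non-female survival estimates only", {
  db <- make_db(data.frame(
    study_id = letters[1:10],
    vital_rate = c(rep("sa", 4), rep("CS", 6)),
    value = c(runif(4, 0.7, 0.95), runif(6, 3, 5)),
    sex = c("female", "male", "male", "female", rep("aggregated", 6))))
  out <- screen_records(db, quiet = TRUE)
  expect_equal(nrow(out), 8)  # 2 male survival records dropped, CS retained
  expect_equal(attr(out, "n_dropped"), 2)
})

test_that("screening matches the eider database situation: 14 male or aggregated survival estimates across 8 studies", {
  db <- make_sex_screen_fixture()
  out <- screen_records(db, quiet = TRUE)
  expect_equal(attr(out, "n_dropped"), 14)
  expect_equal(length(unique(db$study_id)) - length(unique(out$study_id)), 8)
})

test_that("unverified records can be dropped by policy and screening is idempotent", {
  db <- make_db(data.frame(
    study_id = c("a", "b", "c"), vital_rate = "CS",
    value = c(4, 4.2, 4.4), verified = c(TRUE, FALSE, TRUE)))
  once <- screen_records(db, drop_unverified = TRUE, quiet = TRUE)
  expect_equal(nrow(once), 2)
  twice <- screen_records(once, drop_unverified = TRUE, quiet = TRUE)
  expect_equal(as.data.frame(twice), as.data.frame(once),
               ignore_attr = TRUE)
  expect_equal(attr(twice, "n_dropped"), 0)
  # default policy retains unverified and midpoint records
  expect_equal(nrow(screen_records(db, quiet = TRUE)), 3)
})

test_that("within-study replicates collapse to one independent record", {
  db <- make_db(data.frame(
    study_id = "s1", vital_rate = "CS", value = c(4.0, 4.2, 4.4),
    independence_group = "s1", replicate_year = c("2001", "2002", "2003")))
  out <- resolve_independence(db)
  expect_equal(nrow(out), 1)
  expect_equal(out$value, 4.2)
  expect_equal(out$provenance, "sub_meta")
})

test_that("cross-study groups honour the most-precise rule", {
  db <- make_db(data.frame(
    study_id = c("s1", "s2"), vital_rate = "sa", value = c(0.8, 0.9),
    variance = c(0.02, 0.005), independence_group = "shared"))
  out <- resolve_independence(db, rules = c(shared = "most_precise"))
  expect_equal(nrow(out), 1)
  expect_equal(out$study_id, "s2")
  expect_equal(out$provenance, "rule:most_precise")
  expect_error(resolve_independence(db), "unresolved.*shared")
})

test_that("independence resolution never increases record count and keeps one rate", {
  db <- make_adult_survival_fixture()
  rules <- stats::setNames(rep("most_precise", 6), sprintf("grp%d", 1:6))
  out <- resolve_independence(db, rules = rules)
  expect_lte(nrow(out), nrow(db))
  expect_equal(unique(out$vital_rate), "sa")
  mixed <- make_db(data.frame(study_id = c("a", "b"),
                              vital_rate = c("sa", "CS"),
                              value = c(0.8, 4)))
  expect_error(resolve_independence(mixed), "single vital rate")
})

test_that("35 adult-survival studies reduce to 15 independent estimates informing the meta-analysis", {
  db <- make_adult_survival_fixture()
  expect_equal(length(unique(db$study_id)), 35)
  rules <- stats::setNames(rep("most_precise", 6), sprintf("grp%d", 1:6))
  resolved <- resolve_independence(db, rules = rules)
  res <- synthesise_rate(resolved)
  expect_equal(res$method, "meta")
  expect_equal(res$k, 15)
})

test_that("study effort counts unique studies per group with overlap allowed", {
  db <- make_db(data.frame(
    study_id = c("s1", "s2", "s2"), vital_rate = c("CS", "CS", "BPeb"),
    value = c(4, 4.2, 0.7)))
  eff <- count_study_effort(db)
  expect_equal(eff$group_counts[["Reproduction"]], 2L)
  expect_equal(eff$group_counts[["Breeding transitions"]], 1L)
  expect_equal(eff$total_studies, 2L)
  # invariant to record order
  eff2 <- count_study_effort(db[c(3, 1, 2), ])
  expect_equal(eff2$group_counts[names(eff$group_counts)], eff$group_counts)
  # unmapped rate is a configuration error
  expect_error(count_study_effort(db, grouping = list(CS = "Reproduction")),
               "BPeb")
})

test_that("empty databases give zero effort and a zero-total error downstream", {
  db <- make_db(data.frame(study_id = "a", vital_rate = "sa", value = 0.8))
  empty <- db[0, , drop = FALSE]
  eff <- count_study_effort(empty, grouping = eider_rate_groups())
  expect_equal(eff$total_studies, 0L)
  expect_true(all(eff$group_counts == 0))
  expect_error(fractional_effort(eff), "total_studies")
})

test_that("study_effort enforces count <= total and round-trips to fractions", {
  expect_error(study_effort(c(A = 10), total_studies = 5), "exceeds")
  eff <- study_effort(
    c(Recruitment = 39, `Breeding transitions` = 38, Reproduction = 103),
    total_studies = 129)
  frac <- fractional_effort(eff)
  expect_equal(frac[["Reproduction"]], 103 / 129)
  expect_equal(frac[["Recruitment"]], 39 / 129)
})

test_that("databases round-trip through write and read", {
  db <- generate_database(eider_synthetic_config(seed = 7))
  path <- tempfile(fileext = ".csv")
  write_vital_rate_db(db, path)
  back <- read_vital_rate_db(path)
  expect_equal(as.data.frame(back), as.data.frame(db))
})
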