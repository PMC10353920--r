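# fixtures are built in code at test time; nothing is stored on disk

# write a minimal evidence CSV and return its path
write_fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# single-rate synthetic configuration around adult survival
one_rate_config <- function(seed = 1, k = 30, theta = 0.86,
                            T2 = 0.001, sigma2 = 0.05,
                            n_range = c(20, 200), ...) {
  synthetic_config(rates = list(
    sa = rate_config(theta, between_study_sd = sqrt(T2),
                     within_study_variance = sigma2, n_studies = k,
                     n_range = n_range, ...)), seed = seed)
}

# a small in-memory database built through the public reader
make_db <- function(df) {
  read_vital_rate_db(write_fixture_csv(df))
}

# evidence base emulating the sex-screening situation in the eider database:
# 14 male/aggregated survival estimates spread over 8 studies, on top of a
# female core
make_sex_screen_fixture <- function() {
  set.seed(101)
  female <- data.frame(
    study_id = sprintf("f%02d", 1:10), vital_rate = "sa",
    value = seq(0.80, 0.89, by = 0.01), n = 50, sex = "female")
  male_studies <- sprintf("m%d", 1:8)
  male <- data.frame(
    study_id = male_studies[c(1:8, 1:6)], vital_rate = rep("sa", 14),
    value = runif(14, 0.7, 0.95), n = 40,
    sex = rep(c("male", "aggregated"), 7))
  make_db(rbind(female, male))
}

# adult-survival fixture whose independence resolution and sample-size
# exclusions leave 15 independent estimates from 35 studies
make_adult_survival_fixture <- function() {
  set.seed(99)
  studies <- sprintf("sa%02d", 1:35)
  df <- data.frame(study_id = studies, vital_rate = "sa",
                   value = round(runif(35, 0.78, 0.92), 3),
                   variance = 0.002, n = 60,
                   independence_group = NA_character_)
  # 12 studies share 6 two-study independence groups -> 6 records survive
  df$independence_group[1:12] <- rep(sprintf("grp%d", 1:6), each = 2)
  df$variance[1:12] <- rep(c(0.001, 0.004), 6)  # first of each pair precise
  # 14 further studies lack sample sizes -> excluded from the meta
  df$n[13:26] <- NA
  make_db(df)
}
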