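#' Per-rate settings for the synthetic evidence generator
#'
#' Describes the generative model for one vital rate: study-level means are
#' drawn as \eqn{\delta_i \sim N(\theta,\; T^2_{true} + \sigma^2 / n_i)}
#' (truncated to the rate's legal domain), the random-effects structure the
#' meta-analytic estimator targets. Each study reports its population-level
#' sample variance \eqn{s_i^2} (a chi-square draw around \eqn{\sigma^2}), the
#' quantity the mean-adjusted scheme pools into per-study error variances
#' \eqn{s^2 / n_i}; sample sizes and variances are omitted at the configured
#' rates, replicate studies emit per-year draws sharing a `study_id`, and
#' verification/midpoint flags are assigned independently.
#'
#' @param true_mean ground-truth mean theta (within the rate's domain).
#' @param between_study_sd sqrt of the true between-study variance.
#' @param within_study_variance sigma^2, the population-level (per
#'   individual) variance underlying study-level error variances
#'   sigma^2 / n_i.
#' @param n_studies number of studies k (>= 1).
#' @param n_range integer bounds for study sample sizes.
#' @param missing_n_fraction probability a study omits its sample size.
#' @param missing_variance_fraction probability a study omits its variance.
#' @param replicate_fraction probability a study reports multi-year
#'   replicates instead of a single estimate.
#' @param unverified_fraction probability an estimate is flagged unverified.
#' @param midpoint_fraction probability an estimate is flagged as a range
#'   midpoint.
#' @return a `rate_config` list.
#' @export
rate_config <- function(true_mean, between_study_sd = 0,
                        within_study_variance = 0, n_studies = 10,
                        n_range = c(20, 200), missing_n_fraction = 0,
                        missing_variance_fraction = 0,
                        replicate_fraction = 0,
                        unverified_fraction = 0, midpoint_fraction = 0) {
  fracs <- c(missing_n_fraction, missing_variance_fraction,
             replicate_fraction, unverified_fraction, midpoint_fraction)
  stopifnot(all(fracs >= 0 & fracs <= 1), n_studies >= 1,
            between_study_sd >= 0, within_study_variance >= 0,
            length(n_range) == 2, n_range[1] >= 1,
            n_range[2] >= n_range[1])
  structure(list(true_mean = true_mean, between_study_sd = between_study_sd,
                 within_study_variance = within_study_variance,
                 n_studies = as.integer(n_studies),
                 n_range = as.integer(n_range),
                 missing_n_fraction = missing_n_fraction,
                 missing_variance_fraction = missing_variance_fraction,
                 replicate_fraction = replicate_fraction,
                 unverified_fraction = unverified_fraction,
                 midpoint_fraction = midpoint_fraction),
            class = "rate_config")
}

#' Synthetic-database configuration
#'
#' A named collection of [rate_config()]s (names must be valid
#' [vital_rate_codes()]) plus a seed. Each ground-truth mean is checked
#' against the rate's legal domain.
#'
#' @param rates named list of [rate_config()] objects.
#' @param seed integer seed driving the whole database.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(rates, seed = 1L) {
  stopifnot(is.list(rates), length(rates) >= 1, !is.null(names(rates)))
  bad <- setdiff(names(rates), vital_rate_codes())
  if (length(bad) > 0)
    stop("unknown vital rate(s) in config: ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (code in names(rates)) {
    rc <- rates[[code]]
    stopifnot(inherits(rc, "rate_config"))
    dom <- rate_domain(code)
    if (rc$true_mean < dom[1] || rc$true_mean > dom[2])
      stop("true_mean for ", code, " outside its legal domain", call. = FALSE)
  }
  structure(list(rates = rates, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Default synthetic configuration emulating the eider evidence base
#'
#' Mirrors the structure of the published eider database: ground-truth means
#' set to the species-wide synthesised values, study counts per rate as
#' reported there (35 adult-survival studies, 91 clutch-size studies, 27
#' hatching-success studies, and a handful of studies for the sparsely
#' estimated rates), with sparse rates mostly lacking sample sizes (which is
#' what routes them to the simple-mean path) and the heavily studied rates
#' carrying replicates and occasional missing metadata.
#'
#' @param seed integer seed.
#' @return a `synthetic_config`.
#' @export
eider_synthetic_config <- function(seed = 1L) {
  synthetic_config(rates = list(
    s1h = rate_config(0.37, between_study_sd = 0.25,
                      within_study_variance = 0.2, n_studies = 3,
                      n_range = c(20, 80), missing_n_fraction = 0.7),
    s1f = rate_config(0.75, between_study_sd = 0.12,
                      within_study_variance = 0.15, n_studies = 3,
                      n_range = c(20, 80), missing_n_fraction = 0.7),
    s2 = rate_config(0.87, between_study_sd = 0.08,
                     within_study_variance = 0.1, n_studies = 7,
                     n_range = c(20, 120), missing_n_fraction = 0.5),
    sa = rate_config(0.86, between_study_sd = 0.03,
                     within_study_variance = 0.05, n_studies = 35,
                     n_range = c(30, 300), missing_n_fraction = 0.25,
                     missing_variance_fraction = 0.3,
                     replicate_fraction = 0.3,
                     unverified_fraction = 0.1, midpoint_fraction = 0.05),
    FB2 = rate_config(0.17, between_study_sd = 0.08,
                      within_study_variance = 0.1, n_studies = 7,
                      n_range = c(20, 100), missing_n_fraction = 0.6),
    FB3 = rate_config(0.58, between_study_sd = 0.1,
                      within_study_variance = 0.1, n_studies = 6,
                      n_range = c(20, 100), missing_n_fraction = 0.6),
    FB4 = rate_config(0.71, between_study_sd = 0.1,
                      within_study_variance = 0.1, n_studies = 2,
                      n_range = c(20, 100), missing_n_fraction = 0.5),
    FB5 = rate_config(1, between_study_sd = 0, within_study_variance = 0,
                      n_studies = 2, n_range = c(20, 100),
                      missing_n_fraction = 0.5),
    BPeb = rate_config(0.72, between_study_sd = 0.17,
                       within_study_variance = 0.1, n_studies = 7,
                       n_range = c(20, 150), missing_n_fraction = 0.6),
    CS = rate_config(4.08, between_study_sd = 0.3,
                     within_study_variance = 1.5, n_studies = 91,
                     n_range = c(20, 500), missing_n_fraction = 0.2,
                     missing_variance_fraction = 0.4,
                     replicate_fraction = 0.25,
                     unverified_fraction = 0.1, midpoint_fraction = 0.05),
    HS = rate_config(0.61, between_study_sd = 0.1,
                     within_study_variance = 0.15, n_studies = 27,
                     n_range = c(20, 200), missing_n_fraction = 0.3,
                     missing_variance_fraction = 0.4,
                     replicate_fraction = 0.2,
                     unverified_fraction = 0.1),
    FS = rate_config(0.22, between_study_sd = 0.1,
                     within_study_variance = 0.15, n_studies = 13,
                     n_range = c(20, 100), missing_n_fraction = 0.5)
  ), seed = seed)
}

# deterministic substream seed per (rate, study): adding rates or studies
# never perturbs earlier draws; kept below 2^31 - 1
substream_seed <- function(seed, rate_index, study) {
  (as.numeric(seed) * 2654435761 + rate_index * 97561 + study * 7919) %%
    2147483647
}

rtrunc_norm <- function(n, mean, sd, lower, upper, max_tries = 1000) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- out < lower | out > upper
  tries <- 0
  while (any(bad) && tries < max_tries) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out < lower | out > upper
    tries <- tries + 1
  }
  if (any(bad)) {
    warning("truncation resampling exhausted; clamping to the domain",
            call. = FALSE)
    out <- pmin(pmax(out, lower), upper)
  }
  out
}

#' Generate a synthetic vital-rate evidence database
#'
#' Draws a database with known ground truth under the random-effects model
#' described in [rate_config()]. Each (rate, study) pair runs on its own
#' deterministic RNG substream derived from the configuration seed, so the
#' output is reproducible and grows consistently as studies are added. The
#' result always passes database validation.
#'
#' @param config a [synthetic_config()].
#' @return a `vital_rate_db` data frame.
#' @examples
#' db <- generate_database(eider_synthetic_config(seed = 42))
#' table(db$vital_rate)
#' @export
generate_database <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  rows <- list()
  for (rate_index in seq_along(config$rates)) {
    code <- names(config$rates)[rate_index]
    rc <- config$rates[[rate_index]]
    dom <- rate_domain(code)
    upper <- if (is.finite(dom[2])) dom[2] else Inf
    for (i in seq_len(rc$n_studies)) {
      set.seed(substream_seed(config$seed, rate_index, i))
      n_i <- rc$n_range[1] +
        sample.int(rc$n_range[2] - rc$n_range[1] + 1L, 1) - 1L
      total_sd <- sqrt(rc$between_study_sd^2 +
                         rc$within_study_variance / n_i)
      delta_i <- rtrunc_norm(1, rc$true_mean, total_sd, dom[1], upper)
      # the study reports its population-level sample variance s_i^2 (a
      # chi-square draw around sigma^2); the synthesis turns the pooled mean
      # of these into per-study error variances s^2 / n_i
      s2_i <- if (rc$within_study_variance == 0) 0 else
        rc$within_study_variance *
          stats::rchisq(1, df = n_i - 1) / (n_i - 1)
      study_id <- sprintf("%s_study%02d", code, i)
      replicated <- stats::runif(1) < rc$replicate_fraction
      miss_n <- stats::runif(1) < rc$missing_n_fraction
      miss_v <- stats::runif(1) < rc$missing_variance_fraction
      unverified <- stats::runif(1) < rc$unverified_fraction
      midpoint <- stats::runif(1) < rc$midpoint_fraction
      if (replicated) {
        n_years <- sample(2:4, 1)
        yr_sd <- sqrt(rc$within_study_variance / n_i)
        values <- rtrunc_norm(n_years, delta_i, yr_sd, dom[1], upper)
        rows[[length(rows) + 1]] <- data.frame(
          study_id = study_id, vital_rate = code, value = values,
          se = NA_real_,
          variance = if (miss_v) NA_real_ else s2_i,
          n = if (miss_n) NA_real_ else
            pmax(1, round(n_i / n_years)),
          sex = "female", verified = !unverified, midpoint = midpoint,
          independence_group = study_id,
          replicate_site = NA_character_,
          replicate_year = as.character(2000 + seq_len(n_years)),
          subspecies = NA_character_, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          study_id = study_id, vital_rate = code, value = delta_i,
          se = NA_real_,
          variance = if (miss_v) NA_real_ else s2_i,
          n = if (miss_n) NA_real_ else n_i,
          sex = "female", verified = !unverified, midpoint = midpoint,
          independence_group = NA_character_,
          replicate_site = NA_character_,
          replicate_year = NA_character_,
          subspecies = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  new_vital_rate_db(do.call(rbind, rows), quiet = TRUE)
}

#' Generate a jittered vital-rate set
#'
#' Perturbs every rate of a central [vital_rate_set()] multiplicatively by
#' `exp(jitter * z)` with standard-normal `z`, clamping to the rate's legal
#' domain and pinning `BP5` at 1. Used for property sweeps over plausible
#' parameterisations.
#'
#' @param seed integer seed.
#' @param center a [vital_rate_set()] to jitter around.
#' @param jitter relative spread (>= 0); 0 returns `center` unchanged.
#' @return a [vital_rate_set()].
#' @export
generate_vital_rate_set <- function(seed, center = eider_vital_rates(),
                                    jitter = 0.1) {
  stopifnot(inherits(center, "vital_rate_set"), jitter >= 0)
  if (jitter == 0) return(center)
  set.seed(as.integer(seed))
  out <- unclass(center)
  for (nm in names(out)) {
    if (nm == "BP5" || is.na(out[[nm]])) next
    val <- out[[nm]] * exp(jitter * stats::rnorm(1))
    hi <- if (nm == "CS") Inf else 1
    out[[nm]] <- min(max(val, 0), hi)
  }
  do.call(vital_rate_set, out)
}
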