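#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result> method=%s k=%d mean=%.6g variance=%.6g",
              x$method, x$k, x$mean, x$variance))
  if (!is.null(x$T2)) cat(sprintf(" T2=%.6g", x$T2))
  cat("\n")
  invisible(x)
}

new_meta_result <- function(mean, variance, method, k, T2 = NULL,
                            weights = NULL, s2_pooled = NULL) {
  structure(list(mean = mean, variance = variance, method = method, k = k,
                 T2 = T2, weights = weights, s2_pooled = s2_pooled),
            class = "meta_result")
}

#' Choose the synthesis method for one vital rate
#'
#' Formal meta-analysis is withheld from rates with a thin evidence base:
#' a simple mean is used when the number of independent estimates is below
#' `k_min` AND more than `missing_n_max` of them lack a sample size (both
#' conditions; a small but fully sample-sized evidence base is still
#' meta-analysed). Otherwise the rate is meta-analysed.
#'
#' @param records a `vital_rate_db` data frame of independent estimates of a
#'   single vital rate (independence already resolved).
#' @param k_min minimum number of independent estimates (default 20).
#' @param missing_n_max maximum tolerated fraction of estimates without a
#'   sample size (default 1/3).
#' @return `"simple"` or `"meta"`.
#' @export
choose_method <- function(records, k_min = 20, missing_n_max = 1 / 3) {
  stopifnot(inherits(records, "data.frame"))
  if (nrow(records) == 0) stop("no estimates supplied", call. = FALSE)
  k <- nrow(records)
  frac_missing_n <- mean(is.na(records$n))
  if (k < k_min && frac_missing_n > missing_n_max) "simple" else "meta"
}

#' Simple (unweighted) mean synthesis
#'
#' Arithmetic mean of the point estimates with the sample variance (divisor
#' `k - 1`; zero for a single estimate) as the dispersion summary. Used for
#' rates whose evidence base is too thin for precision-weighting; sample
#' sizes and study-level variances are ignored.
#'
#' @param values numeric vector of point estimates (at least one).
#' @return a `meta_result` with `method = "simple"`.
#' @examples
#' simple_mean(c(0.2, 0.4, 0.6))
#' @export
simple_mean <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || all(is.na(values)))
    stop("no estimates supplied", call. = FALSE)
  values <- values[!is.na(values)]
  k <- length(values)
  new_meta_result(mean = mean(values),
                  variance = if (k > 1) stats::var(values) else 0,
                  method = "simple", k = k)
}

#' Mean-adjusted precision-weighted random-effects meta-analysis
#'
#' Random-effects synthesis of study-level means in which each study's error
#' variance is the pooled mean study variance divided by its own sample size,
#' \eqn{v_i = s^2 / n_i} with \eqn{s^2 = \mathrm{mean}(s_i^2)} over the
#' studies that report a variance. This removes the small-sample bias of
#' self-reported variances and lets studies that report replication but no
#' variance still be precision-weighted. The between-study variance is the
#' Cochran/Hedges variance-component estimator
#' \eqn{T^2 = \mathrm{var}(\delta_i) - \mathrm{mean}(v_i)} (sample variance,
#' divisor `k - 1`), truncated at zero. Weights are
#' \eqn{W_i = 1 / (v_i + T^2)}; the synthesised mean is
#' \eqn{\sum W_i \delta_i / \sum W_i} with meta-variance
#' \eqn{1 / \sum W_i}.
#'
#' @param deltas study-level means \eqn{\delta_i} (at least two).
#' @param variances study-level sampling variances \eqn{s_i^2}; `NA` where a
#'   study reports none (at least one must be reported).
#' @param ns study sample sizes \eqn{n_i}; required for every study --
#'   exclude estimates without sample sizes before calling.
#' @return a `meta_result` with `method = "meta"`, the weights, `T2` and the
#'   pooled `s2_pooled`.
#' @examples
#' random_effects_meta(deltas = c(0.8, 0.9),
#'                     variances = c(0.01, 0.01),
#'                     ns = c(10, 40))
#' @export
random_effects_meta <- function(deltas, variances, ns) {
  deltas <- as.numeric(deltas)
  k <- length(deltas)
  if (k < 2) stop("meta-analysis needs at least two studies", call. = FALSE)
  if (missing(variances)) variances <- rep(NA_real_, k)
  variances <- rep_len(as.numeric(variances), k)
  ns <- rep_len(as.numeric(ns), k)
  if (any(is.na(ns)))
    stop("every study needs a sample size n_i; exclude estimates without ",
         "sample sizes before meta-analysis", call. = FALSE)
  if (any(ns <= 0)) stop("sample sizes must be positive", call. = FALSE)
  if (all(is.na(variances)))
    stop("pooled variance undefined: no study reports a variance",
         call. = FALSE)
  s2 <- mean(variances, na.rm = TRUE)
  v <- s2 / ns
  T2 <- max(0, stats::var(deltas) - mean(v))
  if (all(v + T2 == 0)) {
    # fully degenerate: no sampling and no between-study variance
    return(new_meta_result(mean = mean(deltas), variance = 0,
                           method = "meta", k = k, T2 = 0,
                           weights = rep(1, k), s2_pooled = s2))
  }
  W <- 1 / (v + T2)
  new_meta_result(mean = sum(W * deltas) / sum(W),
                  variance = 1 / sum(W),
                  method = "meta", k = k, T2 = T2, weights = W,
                  s2_pooled = s2)
}

record_variances <- function(records) {
  ifelse(is.na(records$variance) & !is.na(records$se), records$se^2,
         records$variance)
}

#' Sub-meta-analysis of spatiotemporal replicates within one study
#'
#' Collapses several replicate estimates (different years and/or sites) from
#' a single study into one independent record before the cross-study
#' synthesis, following the same protocol as the main meta-analysis: the
#' precision-weighted random-effects estimate when all replicates carry
#' sample sizes and at least one a variance, otherwise the simple mean. A
#' single replicate passes through unchanged.
#'
#' @param records a `vital_rate_db` data frame of replicates sharing one
#'   `study_id` and one vital rate.
#' @return a one-row `vital_rate_db`; collapsed rows have
#'   `provenance = "sub_meta"`, value/variance set to the sub-meta
#'   mean/variance, and `n` the summed replicate `n` where all are known.
#' @export
sub_meta_analysis <- function(records) {
  stopifnot(inherits(records, "data.frame"))
  if (nrow(records) == 0) stop("no replicates supplied", call. = FALSE)
  if (length(unique(records$study_id)) != 1)
    stop("sub_meta_analysis expects replicates from a single study",
         call. = FALSE)
  if (length(unique(records$vital_rate)) != 1)
    stop("sub_meta_analysis expects replicates of a single vital rate",
         call. = FALSE)
  if (nrow(records) == 1) return(records)
  v <- record_variances(records)
  res <- if (!any(is.na(records$n)) && any(!is.na(v))) {
    random_effects_meta(records$value, v, records$n)
  } else {
    simple_mean(records$value)
  }
  out <- records[1, , drop = FALSE]
  out$value <- res$mean
  out$variance <- res$variance
  out$se <- NA_real_
  out$n <- if (any(is.na(records$n))) NA_real_ else sum(records$n)
  out$verified <- if (any(is.na(records$verified))) NA else
    all(records$verified)
  out$midpoint <- if (any(is.na(records$midpoint))) NA else
    any(records$midpoint)
  out$replicate_site <- NA_character_
  out$replicate_year <- NA_character_
  out$provenance <- "sub_meta"
  rownames(out) <- NULL
  class(out) <- c("vital_rate_db", "data.frame")
  out
}

#' Synthesise one vital rate from independent estimates
#'
#' Applies [choose_method()] and runs the corresponding synthesis. On the
#' meta-analytic path, estimates without sample sizes are excluded (they
#' cannot be precision-weighted) and study variances are taken from the
#' `variance` column or `se^2`.
#'
#' @inheritParams choose_method
#' @return a `meta_result`; on the meta path, the number of excluded
#'   no-sample-size estimates is attached as attribute `"n_excluded"`.
#' @export
synthesise_rate <- function(records, k_min = 20, missing_n_max = 1 / 3) {
  method <- choose_method(records, k_min = k_min,
                          missing_n_max = missing_n_max)
  if (method == "simple") return(simple_mean(records$value))
  with_n <- records[!is.na(records$n), , drop = FALSE]
  if (nrow(with_n) < 2)
    stop("fewer than two estimates with sample sizes; cannot meta-analyse",
         call. = FALSE)
  res <- random_effects_meta(with_n$value, record_variances(with_n),
                             with_n$n)
  attr(res, "n_excluded") <- nrow(records) - nrow(with_n)
  res
}

#' Sensitivity of a synthesis to flagged estimates
#'
#' Re-runs the synthesis with and without the estimates carrying a screening
#' flag (unverified, or based on a range midpoint) and reports whether the
#' two means are mutually within each other's approximate 95% interval
#' (mean +/- 1.96 sqrt(variance)). An overlapping verdict supports retaining
#' the flagged estimates for completeness.
#'
#' @param records a `vital_rate_db` data frame for one vital rate.
#' @param flag `"unverified"` or `"midpoint"`.
#' @inheritParams choose_method
#' @return list with elements `with` and `without` (both `meta_result`),
#'   `overlapping` (logical verdict), `flag` and `n_flagged`.
#' @export
sensitivity_compare <- function(records, flag = c("unverified", "midpoint"),
                                k_min = 20, missing_n_max = 1 / 3) {
  flag <- match.arg(flag)
  flagged <- switch(flag,
    unverified = !is.na(records$verified) & !records$verified,
    midpoint = !is.na(records$midpoint) & records$midpoint)
  res_with <- synthesise_rate(records, k_min, missing_n_max)
  if (!any(flagged) || all(flagged)) {
    warning("nothing to exclude for flag '", flag,
            "'; returning a degenerate comparison", call. = FALSE)
    return(list(with = res_with, without = res_with, overlapping = TRUE,
                flag = flag, n_flagged = sum(flagged)))
  }
  res_without <- synthesise_rate(records[!flagged, , drop = FALSE],
                                 k_min, missing_n_max)
  ci_half <- function(r) 1.96 * sqrt(max(r$variance, 0))
  overlapping <-
    abs(res_with$mean - res_without$mean) <= ci_half(res_without) &&
    abs(res_with$mean - res_without$mean) <= ci_half(res_with)
  list(with = res_with, without = res_without, overlapping = overlapping,
       flag = flag, n_flagged = sum(flagged))
}
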