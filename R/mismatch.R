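#' Fractional study effort per transition group
#'
#' Number of contributing studies for each transition group divided by the
#' total number of studies across all vital rates. A group studied by every
#' study has fractional effort 1; because studies may contribute to several
#' groups, the fractions need not sum to 1 and are deliberately not
#' renormalised.
#'
#' @param effort a [study_effort()] table.
#' @return named numeric vector of fractions in \[0, 1\].
#' @export
fractional_effort <- function(effort) {
  stopifnot(inherits(effort, "study_effort"))
  if (effort$total_studies == 0)
    stop("total_studies is zero; fractional effort undefined", call. = FALSE)
  effort$group_counts / effort$total_studies
}

#' Chance probability of a study-effort deviation
#'
#' Compares fractional study effort against demographic importance (summed
#' elasticity) for each transition group and asks how probable a deviation
#' at least as extreme, on the same side of the 1:1 line, would be if effort
#' fell uniformly at random on \[0, 1\] independent of importance. Effort
#' above importance (over-representation at least as large) has probability
#' `1 - effort`; effort below importance (under-representation at least as
#' large) has probability `effort`; zero deviation is matched or exceeded
#' with probability 1.
#'
#' @param importance summed elasticities in \[0, 1\] (optionally named by
#'   group).
#' @param effort fractional study efforts in \[0, 1\], recycled against
#'   `importance`.
#' @return a `mismatch_result` data frame with columns `group`,
#'   `importance`, `effort`, `deviation` (effort - importance), `side`
#'   (`over`/`under`/`exact`) and `chance_probability`.
#' @examples
#' chance_probability(importance = c(0.3, 0.6), effort = c(0.6, 0.3))
#' @export
chance_probability <- function(importance, effort) {
  groups <- names(importance)
  importance <- as.numeric(importance)
  n <- max(length(importance), length(effort))
  imp <- rep_len(importance, n)
  eff <- rep_len(as.numeric(effort), n)
  if (any(!is.finite(imp)) || any(!is.finite(eff)) ||
      any(imp < 0 | imp > 1) || any(eff < 0 | eff > 1))
    stop("importance and effort must lie in [0, 1]", call. = FALSE)
  deviation <- eff - imp
  side <- ifelse(deviation > 0, "over",
                 ifelse(deviation < 0, "under", "exact"))
  prob <- ifelse(side == "over", 1 - eff,
                 ifelse(side == "under", eff, 1))
  if (is.null(groups)) groups <- rep(NA_character_, n)
  out <- data.frame(group = rep_len(groups, n), importance = imp,
                    effort = eff, deviation = deviation, side = side,
                    chance_probability = prob, stringsAsFactors = FALSE)
  class(out) <- c("mismatch_result", "data.frame")
  out
}

#' Mismatch table for grouped elasticities and study effort
#'
#' Convenience wrapper aligning a named importance vector (from
#' [group_elasticities()]) with a [study_effort()] table by group label and
#' running [chance_probability()].
#'
#' @param importance named numeric vector of summed elasticities.
#' @param effort a [study_effort()] table covering the same groups.
#' @return a `mismatch_result` data frame, one row per group.
#' @export
mismatch_table <- function(importance, effort) {
  frac <- fractional_effort(effort)
  missing_groups <- setdiff(names(importance), names(frac))
  if (length(missing_groups) > 0)
    stop("no study counts for group(s): ",
         paste(missing_groups, collapse = ", "), call. = FALSE)
  chance_probability(importance, frac[names(importance)])
}

#' Null-probability surface over the importance/effort unit square
#'
#' Evaluates [chance_probability()] on a regular grid, producing the
#' long-format surface behind a cross-plot's shading and contours: the
#' probability of a random effort fraction deviating from the 1:1 line at
#' least as far, on the same side, at each level of importance.
#'
#' @param step grid step in (0, 0.1\].
#' @return data frame with columns `importance`, `effort`, `side`,
#'   `chance_probability`.
#' @export
contour_grid <- function(step = 0.01) {
  if (!is.finite(step) || step <= 0 || step > 0.1)
    stop("step must lie in (0, 0.1]", call. = FALSE)
  g <- expand.grid(importance = seq(0, 1, by = step),
                   effort = seq(0, 1, by = step))
  res <- chance_probability(g$importance, g$effort)
  data.frame(importance = res$importance, effort = res$effort,
             side = res$side, chance_probability = res$chance_probability)
}

#' Simplex null simulation for sets of importance fractions
#'
#' Elasticities are fractions summing to 1, i.e. points on the
#' (k-1)-simplex. Uniform (flat-Dirichlet) draws from the simplex more often
#' contain one high fraction forcing the others low than several moderate
#' ones, so chance mismatches against independently drawn study effort are
#' common. This simulation samples importance sets uniformly on the simplex,
#' records the distribution of the maximum fraction, and estimates, for each
#' requested deviation `d`, the probability that an independent uniform
#' effort draw lands at least `d` from a simplex-drawn importance fraction.
#'
#' @param k number of groups (>= 2).
#' @param draws number of simplex draws (>= 1).
#' @param seed integer seed; the simulation is reproducible under a fixed
#'   seed and leaves the caller's RNG state untouched.
#' @param deviations numeric vector of deviation thresholds `d`.
#' @return list with `k`, `draws`, `max_fraction` (vector of per-draw
#'   maxima), `deviation_probability` (named vector, one entry per `d`) and
#'   `seed`.
#' @examples
#' sim <- simplex_null_simulation(k = 3, draws = 1000, seed = 1)
#' mean(sim$max_fraction >= 0.5)  # about 0.75
#' @export
simplex_null_simulation <- function(k, draws, seed = 1L,
                                    deviations = c(0.1, 0.25, 0.5)) {
  if (!is.finite(k) || k < 2 || k != floor(k))
    stop("k must be an integer >= 2", call. = FALSE)
  if (!is.finite(draws) || draws < 1 || draws != floor(draws))
    stop("draws must be an integer >= 1", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  # flat Dirichlet via normalised exponentials
  e <- matrix(stats::rexp(draws * k), nrow = draws)
  fractions <- e / rowSums(e)
  max_fraction <- apply(fractions, 1, max)
  importance <- fractions[, 1]  # components are exchangeable
  effort <- stats::runif(draws)
  dev <- abs(effort - importance)
  dp <- vapply(deviations, function(d) mean(dev >= d), numeric(1))
  names(dp) <- paste0("d=", deviations)
  list(k = as.integer(k), draws = as.integer(draws),
       max_fraction = max_fraction, deviation_probability = dp,
       seed = as.integer(seed))
}

#' Closed-form tail of the maximum fraction on the flat simplex
#'
#' For fractions drawn uniformly on the (k-1)-simplex, the probability that
#' the largest fraction is at least `t`, by inclusion-exclusion over the
#' k corner regions:
#' \deqn{P(\max \ge t) = \sum_{j\ge 1} (-1)^{j+1} \binom{k}{j}
#'   \max(1 - jt, 0)^{k-1}.}
#'
#' @param k number of fractions (>= 2).
#' @param t threshold in \[0, 1\].
#' @return probability.
#' @examples
#' simplex_max_tail(2, 0.75)  # 0.5
#' simplex_max_tail(3, 0.5)   # 0.75
#' @export
simplex_max_tail <- function(k, t) {
  stopifnot(k >= 2, t >= 0, t <= 1)
  j <- seq_len(k)
  sum((-1)^(j + 1) * choose(k, j) * pmax(1 - j * t, 0)^(k - 1))
}
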