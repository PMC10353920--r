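check_matrix <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("expected a square matrix", call. = FALSE)
  if (any(!is.finite(A)))
    stop("matrix has non-finite entries", call. = FALSE)
  if (any(A < 0))
    stop("matrix has negative entries", call. = FALSE)
  invisible(A)
}

# plain numeric matrix, shedding any projection_matrix attributes
bare_matrix <- function(A) {
  matrix(as.numeric(A), nrow(A), ncol(A), dimnames = dimnames(A))
}

# dominant eigenpair of a nonnegative matrix: largest-modulus eigenvalue
# restricted to (numerically) real, nonnegative candidates (Perron root)
dominant_eigen <- function(A, tol = 1e-9) {
  e <- eigen(A)
  mods <- Mod(e$values)
  real <- abs(Im(e$values)) <= tol * pmax(1, mods)
  if (!any(real)) stop("no real dominant eigenvalue found", call. = FALSE)
  cand <- which(real & Re(e$values) >= -tol)
  i <- cand[which.max(mods[cand])]
  others <- setdiff(which(real), i)
  if (length(others) > 0 && any(abs(mods[others] - mods[i]) <= tol &
                                abs(Re(e$values)[others] - Re(e$values)[i]) <=
                                  tol))
    stop("degeneracy: tied dominant eigenvalues", call. = FALSE)
  list(lambda = Re(e$values[i]), index = i, decomposition = e)
}

#' Asymptotic population growth rate
#'
#' Dominant (largest-modulus, real, nonnegative) eigenvalue of a projection
#' matrix: the asymptotic per-year multiplier of population size at the
#' stable stage structure.
#'
#' @param A nonnegative square projection matrix.
#' @return lambda, the dominant eigenvalue.
#' @examples
#' growth_rate(matrix(c(0, 0.5, 1, 0.5), 2, 2))
#' @export
growth_rate <- function(A) {
  check_matrix(A)
  dominant_eigen(bare_matrix(A))$lambda
}

#' Stable stage distribution and reproductive values
#'
#' Right and left dominant eigenvectors: `w` is the stable stage
#' distribution, scaled to sum to 1; `v` the reproductive values, scaled so
#' that the inner product of `v` and `w` is 1. Stages unreachable at the
#' stable structure (a reducible matrix) legitimately carry zero mass.
#'
#' @param A nonnegative square projection matrix.
#' @return list with elements `lambda`, `w`, `v`.
#' @export
eigen_structure <- function(A) {
  check_matrix(A)
  M <- bare_matrix(A)
  dom <- dominant_eigen(M)
  w <- Re(dom$decomposition$vectors[, dom$index])
  if (sum(w) < 0) w <- -w
  if (any(w < -1e-8 * max(abs(w))))
    stop("dominant right eigenvector not nonnegative", call. = FALSE)
  w <- pmax(w, 0)
  w <- w / sum(w)
  el <- eigen(t(M))
  j <- which.min(abs(el$values - dom$lambda))
  v <- Re(el$vectors[, j])
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)
  s <- sum(v * w)
  if (s <= 0) stop("cannot normalise reproductive values", call. = FALSE)
  v <- v / s
  names(w) <- names(v) <- rownames(M)
  list(lambda = dom$lambda, w = w, v = v)
}

#' Sensitivity and elasticity matrices
#'
#' Perturbation analysis of lambda. Sensitivities are
#' \eqn{s_{ij} = v_i w_j} (with \eqn{\langle v, w\rangle = 1});
#' elasticities, the proportional contributions of each matrix element to
#' lambda, are \eqn{e_{ij} = (a_{ij} / \lambda)\, v_i w_j}. Elasticities are
#' nonnegative, zero wherever \eqn{a_{ij} = 0}, and sum to 1 over the
#' matrix; for each stage, the elasticity row sum equals the column sum
#' (stage throughput conservation).
#'
#' @param A nonnegative square projection matrix.
#' @return a `perturbation_result`: list with `lambda`, `w`, `v`,
#'   `sensitivity` and `elasticity`.
#' @examples
#' res <- elasticity_matrix(build_matrix(eider_vital_rates()))
#' round(res$elasticity, 3)
#' @export
elasticity_matrix <- function(A) {
  es <- eigen_structure(A)
  if (es$lambda == 0)
    stop("elasticities undefined for lambda = 0", call. = FALSE)
  M <- bare_matrix(A)
  S <- outer(es$v, es$w)
  E <- (M / es$lambda) * S
  E[M == 0] <- 0
  dimnames(S) <- dimnames(E) <- dimnames(M)
  structure(list(lambda = es$lambda, w = es$w, v = es$v,
                 sensitivity = S, elasticity = E),
            class = "perturbation_result")
}

#' @export
print.perturbation_result <- function(x, digits = 4, ...) {
  cat(sprintf("<perturbation_result> lambda = %.*f\n", digits, x$lambda))
  cat("elasticities:\n")
  print(round(x$elasticity, digits), ...)
  invisible(x)
}

#' Transition grouping for the eider matrix
#'
#' Maps every structurally possible transition to one of three groups:
#' `Reproduction` (the fertility element, breeder to 1-year-old),
#' `Breeding transitions` (continued breeding, continued nonbreeding and the
#' two state switches) and `Recruitment` (every transition out of the
#' 1-year-old and prebreeder columns).
#'
#' @return data frame with columns `from`, `to`, `group`.
#' @export
eider_grouping <- function() {
  rbind(
    data.frame(from = "B", to = "1yo", group = "Reproduction"),
    data.frame(from = c("B", "B", "NB", "NB"),
               to = c("B", "NB", "B", "NB"),
               group = "Breeding transitions"),
    data.frame(from = c("1yo", "1yo", "PB2", "PB2", "PB3", "PB3", "PB4"),
               to = c("PB2", "B", "PB3", "B", "PB4", "B", "B"),
               group = "Recruitment")
  )
}

#' Summed elasticities per transition group
#'
#' Sums matrix-element elasticities over labelled transition groups. Every
#' nonzero element must be covered by exactly one group; the group sums then
#' total 1.
#'
#' @param result a `perturbation_result` from [elasticity_matrix()].
#' @param grouping data frame with columns `from`, `to`, `group`; see
#'   [eider_grouping()].
#' @return named numeric vector of summed elasticities.
#' @examples
#' res <- elasticity_matrix(build_matrix(eider_vital_rates()))
#' group_elasticities(res)
#' @export
group_elasticities <- function(result, grouping = eider_grouping()) {
  stopifnot(inherits(result, "perturbation_result"))
  E <- result$elasticity
  stopifnot(all(c("from", "to", "group") %in% names(grouping)))
  key <- paste(grouping$to, grouping$from, sep = "<-")
  if (anyDuplicated(key))
    stop("grouping maps a cell to more than one group", call. = FALSE)
  nz <- which(E != 0, arr.ind = TRUE)
  nz_key <- paste(rownames(E)[nz[, "row"]], colnames(E)[nz[, "col"]],
                  sep = "<-")
  uncovered <- setdiff(nz_key, key)
  if (length(uncovered) > 0)
    stop("grouping error: nonzero cell(s) not covered: ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  out <- vapply(split(seq_along(key), grouping$group), function(rows) {
    sum(vapply(rows, function(r) {
      to <- grouping$to[r]; from <- grouping$from[r]
      if (to %in% rownames(E) && from %in% colnames(E)) E[to, from] else 0
    }, numeric(1)))
  }, numeric(1))
  out
}

#' Headline elasticity summary of the eider matrix
#'
#' The sub-sums reported for the eider model: continued breeding (B to B),
#' the two transitions between breeding and nonbreeding states (B to NB plus
#' NB to B), continued nonbreeding (NB to NB), fertility (B to 1yo), and
#' recruitment (everything else).
#'
#' @param result a `perturbation_result` for a matrix with the eider stage
#'   labels.
#' @return named numeric vector of proportions summing to 1.
#' @examples
#' res <- elasticity_matrix(build_matrix(eider_vital_rates()))
#' as_integer_percent(eider_elasticity_summary(res))
#' @export
eider_elasticity_summary <- function(result) {
  stopifnot(inherits(result, "perturbation_result"))
  E <- result$elasticity
  stopifnot(identical(rownames(E), life_cycle_stages()))
  cb <- E["B", "B"]
  sw <- E["NB", "B"] + E["B", "NB"]
  cnb <- E["NB", "NB"]
  fert <- E["1yo", "B"]
  c(continued_breeding = cb,
    breeding_nonbreeding_switch = sw,
    continued_nonbreeding = cnb,
    fertility = fert,
    recruitment = sum(E) - cb - sw - cnb - fert)
}

#' Sweep the fertility pathways of the eider matrix
#'
#' Builds the matrix under every documented fertility pathway (the three
#' first-year-survival modes, each with and without the breeding-propensity
#' adjustment) and tabulates the resulting fertility, lambda and headline
#' elasticity percentages. Used to resolve which pathway reproduces a given
#' set of reported asymptotic results.
#'
#' @param rates a [vital_rate_set()].
#' @return data frame, one row per pathway, with columns `mode`,
#'   `propensity_adjust`, `fertility`, `lambda`, `lambda_2dp`,
#'   `continued_breeding_pct`, `switch_pct`, `continued_nonbreeding_pct`,
#'   `fertility_pct`.
#' @export
sweep_fertility_modes <- function(rates = eider_vital_rates()) {
  grid <- expand.grid(mode = c("pooled", "direct", "fledging_product"),
                      propensity_adjust = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    A <- build_matrix(rates, mode = grid$mode[i],
                      propensity_adjust = grid$propensity_adjust[i])
    res <- elasticity_matrix(A)
    s <- eider_elasticity_summary(res)
    data.frame(mode = grid$mode[i],
               propensity_adjust = grid$propensity_adjust[i],
               fertility = A["1yo", "B"],
               lambda = res$lambda,
               lambda_2dp = round_half_away(res$lambda, 2),
               continued_breeding_pct =
                 as_integer_percent(s[["continued_breeding"]]),
               switch_pct =
                 as_integer_percent(s[["breeding_nonbreeding_switch"]]),
               continued_nonbreeding_pct =
                 as_integer_percent(s[["continued_nonbreeding"]]),
               fertility_pct = as_integer_percent(s[["fertility"]]))
  })
  do.call(rbind, rows)
}
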