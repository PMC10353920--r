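#' Stage labels of the prebreeding eider life cycle
#'
#' Fixed order: `1yo` (1-year-old), `PB2`--`PB4` (2- to 4-year-old
#' prebreeders), `B` (breeder), `NB` (nonbreeder).
#'
#' @return character vector of the six stage labels.
#' @export
life_cycle_stages <- function() c("1yo", "PB2", "PB3", "PB4", "B", "NB")

#' Construct a vital-rate set
#'
#' The twelve parameters needed to build the projection matrix. First-year
#' survival may be supplied directly from hatching (`s1h`), as the product of
#' fledging success and survival from fledging (`FS`, `s1f`), or both (the
#' `pooled` fertility mode averages the two pathways). `BP2`--`BP5` are
#' conditional recruitment propensities (probability of first breeding at age
#' x given not yet recruited); `BP5` must be 1 because all individuals
#' recruit by age 5. `BPeb` is the breeding propensity of established
#' breeders; its complement routes surviving adults to the nonbreeder stage.
#'
#' @param s1h first-year survival from hatching, probability (optional).
#' @param s1f first-year survival from fledging, probability (optional).
#' @param FS fledging success, probability (optional).
#' @param s2 second-year survival, probability.
#' @param sa adult annual survival, probability.
#' @param BP2,BP3,BP4,BP5 recruitment propensity at ages 2--5 (`BP5 = 1`).
#' @param BPeb breeding propensity of established breeders, probability.
#' @param CS clutch size, eggs/nest, nonnegative.
#' @param HS hatching success, probability.
#' @return an object of class `vital_rate_set` (named list).
#' @seealso [eider_vital_rates()], [build_matrix()]
#' @export
vital_rate_set <- function(s1h = NA_real_, s1f = NA_real_, FS = NA_real_,
                           s2, sa, BP2, BP3, BP4, BP5 = 1, BPeb, CS, HS) {
  x <- list(s1h = s1h, s1f = s1f, FS = FS, s2 = s2, sa = sa,
            BP2 = BP2, BP3 = BP3, BP4 = BP4, BP5 = BP5, BPeb = BPeb,
            CS = CS, HS = HS)
  x <- lapply(x, as.numeric)
  probs <- setdiff(names(x), "CS")
  for (nm in probs) {
    if (!is.na(x[[nm]]) && (x[[nm]] < 0 || x[[nm]] > 1))
      stop(nm, " must lie in [0, 1]; got ", x[[nm]], call. = FALSE)
  }
  if (!is.na(x$CS) && x$CS < 0)
    stop("CS must be nonnegative", call. = FALSE)
  mandatory <- c("s2", "sa", "BP2", "BP3", "BP4", "BP5", "BPeb", "CS", "HS")
  miss <- mandatory[vapply(x[mandatory], is.na, logical(1))]
  if (length(miss) > 0)
    stop("missing vital rate(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (x$BP5 != 1)
    stop("BP5 must equal 1: all individuals recruit by age 5", call. = FALSE)
  if (is.na(x$s1h) && (is.na(x$s1f) || is.na(x$FS)))
    stop("first-year survival unavailable: supply s1h, or both s1f and FS",
         call. = FALSE)
  structure(x, class = "vital_rate_set")
}

#' @export
print.vital_rate_set <- function(x, ...) {
  cat("<vital_rate_set>\n")
  print(unlist(x), ...)
  invisible(x)
}

#' Published species-wide mean vital rates for the common eider
#'
#' The synthesised means used to parameterise the eider model: simple means
#' for sparsely estimated rates, precision-weighted meta-analytic means for
#' adult survival, clutch size and hatching success, all to two decimal
#' places.
#'
#' @return a [vital_rate_set()].
#' @examples
#' rates <- eider_vital_rates()
#' growth_rate(build_matrix(rates))
#' @export
eider_vital_rates <- function() {
  vital_rate_set(s1h = 0.37, s1f = 0.75, FS = 0.22,
                 s2 = 0.87, sa = 0.86,
                 BP2 = 0.17, BP3 = 0.58, BP4 = 0.71, BP5 = 1,
                 BPeb = 0.72, CS = 4.08, HS = 0.61)
}

#' Effective first-year survival
#'
#' First-year survival from hatching enters fertility either as a direct
#' estimate (`"direct"`: `s1h`), as the product of fledging success and
#' survival from fledging (`"fledging_product"`: `FS * s1f`), or -- when both
#' pathways are estimated -- as their unweighted mean (`"pooled"`).
#'
#' @param rates a [vital_rate_set()].
#' @param mode `"pooled"`, `"direct"` or `"fledging_product"`.
#' @return probability of surviving from hatching to the first census.
#' @export
effective_first_year_survival <- function(rates,
                                          mode = c("pooled", "direct",
                                                   "fledging_product")) {
  stopifnot(inherits(rates, "vital_rate_set"))
  mode <- match.arg(mode)
  direct <- function() {
    if (is.na(rates$s1h))
      stop("mode 'direct' needs s1h", call. = FALSE)
    rates$s1h
  }
  fledging <- function() {
    if (is.na(rates$s1f) || is.na(rates$FS))
      stop("mode 'fledging_product' needs both FS and s1f", call. = FALSE)
    rates$FS * rates$s1f
  }
  switch(mode,
         direct = direct(),
         fledging_product = fledging(),
         pooled = {
           if (is.na(rates$s1h)) fledging()
           else if (is.na(rates$s1f) || is.na(rates$FS)) direct()
           else mean(c(direct(), fledging()))
         })
}

#' Fertility of the breeder stage
#'
#' Expected daughters recruited to the 1-year-old stage per breeder per
#' year under a prebreeding census:
#' \deqn{F = 0.5 \cdot CS \cdot HS \cdot s_{1} \cdot [BP_{eb}]}
#' The factor 0.5 assumes an equal sex ratio at hatching. With
#' `propensity_adjust = TRUE` (the default) fertility is additionally
#' conditioned on the breeding propensity of established breeders; see the
#' methods vignette for why this reconstruction is the default.
#'
#' @inheritParams effective_first_year_survival
#' @param propensity_adjust multiply by `BPeb` (default `TRUE`).
#' @return expected surviving daughters per breeder per year (may exceed 1).
#' @examples
#' fertility(eider_vital_rates(), mode = "fledging_product",
#'           propensity_adjust = FALSE)
#' @export
fertility <- function(rates, mode = c("pooled", "direct", "fledging_product"),
                      propensity_adjust = TRUE) {
  stopifnot(inherits(rates, "vital_rate_set"))
  mode <- match.arg(mode)
  s1 <- effective_first_year_survival(rates, mode)
  0.5 * rates$CS * rates$HS * s1 * (if (propensity_adjust) rates$BPeb else 1)
}

#' Build the six-stage prebreeding projection matrix
#'
#' Assembles the female-only, prebreeding-census projection matrix over the
#' stages [life_cycle_stages()]. Entry \eqn{a_{ij}} is the contribution of
#' stage j in year t to stage i in year t+1. A surviving 1-year-old either
#' recruits (`s2 * BP2`) or becomes a 2-year-old prebreeder
#' (`s2 * (1 - BP2)`); surviving prebreeders recruit with the age-specific
#' conditional propensity or defer (all recruit by age 5); surviving adults
#' move between breeder and nonbreeder states with probabilities `BPeb` and
#' `1 - BPeb` regardless of current state (the same adult survival `sa`
#' underlies breeders and nonbreeders); only breeders reproduce, via
#' [fertility()].
#'
#' @inheritParams fertility
#' @return a `projection_matrix`: 6 x 6 numeric matrix with stage dimnames
#'   and attributes `fertility_mode` and `propensity_adjust`.
#' @examples
#' A <- build_matrix(eider_vital_rates())
#' round(A, 3)
#' @export
build_matrix <- function(rates,
                         mode = c("pooled", "direct", "fledging_product"),
                         propensity_adjust = TRUE) {
  stopifnot(inherits(rates, "vital_rate_set"))
  mode <- match.arg(mode)
  st <- life_cycle_stages()
  A <- matrix(0, 6, 6, dimnames = list(st, st))
  A["PB2", "1yo"] <- rates$s2 * (1 - rates$BP2)
  A["B", "1yo"] <- rates$s2 * rates$BP2
  A["PB3", "PB2"] <- rates$sa * (1 - rates$BP3)
  A["B", "PB2"] <- rates$sa * rates$BP3
  A["PB4", "PB3"] <- rates$sa * (1 - rates$BP4)
  A["B", "PB3"] <- rates$sa * rates$BP4
  A["B", "PB4"] <- rates$sa * rates$BP5
  A["B", "B"] <- A["B", "NB"] <- rates$sa * rates$BPeb
  A["NB", "B"] <- A["NB", "NB"] <- rates$sa * (1 - rates$BPeb)
  A["1yo", "B"] <- fertility(rates, mode, propensity_adjust)
  non_fertility <- A
  non_fertility["1yo", "B"] <- 0
  if (any(non_fertility < 0 | non_fertility > 1))
    stop("construction error: transition probability outside [0, 1]",
         call. = FALSE)
  if (A["1yo", "B"] < 0)
    stop("construction error: negative fertility", call. = FALSE)
  structure(A, class = c("projection_matrix", "matrix", "array"),
            fertility_mode = mode, propensity_adjust = propensity_adjust)
}

#' @export
print.projection_matrix <- function(x, digits = 4, ...) {
  cat(sprintf(
    "<projection_matrix> 6 x 6 prebreeding, fertility mode '%s'%s\n",
    attr(x, "fertility_mode"),
    if (isTRUE(attr(x, "propensity_adjust"))) " (propensity-adjusted)" else ""))
  y <- unclass(x)
  attributes(y)[c("fertility_mode", "propensity_adjust")] <- NULL
  print(round(y, digits), ...)
  invisible(x)
}

#' Edge list of a projection matrix
#'
#' Long-format life-cycle graph: one row per structurally possible
#' transition, matching a parameterised life-cycle diagram.
#'
#' @param A a `projection_matrix` (or any labelled square matrix).
#' @return data frame with columns `from`, `to`, `value`.
#' @export
matrix_edges <- function(A) {
  idx <- which(A != 0, arr.ind = TRUE)
  out <- data.frame(from = colnames(A)[idx[, "col"]],
                    to = rownames(A)[idx[, "row"]],
                    value = A[idx],
                    stringsAsFactors = FALSE)
  out[order(out$from, out$to), , drop = FALSE]
}
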