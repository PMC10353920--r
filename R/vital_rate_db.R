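#' Vital-rate codes understood by the evidence database
#'
#' The twelve rate codes: `s1h` first-year survival from hatching, `s1f`
#' first-year survival from fledging, `s2` second-year survival, `sa` adult
#' annual survival, `FB2`--`FB5` recruitment (first-breeding) propensity at
#' ages 2--5, `BPeb` breeding propensity of established breeders, `CS` clutch
#' size (eggs/nest), `HS` hatching success and `FS` fledging success. All are
#' probabilities in \[0, 1\] except `CS`, a nonnegative count.
#'
#' @return character vector of rate codes.
#' @export
vital_rate_codes <- function() {
  c("s1h", "s1f", "s2", "sa", "FB2", "FB3", "FB4", "FB5",
    "BPeb", "CS", "HS", "FS")
}

# legal domain per rate: probabilities except clutch size
rate_domain <- function(code) {
  if (code == "CS") c(0, Inf) else c(0, 1)
}

db_columns <- function() {
  c("study_id", "vital_rate", "value", "se", "variance", "n", "sex",
    "verified", "midpoint", "independence_group", "replicate_site",
    "replicate_year", "subspecies", "provenance")
}

db_mandatory_columns <- function() c("study_id", "vital_rate", "value")

as_flag <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[x %in% c("false", "f", "no", "n", "0")] <- FALSE
  out
}

# build + validate a vital_rate_db data.frame from loosely-typed columns;
# invalid rows are dropped with row-indexed diagnostics (or an error when
# strict = TRUE)
new_vital_rate_db <- function(df, strict = FALSE, quiet = FALSE) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(db_mandatory_columns(), names(df))
  if (length(missing_cols) > 0) {
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    study_id = as.character(df$study_id),
    vital_rate = as.character(df$vital_rate),
    value = suppressWarnings(as.numeric(df$value)),
    stringsAsFactors = FALSE
  )
  opt_num <- function(col) {
    if (col %in% names(df)) suppressWarnings(as.numeric(df[[col]])) else
      rep(NA_real_, nrow(df))
  }
  opt_chr <- function(col) {
    if (col %in% names(df)) {
      x <- as.character(df[[col]])
      x[!is.na(x) & trimws(x) == ""] <- NA_character_
      x
    } else rep(NA_character_, nrow(df))
  }
  out$se <- opt_num("se")
  out$variance <- opt_num("variance")
  out$n <- opt_num("n")
  out$sex <- opt_chr("sex")
  out$verified <- if ("verified" %in% names(df)) as_flag(df$verified) else
    rep(NA, nrow(df))
  out$midpoint <- if ("midpoint" %in% names(df)) as_flag(df$midpoint) else
    rep(NA, nrow(df))
  out$independence_group <- opt_chr("independence_group")
  out$replicate_site <- opt_chr("replicate_site")
  out$replicate_year <- opt_chr("replicate_year")
  out$subspecies <- opt_chr("subspecies")
  out$provenance <- opt_chr("provenance")
  out$provenance[is.na(out$provenance)] <- "original"

  # row-level validation
  problems <- character(0)
  bad <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    reasons <- character(0)
    if (is.na(out$study_id[i]) || trimws(out$study_id[i]) == "")
      reasons <- c(reasons, "missing study_id")
    vr <- out$vital_rate[i]
    if (is.na(vr) || !(vr %in% vital_rate_codes())) {
      reasons <- c(reasons, sprintf("unknown vital_rate '%s'", vr))
    } else if (is.na(out$value[i])) {
      reasons <- c(reasons, "unparseable value")
    } else {
      dom <- rate_domain(vr)
      if (out$value[i] < dom[1] || out$value[i] > dom[2])
        reasons <- c(reasons, sprintf(
          "value %g outside legal domain [%g, %g] for %s",
          out$value[i], dom[1], dom[2], vr))
    }
    if (!is.na(out$n[i]) && (out$n[i] <= 0 || out$n[i] != floor(out$n[i])))
      reasons <- c(reasons, "n must be a positive integer")
    if (length(reasons) > 0) {
      bad[i] <- TRUE
      problems <- c(problems, sprintf("row %d: %s", i,
                                      paste(reasons, collapse = "; ")))
    }
  }
  # se and variance both given: se wins, variance recomputed as se^2
  both <- !is.na(out$se) & !is.na(out$variance)
  inconsistent <- both & abs(out$variance - out$se^2) >
    1e-8 * pmax(1, out$variance)
  if (any(inconsistent) && !quiet) {
    warning("se and variance both present and inconsistent in row(s) ",
            paste(which(inconsistent), collapse = ", "),
            "; using variance = se^2", call. = FALSE)
  }
  out$variance[both] <- out$se[both]^2

  if (any(bad)) {
    msg <- paste0("rejected ", sum(bad), " invalid row(s):\n  ",
                  paste(problems, collapse = "\n  "))
    if (strict) stop(msg, call. = FALSE)
    if (!quiet) warning(msg, call. = FALSE)
    rejected <- out[bad, , drop = FALSE]
    out <- out[!bad, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "rejected") <- rejected
  }
  class(out) <- c("vital_rate_db", "data.frame")
  out
}

#' Read a vital-rate evidence database from CSV
#'
#' One row per published estimate. Mandatory columns: `study_id`,
#' `vital_rate` (see [vital_rate_codes()]) and `value`. Optional columns:
#' `se`, `variance` (at most one should be given; when both are present the
#' standard error wins and the variance is recomputed as `se^2`), `n` (sample
#' size), `sex` (`female`/`male`/`aggregated`), `verified` (was the estimate
#' located in its original source), `midpoint` (is the estimate the midpoint
#' of a reported range), `independence_group` (label tying estimates that
#' share underlying data), `replicate_site`, `replicate_year`, `subspecies`.
#' Missing values are empty fields; they are recorded as missing, never
#' imputed.
#'
#' Rows whose mandatory fields cannot be parsed, or whose value falls outside
#' the rate's legal domain, are rejected with row-indexed diagnostics (a
#' warning by default, an error when `strict = TRUE`); rejected rows are kept
#' in the `"rejected"` attribute of the result.
#'
#' @param path path to a UTF-8, comma-separated file with a header row.
#' @param column_map optional named character vector adapting external
#'   headers: names are the canonical column names above, values the headers
#'   found in the file, e.g. `c(study_id = "Study", value = "Estimate")`.
#' @param strict error instead of warning on invalid rows.
#' @return a `vital_rate_db` data frame.
#' @seealso [write_vital_rate_db()], [screen_records()]
#' @export
read_vital_rate_db <- function(path, column_map = NULL, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), comment.char = "#",
                        check.names = FALSE)
  if (!is.null(column_map)) {
    for (canonical in names(column_map)) {
      ext <- column_map[[canonical]]
      if (!ext %in% names(df))
        stop("column_map refers to absent column '", ext, "'", call. = FALSE)
      names(df)[names(df) == ext] <- canonical
    }
  }
  new_vital_rate_db(df, strict = strict)
}

#' Write a vital-rate database to CSV
#'
#' Emits the same schema accepted by [read_vital_rate_db()] plus the
#' `provenance` column recording how each record was obtained (`original`,
#' `sub_meta`, or the independence rule applied).
#'
#' @param records a `vital_rate_db` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vital_rate_db <- function(records, path) {
  stopifnot(inherits(records, "data.frame"))
  utils::write.csv(as.data.frame(records)[, db_columns()], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.vital_rate_db <- function(x, ...) {
  cat(sprintf("<vital_rate_db> %d estimate(s), %d stud(ies), %d rate(s)\n",
              nrow(x), length(unique(x$study_id)),
              length(unique(x$vital_rate))))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Screen an evidence database
#'
#' Applies the record-level screening policy ahead of synthesis. The default
#' policy retains unverified and range-midpoint estimates (their influence is
#' checked separately with [sensitivity_compare()]) and drops survival
#' estimates that are not female-only, because a female-only projection model
#' should not be informed by male or sex-aggregated survival.
#'
#' Records with a missing flag are never dropped by that flag (missingness is
#' not evidence). Screening is idempotent.
#'
#' @param records a `vital_rate_db` data frame.
#' @param drop_unverified drop records with `verified == FALSE`.
#' @param drop_midpoint drop records with `midpoint == TRUE`.
#' @param sexes sexes retained for survival rates (default `"female"`).
#' @param survival_rates the rate codes treated as survival for the sex
#'   filter.
#' @param quiet suppress the message reporting the number of dropped records.
#' @return the screened `vital_rate_db`; the number of dropped records is
#'   attached as attribute `"n_dropped"`.
#' @examples
#' db <- generate_database(eider_synthetic_config(seed = 1))
#' nrow(screen_records(db))
#' @export
screen_records <- function(records, drop_unverified = FALSE,
                           drop_midpoint = FALSE, sexes = "female",
                           survival_rates = c("s1h", "s1f", "s2", "sa"),
                           quiet = FALSE) {
  stopifnot(inherits(records, "data.frame"))
  drop <- logical(nrow(records))
  if (drop_unverified)
    drop <- drop | (!is.na(records$verified) & !records$verified)
  if (drop_midpoint)
    drop <- drop | (!is.na(records$midpoint) & records$midpoint)
  sex_drop <- records$vital_rate %in% survival_rates &
    !is.na(records$sex) & !(records$sex %in% sexes)
  drop <- drop | sex_drop
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(drop)
  if (!quiet && sum(drop) > 0)
    message("screen_records: dropped ", sum(drop), " record(s) (",
            sum(sex_drop), " by sex)")
  class(out) <- class(records)
  out
}

#' Resolve non-independence among estimates of one vital rate
#'
#' Where several estimates share underlying data (same `independence_group`),
#' at most one may inform the cross-study synthesis. Groups consisting of
#' spatiotemporal replicates within a single study are collapsed by
#' [sub_meta_analysis()]. Groups spanning several studies need an explicit
#' rule: `"most_precise"` keeps the record with the smallest sampling
#' variance, `"sub_meta"` forces a sub-meta-analytic collapse, and
#' `"keep:<study_id>"` keeps the named study's record. Records without an
#' `independence_group` are treated as independent.
#'
#' @param records a `vital_rate_db` data frame, all of one vital rate.
#' @param rules named character vector mapping `independence_group` labels to
#'   rules, mirroring case-by-case inclusion decisions kept alongside a
#'   database's metadata.
#' @return a `vital_rate_db` with at most one record per independence group;
#'   collapsed or selected records carry the collapse method in `provenance`.
#' @export
resolve_independence <- function(records, rules = NULL) {
  stopifnot(inherits(records, "data.frame"))
  if (nrow(records) == 0) return(records)
  if (length(unique(records$vital_rate)) > 1)
    stop("resolve_independence expects records of a single vital rate; got: ",
         paste(unique(records$vital_rate), collapse = ", "), call. = FALSE)
  grp <- records$independence_group
  grp[is.na(grp)] <- paste0(".solo.", seq_len(nrow(records)))[is.na(grp)]
  pieces <- list()
  unresolved <- character(0)
  for (g in unique(grp)) {
    rows <- records[grp == g, , drop = FALSE]
    if (nrow(rows) == 1) {
      pieces[[length(pieces) + 1]] <- rows
      next
    }
    rule <- if (!is.null(rules) && g %in% names(rules)) rules[[g]] else NULL
    single_study <- length(unique(rows$study_id)) == 1
    if (is.null(rule) && single_study) rule <- "sub_meta"
    if (is.null(rule)) {
      unresolved <- c(unresolved, g)
      next
    }
    if (identical(rule, "sub_meta")) {
      pieces[[length(pieces) + 1]] <- sub_meta_analysis(rows)
    } else if (identical(rule, "most_precise")) {
      v <- ifelse(is.na(rows$variance) & !is.na(rows$se), rows$se^2,
                  rows$variance)
      if (all(is.na(v)))
        stop("rule 'most_precise' for group '", g,
             "' but no record reports a variance", call. = FALSE)
      keep <- rows[which.min(v), , drop = FALSE]
      keep$provenance <- "rule:most_precise"
      pieces[[length(pieces) + 1]] <- keep
    } else if (startsWith(rule, "keep:")) {
      sid <- sub("^keep:", "", rule)
      keep <- rows[rows$study_id == sid, , drop = FALSE]
      if (nrow(keep) != 1)
        stop("rule '", rule, "' for group '", g, "' matches ", nrow(keep),
             " record(s)", call. = FALSE)
      keep$provenance <- paste0("rule:", rule)
      pieces[[length(pieces) + 1]] <- keep
    } else {
      stop("unknown independence rule '", rule, "' for group '", g, "'",
           call. = FALSE)
    }
  }
  if (length(unresolved) > 0)
    stop("unresolved independence group(s) with multiple studies and no ",
         "rule: ", paste(unresolved, collapse = ", "), call. = FALSE)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("vital_rate_db", "data.frame")
  out
}

#' Default mapping from vital-rate codes to eider transition groups
#'
#' A study contributes to every transition group touched by a rate it
#' estimates, so the mapping is one-to-many: first-year survival, fledging
#' success, clutch size and hatching success inform `Reproduction` (the
#' fertility element); second-year survival, adult survival and the
#' recruitment propensities inform `Recruitment` (all transitions out of the
#' prebreeder columns); adult survival and breeding propensity of established
#' breeders inform `Breeding transitions` (the four breeder/nonbreeder
#' elements).
#'
#' @return named list: rate code to character vector of group labels.
#' @export
eider_rate_groups <- function() {
  list(
    s1h = "Reproduction", s1f = "Reproduction", FS = "Reproduction",
    CS = "Reproduction", HS = "Reproduction",
    s2 = "Recruitment",
    FB2 = "Recruitment", FB3 = "Recruitment", FB4 = "Recruitment",
    FB5 = "Recruitment",
    sa = c("Recruitment", "Breeding transitions"),
    BPeb = "Breeding transitions"
  )
}

#' Count per-transition-group study effort
#'
#' A study contributes to a transition group if it supplies at least one
#' estimate of any rate mapped to that group, so studies may count toward
#' several groups and group counts need not sum to the total.
#'
#' @param records a `vital_rate_db` data frame.
#' @param grouping named list (or named character vector) mapping every
#'   vital-rate code present in `records` to one or more group labels; see
#'   [eider_rate_groups()].
#' @return a [study_effort()] table.
#' @examples
#' counts <- study_effort(
#'   c(Recruitment = 39, `Breeding transitions` = 38, Reproduction = 103),
#'   total_studies = 129)
#' fractional_effort(counts)
#' @export
count_study_effort <- function(records, grouping = eider_rate_groups()) {
  stopifnot(inherits(records, "data.frame"))
  grouping <- as.list(grouping)
  unmapped <- setdiff(unique(records$vital_rate), names(grouping))
  if (length(unmapped) > 0)
    stop("configuration error: no transition group mapped for rate(s): ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  groups <- unique(unlist(grouping, use.names = FALSE))
  counts <- vapply(groups, function(g) {
    rates <- names(grouping)[vapply(grouping, function(x) g %in% x, logical(1))]
    length(unique(records$study_id[records$vital_rate %in% rates]))
  }, integer(1))
  names(counts) <- groups
  study_effort(counts, total_studies = length(unique(records$study_id)))
}

#' Study-effort table
#'
#' Per-group unique-study counts plus the total number of unique studies
#' across all rates. Group counts may overlap across studies, so they need
#' not sum to the total, but none may exceed it.
#'
#' @param group_counts named integer vector of per-group study counts.
#' @param total_studies total number of unique studies.
#' @return an object of class `study_effort`.
#' @export
study_effort <- function(group_counts, total_studies) {
  group_counts <- vapply(group_counts, as.integer, integer(1))
  total_studies <- as.integer(total_studies)
  if (is.null(names(group_counts)) && length(group_counts) > 0)
    stop("group_counts must be named", call. = FALSE)
  if (any(group_counts < 0) || total_studies < 0)
    stop("counts must be nonnegative", call. = FALSE)
  if (any(group_counts > total_studies))
    stop("group count exceeds total_studies", call. = FALSE)
  structure(list(group_counts = group_counts,
                 total_studies = total_studies),
            class = "study_effort")
}

#' @export
print.study_effort <- function(x, ...) {
  cat(sprintf("<study_effort> %d unique stud(ies)\n", x$total_studies))
  for (g in names(x$group_counts))
    cat(sprintf("  %-22s %4d\n", g, x$group_counts[[g]]))
  invisible(x)
}
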