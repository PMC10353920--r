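#' Pipeline run configuration
#'
#' Collects everything a reproducible end-to-end run needs: exactly one
#' input source (an evidence database -- a CSV path or an in-memory
#' `vital_rate_db` -- or a ready-made vital-rate summary), the fertility
#' pathway, synthesis thresholds, the transition grouping, study-effort
#' counts where they are not derivable from the database, a seed, and the
#' output directory.
#'
#' @param database path to an evidence CSV, or a `vital_rate_db` data frame.
#' @param summary path to a per-rate summary CSV (columns `rate`, `mean`;
#'   as written by [run_meta()]), or a summary data frame, or a
#'   [vital_rate_set()]. Supply either `database` or `summary`, not both.
#' @param out_dir output directory (created if absent).
#' @param fertility_mode first-year-survival pathway for [build_matrix()].
#' @param propensity_adjust condition fertility on `BPeb`; see [fertility()].
#' @param k_min,missing_n_max method-selection thresholds; see
#'   [choose_method()].
#' @param rate_groups vital-rate to transition-group mapping for study
#'   effort; see [eider_rate_groups()].
#' @param grouping transition grouping for elasticities; see
#'   [eider_grouping()].
#' @param study_effort optional [study_effort()] table; required by
#'   [run_model()] when no database is supplied.
#' @param independence_rules named rules for [resolve_independence()].
#' @param drop_unverified,drop_midpoint screening policy flags.
#' @param seed integer seed recorded with every output.
#' @return a `run_config` list.
#' @export
run_config <- function(database = NULL, summary = NULL,
                       out_dir = tempfile("vitalsynth_run_"),
                       fertility_mode = "pooled", propensity_adjust = TRUE,
                       k_min = 20, missing_n_max = 1 / 3,
                       rate_groups = eider_rate_groups(),
                       grouping = eider_grouping(),
                       study_effort = NULL,
                       independence_rules = NULL,
                       drop_unverified = FALSE, drop_midpoint = FALSE,
                       seed = 1L) {
  if (is.null(database) == is.null(summary))
    stop("supply exactly one of 'database' or 'summary'", call. = FALSE)
  structure(list(database = database, summary = summary, out_dir = out_dir,
                 fertility_mode = fertility_mode,
                 propensity_adjust = propensity_adjust,
                 k_min = k_min, missing_n_max = missing_n_max,
                 rate_groups = rate_groups, grouping = grouping,
                 study_effort = study_effort,
                 independence_rules = independence_rules,
                 drop_unverified = drop_unverified,
                 drop_midpoint = drop_midpoint,
                 seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(config[setdiff(names(config), "out_dir")]),
                   collapse = ""), f)
  unname(tools::md5sum(f))
}

output_header <- function(config) {
  sprintf("# vitalsynth %s | config %s | seed %d",
          as.character(utils::packageVersion("vitalsynth")),
          config_hash(config), config$seed)
}

write_csv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

load_database <- function(config) {
  db <- config$database
  if (is.null(db)) stop("config has no database input", call. = FALSE)
  if (is.character(db)) db <- read_vital_rate_db(db)
  stopifnot(inherits(db, "data.frame"))
  db
}

#' Run the evidence-synthesis half of the pipeline
#'
#' Reads the database, applies the screening policy, resolves independence
#' per rate, chooses and runs the synthesis for every rate present, and
#' writes a per-rate summary (`summary.csv`: rate, n_studies, k, mean,
#' variance, method, T2) plus the study-level data behind forest and funnel
#' plots (`forest_data.csv`: rate, study, delta, v, W) for the meta-analysed
#' rates. Screening and method decisions are logged as messages. Every
#' output carries a header comment with the package version and a
#' configuration hash.
#'
#' @param config a [run_config()] with a `database` input.
#' @return the summary data frame, invisibly; also attached are the output
#'   paths in attribute `"paths"`.
#' @export
run_meta <- function(config) {
  stopifnot(inherits(config, "run_config"))
  db <- load_database(config)
  db <- screen_records(db, drop_unverified = config$drop_unverified,
                       drop_midpoint = config$drop_midpoint)
  rates_present <- intersect(vital_rate_codes(), unique(db$vital_rate))
  absent <- setdiff(vital_rate_codes(), rates_present)
  if (length(absent) > 0)
    warning("no estimates for rate(s): ", paste(absent, collapse = ", "),
            call. = FALSE)
  summary_rows <- list()
  forest_rows <- list()
  for (code in rates_present) {
    sub <- db[db$vital_rate == code, , drop = FALSE]
    class(sub) <- class(db)
    n_studies <- length(unique(sub$study_id))
    resolved <- resolve_independence(sub, rules = config$independence_rules)
    res <- synthesise_rate(resolved, k_min = config$k_min,
                           missing_n_max = config$missing_n_max)
    message(sprintf("run_meta: %s -> %s (k = %d of %d studies)", code,
                    res$method, res$k, n_studies))
    summary_rows[[code]] <- data.frame(
      rate = code, n_studies = n_studies, k = res$k, mean = res$mean,
      variance = res$variance, method = res$method,
      T2 = if (is.null(res$T2)) NA_real_ else res$T2,
      stringsAsFactors = FALSE)
    if (res$method == "meta") {
      with_n <- resolved[!is.na(resolved$n), , drop = FALSE]
      forest_rows[[code]] <- data.frame(
        rate = code, study = with_n$study_id, delta = with_n$value,
        v = res$s2_pooled / with_n$n, W = res$weights,
        stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  header <- output_header(config)
  paths <- c(summary = file.path(config$out_dir, "summary.csv"))
  write_csv_with_header(summary, paths[["summary"]], header)
  if (length(forest_rows) > 0) {
    forest <- do.call(rbind, forest_rows)
    rownames(forest) <- NULL
    paths[["forest"]] <- file.path(config$out_dir, "forest_data.csv")
    write_csv_with_header(forest, paths[["forest"]], header)
  }
  attr(summary, "paths") <- paths
  invisible(summary)
}

summary_to_rates <- function(summary) {
  if (inherits(summary, "vital_rate_set")) return(summary)
  if (is.character(summary)) {
    summary <- utils::read.csv(summary, stringsAsFactors = FALSE,
                               comment.char = "#")
  }
  stopifnot(is.data.frame(summary),
            all(c("rate", "mean") %in% names(summary)))
  means <- stats::setNames(summary$mean, summary$rate)
  code_map <- c(s1h = "s1h", s1f = "s1f", FS = "FS", s2 = "s2", sa = "sa",
                FB2 = "BP2", FB3 = "BP3", FB4 = "BP4", FB5 = "BP5",
                BPeb = "BPeb", CS = "CS", HS = "HS")
  args <- list()
  for (code in names(code_map)) {
    if (code %in% names(means)) args[[code_map[[code]]]] <- means[[code]]
  }
  needed <- c("s2", "sa", "BP2", "BP3", "BP4", "BP5", "BPeb", "CS", "HS")
  missing_codes <- setdiff(needed, names(args))
  if (length(missing_codes) > 0)
    stop("vital-rate summary incomplete; missing: ",
         paste(missing_codes, collapse = ", "), call. = FALSE)
  do.call(vital_rate_set, args)
}

#' Run the modelling half of the pipeline
#'
#' Builds the projection matrix from a vital-rate summary, runs the
#' perturbation analysis, compares grouped elasticities against fractional
#' study effort, and writes: the labelled matrix (`matrix.csv`,
#' `matrix.json`), the life-cycle edge list (`edges.csv`), lambda and the
#' grouped elasticities (`lambda_groups.json`, with lambda also rounded to
#' two decimals), the mismatch table (`mismatch.csv`) and the null contour
#' surface (`contour_grid.csv`). Study effort comes from the database when
#' one is configured, otherwise from `config$study_effort`.
#'
#' @param config a [run_config()]; its `summary` may be a summary CSV path,
#'   a summary data frame from [run_meta()], or a [vital_rate_set()]. With a
#'   `database` input the summary is computed by [run_meta()] first.
#' @return list with `rates`, `matrix`, `perturbation`, `groups`,
#'   `mismatch`, and the output `paths`.
#' @export
run_model <- function(config) {
  stopifnot(inherits(config, "run_config"))
  effort <- config$study_effort
  if (!is.null(config$database)) {
    db <- load_database(config)
    summary <- run_meta(config)
    if (is.null(effort))
      effort <- count_study_effort(
        screen_records(db, drop_unverified = config$drop_unverified,
                       drop_midpoint = config$drop_midpoint, quiet = TRUE),
        grouping = config$rate_groups)
  } else {
    summary <- config$summary
  }
  rates <- summary_to_rates(summary)
  A <- build_matrix(rates, mode = config$fertility_mode,
                    propensity_adjust = config$propensity_adjust)
  res <- elasticity_matrix(A)
  groups <- group_elasticities(res, grouping = config$grouping)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  header <- output_header(config)
  paths <- c(matrix_csv = file.path(config$out_dir, "matrix.csv"),
             matrix_json = file.path(config$out_dir, "matrix.json"),
             edges = file.path(config$out_dir, "edges.csv"),
             lambda = file.path(config$out_dir, "lambda_groups.json"),
             elasticity = file.path(config$out_dir, "elasticity.csv"),
             contour = file.path(config$out_dir, "contour_grid.csv"))
  mat_df <- data.frame(stage = rownames(A), unclass(A), check.names = FALSE)
  write_csv_with_header(mat_df, paths[["matrix_csv"]], header)
  el_df <- data.frame(stage = rownames(res$elasticity), res$elasticity,
                      check.names = FALSE)
  write_csv_with_header(el_df, paths[["elasticity"]], header)
  write_csv_with_header(matrix_edges(A), paths[["edges"]], header)
  write_csv_with_header(contour_grid(0.01), paths[["contour"]], header)
  jsonlite::write_json(
    list(header = output_header(config),
         stage_order = life_cycle_stages(),
         matrix = unname(apply(unclass(A), 1, as.numeric, simplify = FALSE))),
    paths[["matrix_json"]], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(header = output_header(config),
         lambda = res$lambda,
         lambda_2dp = round_half_away(res$lambda, 2),
         fertility_mode = config$fertility_mode,
         propensity_adjust = config$propensity_adjust,
         group_elasticities = as.list(groups),
         group_elasticities_pct =
           as.list(stats::setNames(as_integer_percent(groups),
                                   names(groups)))),
    paths[["lambda"]], auto_unbox = TRUE, digits = NA)

  mismatch <- NULL
  if (!is.null(effort)) {
    mismatch <- mismatch_table(groups, effort)
    paths[["mismatch"]] <- file.path(config$out_dir, "mismatch.csv")
    write_csv_with_header(as.data.frame(mismatch), paths[["mismatch"]],
                          header)
  }
  invisible(list(rates = rates, matrix = A, perturbation = res,
                 groups = groups, mismatch = mismatch, paths = paths))
}
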