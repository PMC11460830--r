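#' Percent (relative) difference between two odds ratios
#'
#' `100 * (or_a - or_b) / or_b`, the comparison metric for method-vs-
#' benchmark odds ratios.  Equivalently `-100 * (1 - or_a / or_b)`; note
#' the metric is not antisymmetric in its arguments.
#'
#' @param or_a,or_b positive odds ratios (vectors recycle).
#' @return percent difference of `or_a` relative to `or_b`.
#' @examples
#' relative_difference(1.42, 1.38)  # +2.9
#' relative_difference(1.42, 1.23)  # +15.4
#' @export
relative_difference <- function(or_a, or_b) {
  if (any(!is.finite(or_a)) || any(!is.finite(or_b)) ||
      any(or_a <= 0) || any(or_b <= 0))
    stop("odds ratios must be positive and finite", call. = FALSE)
  100 * (or_a - or_b) / or_b
}

#' Run replicated generate-phenotype-estimate simulations
#'
#' For each replicate: generate a dataset with seed `base_seed + i`, build
#' the analysis table, and run every requested estimation strategy.
#' Replicates whose fits fail or do not converge are recorded and excluded
#' from aggregates; if more than `max_failure_rate` of the replicate-method
#' fits fail, the run stops.
#'
#' @param config an [ehr_config()].
#' @param methods subset of `c("naive", "sufficiency", "ipw", "dag")`.
#' @param n_reps number of replicates (>= 1).
#' @param base_seed integer; replicate `i` uses seed `base_seed + i`.
#' @param exposure `"asthma"` or `"race"`.
#' @param race_handling forwarded to [model_spec()].
#' @param sufficiency sufficiency `definition_id` for the analysis table.
#' @param max_failure_rate failure tolerance before the run aborts.
#' @return object of class `sim_report`: `results` (one row per replicate
#'   x method x exposure term: `logor`, `se`, `lower`, `upper`,
#'   `converged`, `n`, `seed`), `truth` (named true log odds ratios from
#'   the generator), `config`, `methods`, `exposure`, `failures`.
#' @export
run_replicates <- function(config, methods = c("naive", "sufficiency",
                                               "ipw", "dag"),
                           n_reps, base_seed,
                           exposure = "asthma",
                           race_handling = "surrogate_imputation",
                           sufficiency = "default",
                           max_failure_rate = 0.05) {
  validate_ehr_config(config)
  stopifnot(n_reps >= 1)
  methods <- match.arg(methods, several.ok = TRUE)
  spec <- model_spec(exposure, race_handling)
  truth <- truth_log_or(config, spec)

  rows <- vector("list", n_reps * length(methods))
  failures <- list()
  k <- 0L
  for (i in seq_len(n_reps)) {
    seed_i <- base_seed + i
    ds <- generate_dataset(config, seed = seed_i)
    tab <- build_analysis_table(ds, sufficiency = sufficiency)
    for (m in methods) {
      k <- k + 1L
      res <- tryCatch({
        fit <- switch(m,
          naive = estimate_naive(tab, spec),
          sufficiency = estimate_sufficiency(tab, spec),
          ipw = estimate_ipw(tab, spec),
          dag = estimate_dag(tab, spec))
        ot <- fit$or_table
        data.frame(replicate = i, method = m, term = ot$term,
                   logor = ot$logor, se = ot$se_logor,
                   lower = ot$lower, upper = ot$upper,
                   converged = fit$converged, n = fit$n, seed = seed_i,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        failures[[length(failures) + 1]] <<- list(replicate = i, method = m,
                                                  message = conditionMessage(e))
        NULL
      })
      rows[[k]] <- res
    }
  }
  results <- do.call(rbind, rows)
  n_fail <- length(failures) +
    if (is.null(results)) 0 else sum(!results$converged)
  if (n_fail / (n_reps * length(methods)) > max_failure_rate)
    stop("more than ", 100 * max_failure_rate,
         "% of replicate fits failed or did not converge", call. = FALSE)
  structure(list(results = results, truth = truth, config = config,
                 methods = methods, exposure = exposure,
                 base_seed = base_seed, failures = failures),
            class = "sim_report")
}

# true conditional log odds ratios the estimators target, read off the
# generator configuration
truth_log_or <- function(config, spec) {
  b <- config$true_log_or$diabetes
  if (spec$exposure == "asthma") {
    c(asthma_starTRUE = unname(b["asthma"]))
  } else {
    out <- b[c("Black", "Latino", "Asian", "Other")]
    names(out) <- paste0(spec$race_var, names(out))
    out
  }
}

#' @export
print.sim_report <- function(x, ...) {
  nr <- if (is.null(x$results)) 0 else max(x$results$replicate)
  cat("<sim_report>", nr, "replicates x",
      paste(x$methods, collapse = "/"),
      "| exposure:", x$exposure,
      "| truth OR:", paste(round(exp(x$truth), 3), collapse = ", "), "\n")
  if (length(x$failures)) cat("  failures:", length(x$failures), "\n")
  invisible(x)
}

#' Aggregate a simulation report
#'
#' Per method (and exposure term): mean log-OR bias against the
#' generator's truth with its Monte Carlo standard error (`SD/sqrt(R)`),
#' the empirical SD of the estimates, the mean model-based SE, 95% CI
#' coverage of the true OR, the mean OR, and the rank of the method by
#' absolute mean bias (1 = least biased).  Only converged replicates
#' enter; their count is reported.
#'
#' @param report a `sim_report`.
#' @param benchmark_or optional named benchmark OR(s); adds the mean
#'   percent difference of each method's OR versus the benchmark.
#' @return data frame, one row per method x term.
#' @export
summarize_bias <- function(report, benchmark_or = NULL) {
  stopifnot(inherits(report, "sim_report"))
  res <- report$results
  if (is.null(res) || nrow(res) == 0)
    stop("empty simulation report", call. = FALSE)
  res <- res[res$converged, , drop = FALSE]
  truth <- report$truth
  groups <- split(res, list(res$method, res$term), drop = TRUE)
  out <- lapply(groups, function(g) {
    tr <- truth[g$term[1]]
    if (is.na(tr)) tr <- NA_real_
    bias <- g$logor - tr
    covered <- g$lower <= exp(tr) & exp(tr) <= g$upper
    data.frame(method = g$method[1], term = g$term[1],
               n_reps = nrow(g),
               true_or = exp(unname(tr)),
               mean_or = mean(exp(g$logor)),
               mean_logor = mean(g$logor),
               mean_bias = mean(bias),
               sd_logor = stats::sd(g$logor),
               mc_se = stats::sd(g$logor) / sqrt(nrow(g)),
               mean_est_se = mean(g$se),
               coverage = mean(covered),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (!is.null(benchmark_or))
    out$pct_diff_benchmark <- relative_difference(out$mean_or,
                                                  benchmark_or[1])
  out$rank_abs_bias <- stats::ave(abs(out$mean_bias), out$term,
                                  FUN = function(v) rank(v,
                                                         ties.method = "min"))
  out
}

#' Serialize / restore a simulation report
#'
#' JSON for the metadata plus a flat CSV of the per-replicate results;
#' `read_sim_report(write_sim_report(rep, dir))` reproduces the report.
#'
#' @param report a `sim_report`.
#' @param dir output directory.
#' @return `write_sim_report` returns `dir` invisibly; `read_sim_report`
#'   returns the `sim_report`.
#' @export
write_sim_report <- function(report, dir) {
  stopifnot(inherits(report, "sim_report"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir, call. = FALSE)
  utils::write.csv(report$results, file.path(dir, "results.csv"),
                   row.names = FALSE)
  cfgp <- file.path(dir, "config.yaml")
  write_ehr_config(report$config, cfgp)
  meta <- list(truth = as.list(report$truth), methods = report$methods,
               exposure = report$exposure, base_seed = report$base_seed,
               failures = report$failures)
  jsonlite::write_json(meta, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_sim_report
#' @export
read_sim_report <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "report.json"),
                              simplifyVector = TRUE)
  results <- utils::read.csv(file.path(dir, "results.csv"),
                             stringsAsFactors = FALSE)
  truth <- unlist(meta$truth)
  failures <- meta$failures
  if (length(failures) == 0) failures <- list()
  structure(list(results = results, truth = truth,
                 config = read_ehr_config(file.path(dir, "config.yaml")),
                 methods = meta$methods, exposure = meta$exposure,
                 base_seed = meta$base_seed, failures = failures),
            class = "sim_report")
}
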