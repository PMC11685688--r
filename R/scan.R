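default_thresholds <- function() {
  list(p_exposure = 5e-8, p_outcome_exclude = 5e-5, clump_r2 = 0.001,
       clump_window_kb = 100, f_flag = 20, alpha = 0.05,
       pleiotropy_max_traits = 5)
}

#' Read a run manifest from YAML
#'
#' A manifest lists the exposure and outcome summary-statistic tables of a
#' scan plus the analysis thresholds. Expected YAML structure:
#'
#' ```yaml
#' exposures:
#'   - name: IBD
#'     path: data/ibd.tsv
#'     column_map: {pvalue: PVAL}   # optional dialect remapping
#' outcomes:
#'   - name: skin_cancer
#'     path: data/skin.tsv
#' ld: ld_pairs.tsv                 # optional pairwise r2 table
#' thresholds: {p_exposure: 5.0e-8} # optional overrides
#' seed: 1
#' output_dir: results
#' ```
#'
#' @param path YAML file path.
#' @return Manifest list suitable for [run_scan()].
#' @export
read_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  if (is.null(man$exposures) || is.null(man$outcomes))
    stop("manifest must list at least one exposure and one outcome")
  man
}

# accept either an in-memory summary_dataset or a (name, path, column_map)
# manifest entry
resolve_dataset <- function(entry) {
  if (inherits(entry, "summary_dataset")) return(entry)
  cm <- if (!is.null(entry$column_map)) unlist(entry$column_map)
  read_summary_table(entry$path, column_map = cm,
                     trait_name = entry$name %||% entry$path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

dataset_name <- function(entry) {
  if (inherits(entry, "summary_dataset")) entry$trait_name
  else entry$name %||% entry$path
}

#' Run a full exposure-by-outcome Mendelian randomization scan
#'
#' For every exposure/outcome pair: select genome-wide significant
#' candidates, clump them, apply the outcome-association exclusion and
#' the cross-trait pleiotropy screen (against the scan's other
#' exposures), harmonize against the outcome, pick the estimator from the
#' instrument count, and report the odds ratio. Pairs where no instrument
#' survives yield a row with status `no_instruments`; a pair whose
#' dataset cannot be read yields status `failed` and the scan continues.
#'
#' @param manifest A list as produced by [read_manifest()], whose
#'   `exposures`/`outcomes` entries may also be in-memory
#'   [summary_dataset] objects.
#' @return Data frame of class `mr_scan`, one row per exposure-outcome
#'   pair: status, instrument funnel counts (`n_candidates`,
#'   `n_clumped`, `n_after_outcome_filter`, `n_harmonized`), `f_stat`,
#'   the selected `method`, and the estimate (`beta`, `se`, `or`,
#'   `ci_low`, `ci_high`, `pvalue`, `q_stat`, `q_df`, `q_pvalue`).
#'   If `manifest$output_dir` is set, the result table (`scan_results.tsv`)
#'   and one JSON-lines audit record per pair (`audit.jsonl`) are written
#'   there.
#' @export
run_scan <- function(manifest) {
  th <- utils::modifyList(default_thresholds(),
                          manifest$thresholds %||% list())
  ld <- manifest$ld %||% NULL
  if (is.character(ld) && length(ld) == 1 && !identical(ld, "synthetic")) {
    ld <- utils::read.delim(ld, stringsAsFactors = FALSE)
  }
  exposures <- manifest$exposures
  outcomes <- manifest$outcomes
  if (length(exposures) == 0 || length(outcomes) == 0)
    stop("manifest must list at least one exposure and one outcome")

  exp_ds <- lapply(exposures, function(e) tryCatch(resolve_dataset(e),
                                                   error = function(err) err))
  out_ds <- lapply(outcomes, function(o) tryCatch(resolve_dataset(o),
                                                  error = function(err) err))

  empty_row <- function(exp_name, out_name, status) {
    data.frame(exposure = exp_name, outcome = out_name, status = status,
               n_candidates = NA_integer_, n_clumped = NA_integer_,
               n_after_outcome_filter = NA_integer_,
               n_harmonized = NA_integer_, f_stat = NA_real_,
               method = NA_character_, k = NA_integer_, beta = NA_real_,
               se = NA_real_, or = NA_real_, ci_low = NA_real_,
               ci_high = NA_real_, pvalue = NA_real_, q_stat = NA_real_,
               q_df = NA_integer_, q_pvalue = NA_real_)
  }

  audit <- list()
  rows <- list()
  for (i in seq_along(exposures)) {
    for (j in seq_along(outcomes)) {
      en <- dataset_name(exposures[[i]]); on <- dataset_name(outcomes[[j]])
      row <- if (inherits(exp_ds[[i]], "error") ||
                 inherits(out_ds[[j]], "error")) {
        empty_row(en, on, "failed")
      } else {
        iv <- select_instruments(
          exp_ds[[i]], out_ds[[j]],
          other_exposures = exp_ds[-i][!vapply(exp_ds[-i], inherits,
                                               logical(1), "error")],
          ld = ld, p_threshold = th$p_exposure, clump_r2 = th$clump_r2,
          clump_window_kb = th$clump_window_kb,
          p_outcome_exclude = th$p_outcome_exclude,
          pleiotropy_max_traits = th$pleiotropy_max_traits,
          f_flag = th$f_flag)
        pairs <- harmonize_set(iv$snps, out_ds[[j]])
        kept <- kept_pairs(pairs)
        r <- empty_row(en, on, "ok")
        r$n_candidates <- iv$n_candidates
        r$n_clumped <- iv$n_clumped
        r$n_after_outcome_filter <- iv$n_after_outcome_filter
        r$n_harmonized <- nrow(kept)
        r$f_stat <- iv$f_stat
        if (nrow(kept) == 0) {
          r$status <- "no_instruments"
        } else {
          fit <- mr_fit(kept, alpha = th$alpha)
          r$method <- fit$method; r$k <- fit$k
          r$beta <- fit$beta; r$se <- fit$se; r$or <- fit$or
          r$ci_low <- fit$ci_low; r$ci_high <- fit$ci_high
          r$pvalue <- fit$pvalue; r$q_stat <- fit$q_stat
          r$q_df <- fit$q_df; r$q_pvalue <- fit$q_pvalue
        }
        audit[[length(audit) + 1]] <- list(
          exposure = en, outcome = on, status = r$status,
          funnel = list(candidates = iv$n_candidates,
                        clumped = iv$n_clumped,
                        after_outcome_filter = iv$n_after_outcome_filter,
                        harmonized = nrow(kept)),
          dropped = as.list(table(pairs$drop_reason[pairs$action == "dropped"])))
        r
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("mr_scan", "data.frame")
  if (all(res$status == "failed")) stop("every exposure-outcome pair failed")

  if (!is.null(manifest$output_dir)) {
    dir.create(manifest$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(res, file.path(manifest$output_dir,
                                      "scan_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    con <- file(file.path(manifest$output_dir, "audit.jsonl"), "w")
    for (a in audit) {
      writeLines(jsonlite::toJSON(a, auto_unbox = TRUE), con)
    }
    close(con)
  }
  res
}

#' @export
print.mr_scan <- function(x, ...) {
  cat(sprintf("MR scan: %d exposure-outcome pairs (%d ok, %d no_instruments, %d failed)\n",
              nrow(x), sum(x$status == "ok"),
              sum(x$status == "no_instruments"), sum(x$status == "failed")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Export forest-plot-ready data from a scan
#'
#' Writes one TSV line per estimated exposure-outcome pair with the odds
#' ratio, CI bounds, p-value, method and instrument count — enough to
#' redraw a forest plot of the scan.
#'
#' @param rows An `mr_scan` result (non-empty).
#' @param path Output TSV path.
#' @param significant_only If `TRUE`, write only rows with
#'   `pvalue < alpha`.
#' @param alpha Significance level for the filter (default 0.05).
#' @return The path, invisibly.
#' @export
export_forest_data <- function(rows, path, significant_only = FALSE,
                               alpha = 0.05) {
  if (nrow(rows) == 0) stop("no rows to export")
  keep <- rows$status == "ok"
  if (significant_only) keep <- keep & !is.na(rows$pvalue) & rows$pvalue < alpha
  out <- rows[keep, c("exposure", "outcome", "or", "ci_low", "ci_high",
                      "pvalue", "method", "k"), drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Multiple-testing adjustment across a scan
#'
#' Adds a `qvalue` column: equal to `pvalue` for `method = "none"`
#' (nominal significance, the default convention for this analysis), or
#' Benjamini-Hochberg step-up q-values across all estimated rows.
#'
#' @param rows An `mr_scan` result.
#' @param method `"none"` or `"benjamini_hochberg"`.
#' @return `rows` with a `qvalue` column.
#' @export
adjust_multiplicity <- function(rows, method = c("none",
                                                 "benjamini_hochberg")) {
  method <- match.arg(method)
  rows$qvalue <- NA_real_
  est <- !is.na(rows$pvalue)
  rows$qvalue[est] <- switch(method,
                             none = rows$pvalue[est],
                             benjamini_hochberg =
                               stats::p.adjust(rows$pvalue[est], "BH"))
  rows
}
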