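#' Read and write feature tables as CSV
#'
#' Fixed, documented column order: metadata (`call_id`, `caller_id`, `sex`,
#' `population`, `context`, `bout_id`), the ten analysis variables
#' ([call_feature_vars()]), then any auxiliary columns
#' (`call_duration_ms`, `mean_pf_all_hz`, `inter_call_interval_ms`).
#'
#' @param table Feature table.
#' @param path CSV path.
#' @return `read_feature_csv()` returns a data.frame.
#' @export
write_feature_csv <- function(table, path) {
  order <- c(intersect(.meta_vars, names(table)),
             intersect(call_feature_vars(), names(table)))
  order <- c(order, setdiff(names(table), order))
  write.csv(table[, order], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Subsample calls within calling bouts
#'
#' Caps the contribution of any one calling bout at `max_calls_per_bout`
#' calls (default 16), drawn uniformly without replacement, to limit
#' pseudo-replication from long bouts.
#'
#' @param table Feature table with a `bout_id` column.
#' @param max_calls_per_bout Cap per bout (>= 1).
#' @param seed Integer seed.
#' @return The subsampled table (original row order preserved).
#' @export
subsample_bouts <- function(table, max_calls_per_bout = 16, seed = NULL) {
  if (is.null(table$bout_id)) stop("table lacks a bout_id column",
                                   call. = FALSE)
  stopifnot(max_calls_per_bout >= 1)
  local_seed(seed)
  keep <- unlist(lapply(split(seq_len(nrow(table)), table$bout_id),
                        function(ix) {
                          if (length(ix) <= max_calls_per_bout) ix
                          else sort(sample(ix, max_calls_per_bout))
                        }))
  table[sort(unname(keep)), , drop = FALSE]
}

#' Per-context descriptive statistics
#'
#' Mean and standard error of the mean (`SEM = SD / sqrt(n)`) of each
#' analysis variable within each context, the layout of the descriptive
#' tables.
#'
#' @param table Feature table with a `context` column.
#' @param variables Variables to summarise.
#' @return Data.frame with columns `variable`, `context`, `mean`, `sem`,
#'   `n`. Singleton contexts get `NA` SEMs with a warning.
#' @export
descriptive_stats <- function(table, variables = NULL) {
  variables <- variables %||% intersect(call_feature_vars(), names(table))
  if (is.null(table$context)) stop("table lacks a context column",
                                   call. = FALSE)
  ctx <- as.character(table$context)
  out <- do.call(rbind, lapply(variables, function(v) {
    do.call(rbind, lapply(unique(ctx), function(cc) {
      x <- table[[v]][ctx == cc]
      n <- length(x)
      data.frame(variable = v, context = cc, mean = mean(x),
                 sem = if (n > 1) sd(x) / sqrt(n) else NA_real_, n = n,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (any(out$n < 2)) warning("singleton context(s): SEM undefined")
  rownames(out) <- NULL
  out
}

#' Run the analysis pipeline end-to-end
#'
#' Orchestrates feature extraction (for waveform input), bout subsampling,
#' standardization, and the requested analyses (two-step clustering, DFA
#' with leave-one-out classification, nested pDFA), writing all result
#' tables and a machine-readable summary to an output directory. Reruns
#' with an identical config and seed are bit-for-bit reproducible; every
#' output records the config hash and seed.
#'
#' @param config Named list (or path to a JSON file) with fields:
#'   `feature_csv` (or `recordings`, a list of `call_recording`s),
#'   `analyses` (subset of `"cluster"`, `"dfa"`, `"pdfa"`, or `"all"`),
#'   `out_dir`, `seed`, `max_calls_per_bout` (default 16), `sex_filter`
#'   (optional), and optional per-module parameter blocks `twostep`,
#'   `pdfa` (arguments passed through).
#' @return Invisibly, a list with the computed results and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  analyses <- config$analyses %||% "all"
  if ("all" %in% analyses) analyses <- c("cluster", "dfa", "pdfa")
  out_dir <- config$out_dir %||% stop("config$out_dir is required",
                                      call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  # hash identifies the analytic content; the output location is excluded
  hashed <- config[sort(setdiff(names(config), "out_dir"))]
  cfg_hash <- rlang::hash(hashed)

  table <- if (!is.null(config$feature_csv)) {
    read_feature_csv(config$feature_csv)
  } else if (!is.null(config$recordings)) {
    extract_feature_table(config$recordings)
  } else stop("config needs feature_csv or recordings", call. = FALSE)

  if (!is.null(config$sex_filter) && "sex" %in% names(table))
    table <- table[table$sex %in% config$sex_filter, , drop = FALSE]
  if (!is.null(table$bout_id))
    table <- subsample_bouts(table, config$max_calls_per_bout %||% 16,
                             seed = seed)
  write_feature_csv(table, file.path(out_dir, "features.csv"))

  results <- list(config_hash = cfg_hash, seed = seed,
                  n_calls = nrow(table))
  summary <- list(config_hash = cfg_hash, seed = seed,
                  n_calls = nrow(table))

  if ("cluster" %in% analyses) {
    ts_args <- c(list(table = table), config$twostep)
    sol <- do.call(fit_twostep, ts_args)
    write.csv(data.frame(call_id = table$call_id %||% seq_len(nrow(table)),
                         cluster = sol$labels),
              file.path(out_dir, "cluster_assignments.csv"),
              row.names = FALSE)
    write.csv(data.frame(k = seq_along(sol$bic_trace), bic = sol$bic_trace),
              file.path(out_dir, "bic_trace.csv"), row.names = FALSE)
    if (!is.null(table$context))
      write.csv(cluster_context_crosstab(sol, table),
                file.path(out_dir, "cluster_context_crosstab.csv"))
    results$cluster <- sol
    summary$cluster <- list(k = sol$k, silhouette_sc = sol$silhouette_sc)
  }

  if ("dfa" %in% analyses) {
    ct <- classify_loo(table)
    fit <- fit_lda(table)
    sc <- predict(fit, table)
    write.csv(ct$counts, file.path(out_dir, "confusion_counts.csv"))
    write.csv(ct$row_percent, file.path(out_dir, "confusion_percent.csv"))
    scores <- data.frame(call_id = table$call_id %||% seq_len(nrow(table)),
                         DF1 = sc$scores[, 1],
                         DF2 = if (ncol(sc$scores) >= 2) sc$scores[, 2]
                         else NA_real_,
                         true_context = table$context,
                         predicted_context = attr(ct, "predicted"))
    write.csv(scores, file.path(out_dir, "discriminant_scores.csv"),
              row.names = FALSE)
    results$dfa <- ct
    summary$dfa <- list(overall_percent_correct = ct$overall_percent_correct)
  }

  if ("pdfa" %in% analyses) {
    pd_args <- config$pdfa %||% list()
    pd_args$seed <- pd_args$seed %||% seed
    cfg <- do.call(pdfa_config, pd_args)
    res <- run_pdfa(table, config = cfg)
    write.csv(data.frame(null_statistic = res$null_statistics),
              file.path(out_dir, "pdfa_null_distribution.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(observed_statistic = res$observed_statistic,
           p_value = res$p_value, n_calls_used = res$n_calls_used,
           n_individuals_used = res$n_individuals_used,
           n_permutations = cfg$n_permutations,
           n_selections = cfg$n_selections, seed = seed,
           config_hash = cfg_hash),
      file.path(out_dir, "pdfa_result.json"), auto_unbox = TRUE,
      digits = NA)
    results$pdfa <- res
    summary$pdfa <- list(observed = res$observed_statistic,
                         p_value = res$p_value)
  }

  if (!is.null(table$context)) {
    write.csv(descriptive_stats(table),
              file.path(out_dir, "descriptive_stats.csv"), row.names = FALSE)
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}
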