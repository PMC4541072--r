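#' Configuration for the nested permuted DFA
#'
#' @param n_permutations Permutations per selection replicate (>= 100).
#' @param n_selections Random subset-selection replicates (the selection
#'   rule is stochastic only for individuals qualifying in more than one
#'   context).
#' @param min_calls_per_level Minimum calls an individual must have within
#'   a single context to be retained (>= 2; the conventional rule uses 3).
#' @param statistic Test statistic: percent correct under resubstitution
#'   (convention) or under leave-one-out.
#' @param seed Integer seed governing selections and permutations.
#' @return An object of class `pdfa_config`.
#' @export
pdfa_config <- function(n_permutations = 1000, n_selections = 100,
                        min_calls_per_level = 3,
                        statistic = c("percent_correct_resubstitution",
                                      "percent_correct_loo"),
                        seed = NULL) {
  if (n_permutations < 100) stop("n_permutations must be >= 100",
                                 call. = FALSE)
  if (min_calls_per_level < 2) stop("min_calls_per_level must be >= 2",
                                    call. = FALSE)
  structure(list(n_permutations = as.integer(n_permutations),
                 n_selections = as.integer(n_selections),
                 min_calls_per_level = as.integer(min_calls_per_level),
                 statistic = match.arg(statistic), seed = seed),
            class = "pdfa_config")
}

#' Select the analysis subset for a nested pDFA
#'
#' Applies the subject-selection rule of the nested design: calls from a
#' single individual enter only from one level of the test factor
#' (context), and only if that individual has at least
#' `min_calls_per_level` calls within that level. Individuals qualifying in
#' several contexts are assigned one of them uniformly at random (per
#' selection replicate); individuals qualifying nowhere are dropped.
#'
#' @param table Feature table.
#' @param labels Context labels (default `table$context`).
#' @param caller_ids Caller identities (default `table$caller_id`).
#' @param min_calls_per_level Minimum calls per individual within the
#'   chosen context.
#' @param seed Optional seed for the random context assignment.
#' @return The retained rows of `table`; errors with class
#'   `vocalarm_insufficient_design` if any context retains fewer than two
#'   individuals.
#' @export
pdfa_select_subset <- function(table, labels = NULL, caller_ids = NULL,
                               min_calls_per_level = 3, seed = NULL) {
  labels <- as.character(labels %||% table$context)
  caller_ids <- as.character(caller_ids %||% table$caller_id)
  if (is.null(labels) || is.null(caller_ids))
    stop("context and caller_id are required", call. = FALSE)
  local_seed(seed)
  keep <- logical(nrow(table))
  chosen <- character(0)
  for (id in unique(caller_ids)) {
    rows <- caller_ids == id
    counts <- base::table(labels[rows])
    ok <- names(counts)[counts >= min_calls_per_level]
    if (!length(ok)) next
    ctx <- if (length(ok) == 1) ok else sample(ok, 1)
    keep <- keep | (rows & labels == ctx)
    chosen[id] <- ctx
  }
  sub <- table[keep, , drop = FALSE]
  n_ind <- base::table(chosen)
  if (length(n_ind) < 2 || any(n_ind < 2))
    stop_vocalarm(
      paste0("insufficient design after subject selection: every context ",
             "needs >= 2 individuals (got: ",
             paste(names(n_ind), n_ind, sep = "=", collapse = ", "), ")"),
      "vocalarm_insufficient_design")
  attr(sub, "individual_context") <- chosen
  sub
}

# permute the individual -> context assignment, preserving the number of
# individuals per context; every individual's calls move as a block
permute_individual_contexts <- function(ind_ctx) {
  setNames(sample(unname(ind_ctx)), names(ind_ctx))
}

# classification statistic on one (sub)table: percent correct
.pdfa_statistic <- function(x, g, statistic) {
  if (statistic == "percent_correct_resubstitution") {
    fit <- fit_lda(x, g, prior = "equal")
    100 * mean(predict(fit, x)$class == g)
  } else {
    ct <- classify_loo(x, g, prior = "equal")
    100 * sum(diag(ct$counts)) / sum(ct$counts)
  }
}

#' Nested permuted discriminant function analysis
#'
#' Permutation test of context discriminability that controls for caller
#' identity: the DFA classification statistic observed on a rule-selected
#' subset (see [pdfa_select_subset()]) is compared with a null distribution
#' obtained by permuting context assignments at the level of individuals —
#' each individual's calls move between contexts as a block, preserving the
#' number of individuals per context. Variables are z-transformed before
#' analysis. The p-value per selection replicate uses the add-one rule
#' `(1 + #\{null >= observed\}) / (1 + n_permutations)` and the reported p
#' is the mean over selection replicates, so it is never exactly zero.
#'
#' Setting `permutation_unit = "call"` gives the naive (non-nested) test
#' that ignores caller identity; it is provided for the calibration
#' contrast and inflates the type-I error when calls of an individual are
#' correlated.
#'
#' @param table Feature table.
#' @param labels,caller_ids Context and caller columns (defaults from the
#'   table).
#' @param config A [pdfa_config()].
#' @param permutation_unit `"individual"` (nested; default) or `"call"`.
#' @return An object of class `pdfa_result`: `observed_statistic` (mean
#'   over selections), `null_statistics`, `p_value`, `per_selection_p`,
#'   `n_calls_used`, `n_individuals_used`, `config`.
#' @export
run_pdfa <- function(table, labels = NULL, caller_ids = NULL,
                     config = pdfa_config(),
                     permutation_unit = c("individual", "call")) {
  permutation_unit <- match.arg(permutation_unit)
  labels <- as.character(labels %||% table$context)
  caller_ids <- as.character(caller_ids %||% table$caller_id)
  local_seed(config$seed)
  vars <- intersect(call_feature_vars(), names(table))
  df <- as.data.frame(table)
  df$.context <- labels
  df$.caller <- caller_ids

  per_p <- numeric(config$n_selections)
  per_obs <- numeric(config$n_selections)
  nulls <- vector("list", config$n_selections)
  n_calls <- NA_integer_; n_ind <- NA_integer_
  for (s in seq_len(config$n_selections)) {
    sub <- pdfa_select_subset(df, df$.context, df$.caller,
                              config$min_calls_per_level)
    ind_ctx <- attr(sub, "individual_context")
    x <- feature_matrix(sub, vars)
    x <- scale(x[, apply(x, 2, sd) > 0, drop = FALSE])  # z-transform

    g <- factor(sub$.context)
    id <- sub$.caller
    n_calls <- nrow(sub); n_ind <- length(ind_ctx)

    obs <- .pdfa_statistic(x, g, config$statistic)
    null_s <- numeric(config$n_permutations)
    if (permutation_unit == "individual") {
      for (b in seq_len(config$n_permutations)) {
        perm <- permute_individual_contexts(ind_ctx)
        g_perm <- factor(perm[id], levels = levels(g))
        null_s[b] <- .pdfa_statistic(x, g_perm, config$statistic)
      }
    } else {
      for (b in seq_len(config$n_permutations)) {
        g_perm <- sample(g)
        null_s[b] <- .pdfa_statistic(x, g_perm, config$statistic)
      }
    }
    per_obs[s] <- obs
    nulls[[s]] <- null_s
    per_p[s] <- (1 + sum(null_s >= obs)) / (1 + config$n_permutations)
  }
  structure(list(observed_statistic = mean(per_obs),
                 null_statistics = unlist(nulls),
                 p_value = mean(per_p), per_selection_p = per_p,
                 n_calls_used = n_calls, n_individuals_used = n_ind,
                 permutation_unit = permutation_unit, config = config),
            class = "pdfa_result")
}

#' @export
print.pdfa_result <- function(x, ...) {
  cat(sprintf(paste0("<pdfa_result> observed = %.1f%% correct, ",
                     "p = %.4g (%d calls, %d individuals, %s-level ",
                     "permutation)\n"),
              x$observed_statistic, x$p_value, x$n_calls_used,
              x$n_individuals_used, x$permutation_unit))
  invisible(x)
}
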