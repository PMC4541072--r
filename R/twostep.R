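#' Standardize the analysis variables of a feature table
#'
#' Z-transforms each analysis variable to mean 0, SD 1, storing the centring
#' and scaling parameters as attributes so the transform can be inverted.
#'
#' @param table Feature table.
#' @param variables Variables to transform (default: the ten analysis
#'   variables present).
#' @return The table with transformed variables and attributes
#'   `"standardize_center"`, `"standardize_scale"`.
#' @export
standardize_features <- function(table, variables = NULL) {
  variables <- variables %||% intersect(call_feature_vars(), names(table))
  x <- feature_matrix(table, variables)
  if (nrow(x) < 2) stop("need at least 2 rows", call. = FALSE)
  if (anyNA(x)) stop("missing values in analysis variables", call. = FALSE)
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  zero <- scl == 0
  if (any(zero))
    stop("zero-variance variable(s): ",
         paste(variables[zero], collapse = ", "), call. = FALSE)
  table[, variables] <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  attr(table, "standardize_center") <- ctr
  attr(table, "standardize_scale") <- scl
  table
}

#' @rdname standardize_features
#' @export
unstandardize_features <- function(table) {
  ctr <- attr(table, "standardize_center")
  scl <- attr(table, "standardize_scale")
  if (is.null(ctr)) stop("table carries no standardization parameters",
                         call. = FALSE)
  vars <- names(ctr)
  table[, vars] <- sweep(sweep(as.matrix(table[, vars]), 2, scl, "*"),
                         2, ctr, "+")
  attr(table, "standardize_center") <- NULL
  attr(table, "standardize_scale") <- NULL
  table
}

# xi term of a cluster: -N_c * sum_v 0.5 * log(reg_var_v + within_var_cv),
# with within variance the biased (1/N) estimator and reg_var the overall
# per-variable variance acting as regularizer
.xi_from_stats <- function(n, s, q, reg_var) {
  wv <- pmax(q / n - (s / n)^2, 0)
  -n * sum(0.5 * log(reg_var + wv))
}

#' Log-likelihood merge distance between two clusters
#'
#' The distance used by the two-step procedure:
#' `d(a, b) = xi_a + xi_b - xi_{a union b}` with
#' `xi_c = -N_c * sum_v 0.5 * log(sigma_v^2 + sigma_cv^2)`, where
#' `sigma_v^2` is the overall variance of variable `v` (regularizer) and
#' `sigma_cv^2` the biased within-cluster variance. Always non-negative;
#' zero for clusters that merge without any increase in within-cluster
#' spread.
#'
#' @param cluster_a,cluster_b Numeric matrices (rows = calls, columns =
#'   variables).
#' @param variable_sds Overall per-variable SDs (the regularizer scale).
#' @return Non-negative real.
#' @export
loglik_distance <- function(cluster_a, cluster_b, variable_sds) {
  a <- as.matrix(cluster_a); b <- as.matrix(cluster_b)
  if (!nrow(a) || !nrow(b)) stop("clusters must be non-empty", call. = FALSE)
  reg <- variable_sds^2
  xi_a <- .xi_from_stats(nrow(a), colSums(a), colSums(a^2), reg)
  xi_b <- .xi_from_stats(nrow(b), colSums(b), colSums(b^2), reg)
  u <- rbind(a, b)
  xi_u <- .xi_from_stats(nrow(u), colSums(u), colSums(u^2), reg)
  max(xi_a + xi_b - xi_u, 0)
}

#' Two-step cluster analysis with BIC model selection
#'
#' Unsupervised call-type discovery: agglomerative merging from singletons
#' under the log-likelihood distance, with the number of clusters chosen
#' automatically (up to `k_max`, default 15) by a two-stage rule on
#' Schwarz's Bayesian Information Criterion and the merge-distance trace,
#' and the chosen solution appraised by the mean silhouette coefficient.
#'
#' `BIC(J) = -2 * sum_j xi_j + 2 J V log N` over the `J`-cluster partition
#' of the merge hierarchy (`V` = number of variables). The auto-`k` rule:
#' (1) screening keeps the largest `J` whose BIC change
#' `|BIC(J) - BIC(J-1)|` still exceeds `bic_ratio_threshold` times
#' `|BIC(2) - BIC(1)|`; (2) among `J = 2 .. J_screen` the chosen `k`
#' maximizes the ratio of successive minimum merge distances
#' `m(k-1)/m(k)` (the cost of merging below `k` relative to the cost of
#' reaching `k`), and must exceed `dist_ratio_threshold`, else `k = 1`.
#' Ties in the minimum merge distance are broken by lowest pair index.
#'
#' @param table Feature table (or plain data.frame/matrix of variables).
#' @param k_max Maximum number of clusters considered.
#' @param variables Analysis variables (default: the ten present).
#' @param standardize Z-transform variables first (recommended; the
#'   distance and silhouette are computed on the standardized scale).
#' @param bic_ratio_threshold,dist_ratio_threshold Auto-`k` thresholds.
#' @return An object of class `cluster_solution`: `k`, `labels`,
#'   `bic_trace`, `silhouette_sc`, `cluster_profiles` (per-cluster mean/SD
#'   on the original scale), `merge_distances`.
#' @export
fit_twostep <- function(table, k_max = 15, variables = NULL,
                        standardize = TRUE, bic_ratio_threshold = 0.04,
                        dist_ratio_threshold = 1.15) {
  variables <- variables %||%
    intersect(call_feature_vars(), colnames(table) %||% names(table))
  x_raw <- feature_matrix(as.data.frame(table), variables)
  n <- nrow(x_raw)
  V <- ncol(x_raw)
  if (n < 2) stop("need at least 2 rows", call. = FALSE)

  degenerate <- all(apply(x_raw, 2, function(c) diff(range(c)) == 0))
  if (degenerate) {
    return(structure(list(k = 1L, labels = rep(1L, n), bic_trace = NA_real_,
                          silhouette_sc = NA_real_,
                          cluster_profiles = .cluster_profiles(x_raw,
                                                               rep(1L, n)),
                          merge_distances = numeric(0), variables = variables),
                     class = "cluster_solution"))
  }
  x <- if (standardize) {
    scl <- apply(x_raw, 2, sd)
    if (any(scl == 0))
      stop("zero-variance variable(s): ",
           paste(variables[scl == 0], collapse = ", "), call. = FALSE)
    sweep(sweep(x_raw, 2, colMeans(x_raw)), 2, scl, "/")
  } else x_raw
  if (k_max > n) {
    warning("k_max reduced to the number of rows (", n, ")")
    k_max <- n
  }
  reg <- apply(x, 2, var)

  # per-cluster sufficient statistics; clusters indexed by original row of
  # their first member
  cnt <- rep(1, n)
  S <- x
  Q <- x^2
  xi <- vapply(seq_len(n), function(i)
    .xi_from_stats(1, S[i, ], Q[i, ], reg), numeric(1))
  active <- rep(TRUE, n)
  labels <- seq_len(n)

  dist_to <- function(j, others) {
    cu <- cnt[j] + cnt[others]
    Su <- sweep(S[others, , drop = FALSE], 2, S[j, ], "+")
    Qu <- sweep(Q[others, , drop = FALSE], 2, Q[j, ], "+")
    wv <- pmax(Qu / cu - (Su / cu)^2, 0)
    xi_u <- -cu * rowSums(0.5 * log(sweep(wv, 2, reg, "+")))
    pmax(xi[j] + xi[others] - xi_u, 0)
  }

  D <- matrix(Inf, n, n)
  for (j in seq_len(n - 1)) {
    others <- (j + 1):n
    D[j, others] <- dist_to(j, others)
  }

  total_xi <- rep(NA_real_, k_max)     # sum of xi at each level J
  labels_at <- vector("list", k_max)
  m_dist <- rep(NA_real_, n)           # m[J]: distance of merge into J clusters
  c_now <- n
  snapshot <- function(J) {
    if (J <= k_max) {
      total_xi[J] <<- sum(xi[active])
      labels_at[[J]] <<- match(labels, unique(labels))
    }
  }
  snapshot(c_now)

  while (c_now > 1) {
    # minimum-distance pair; which.min returns the lowest linear index,
    # i.e. the lowest pair index under column-major order
    idx <- which.min(D)
    b <- ((idx - 1) %/% n) + 1
    a <- idx - (b - 1) * n
    d_min <- D[a, b]
    # merge b into a
    cnt[a] <- cnt[a] + cnt[b]
    S[a, ] <- S[a, ] + S[b, ]
    Q[a, ] <- Q[a, ] + Q[b, ]
    xi[a] <- .xi_from_stats(cnt[a], S[a, ], Q[a, ], reg)
    active[b] <- FALSE
    labels[labels == b] <- a
    D[b, ] <- Inf; D[, b] <- Inf
    others <- which(active)
    others <- others[others != a]
    if (length(others)) {
      dn <- dist_to(a, others)
      lo <- others[others < a]; hi <- others[others > a]
      if (length(lo)) D[lo, a] <- dn[others < a]
      if (length(hi)) D[a, hi] <- dn[others > a]
    }
    c_now <- c_now - 1
    m_dist[c_now] <- d_min
    snapshot(c_now)
  }

  J_seq <- seq_len(k_max)
  bic <- -2 * total_xi + 2 * J_seq * V * log(n)
  k <- .choose_k(bic, m_dist, k_max, bic_ratio_threshold,
                 dist_ratio_threshold)
  lab <- labels_at[[k]]
  sc <- if (k >= 2) silhouette_sc(x, lab) else NA_real_
  structure(list(k = k, labels = lab, bic_trace = setNames(bic, J_seq),
                 silhouette_sc = sc,
                 cluster_profiles = .cluster_profiles(x_raw, lab),
                 merge_distances = m_dist[seq_len(min(k_max, n - 1))],
                 variables = variables),
            class = "cluster_solution")
}

# two-stage auto-k rule on the BIC trace and merge-distance ratios
.choose_k <- function(bic, m_dist, k_max, bic_ratio_threshold,
                      dist_ratio_threshold) {
  if (k_max < 2 || is.na(bic[2])) return(1L)
  dbic <- diff(bic)                       # dbic[J-1] = BIC(J) - BIC(J-1)
  if (dbic[1] >= 0) return(1L)            # no BIC support for any clustering
  denom <- abs(dbic[1])
  surv <- which(abs(dbic) / denom > bic_ratio_threshold) + 1L
  if (!length(surv)) return(1L)
  J_screen <- max(surv)
  cand <- 2:J_screen
  ratio <- vapply(cand, function(J) {
    below <- m_dist[J - 1]; at <- m_dist[J]
    if (is.na(below) || is.na(at)) return(NA_real_)
    if (at == 0) return(if (below > 0) Inf else 1)
    below / at
  }, numeric(1))
  if (all(is.na(ratio))) return(1L)
  best <- cand[which.max(ratio)]
  if (max(ratio, na.rm = TRUE) > dist_ratio_threshold) as.integer(best)
  else 1L
}

.cluster_profiles <- function(x, labels) {
  ks <- sort(unique(labels))
  means <- t(vapply(ks, function(k) colMeans(x[labels == k, , drop = FALSE]),
                    numeric(ncol(x))))
  sds <- t(vapply(ks, function(k) apply(x[labels == k, , drop = FALSE], 2,
                                        sd), numeric(ncol(x))))
  list(mean = means, sd = sds, n = as.integer(table(factor(labels, ks))))
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> k = %d, n = %d, silhouette S_C = %s\n",
              x$k, length(x$labels),
              if (is.na(x$silhouette_sc)) "NA"
              else sprintf("%.2f", x$silhouette_sc)))
  invisible(x)
}

#' Mean silhouette coefficient
#'
#' Mean over items of `(b - a) / max(a, b)` with Euclidean distance, where
#' `a` is the mean distance to the item's own cluster and `b` the smallest
#' mean distance to another cluster. Items in singleton clusters, and items
#' for which `max(a, b) = 0`, contribute 0.
#'
#' @param x Numeric matrix (rows = items; typically standardized
#'   variables) or feature table.
#' @param labels Cluster labels, at least two distinct.
#' @return Real in \[-1, 1\].
#' @export
silhouette_sc <- function(x, labels) {
  if (is.data.frame(x)) x <- feature_matrix(x)
  ks <- unique(labels)
  if (length(ks) < 2)
    stop("silhouette requires at least 2 clusters", call. = FALSE)
  dm <- as.matrix(dist(x))
  s <- vapply(seq_len(nrow(x)), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1) return(0)
    a <- mean(dm[i, own & seq_len(nrow(x)) != i])
    b <- min(vapply(setdiff(ks, labels[i]), function(k)
      mean(dm[i, labels == k]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Cluster-by-context contingency table
#'
#' Cross-tabulates cluster assignments against eliciting contexts, the
#' table used to read off which call types occur in which situations.
#'
#' @param solution A `cluster_solution` (or an integer label vector).
#' @param table Feature table with a `context` column.
#' @return Integer matrix (clusters x contexts).
#' @export
cluster_context_crosstab <- function(solution, table) {
  labels <- if (inherits(solution, "cluster_solution")) solution$labels
  else solution
  if (is.null(table$context)) stop("table lacks a context column",
                                   call. = FALSE)
  as.matrix(stats::xtabs(~ cluster + context,
                         data.frame(cluster = labels,
                                    context = table$context)))
}
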