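#' Linear discriminant analysis of call contexts
#'
#' Fits discriminant functions for the contexts: class means, pooled
#' within-class covariance, and up to `min(contexts - 1, variables)`
#' canonical axes maximizing the between/within variance ratio (scaled to
#' unit pooled within-class variance). All variables are entered together.
#' Priors default to equal across contexts; a near-singular pooled
#' covariance is ridged (`1e-8` on the diagonal scale) with a message.
#'
#' @param table Feature table (or matrix of variables).
#' @param labels Context labels (default: the table's `context` column).
#' @param variables Analysis variables.
#' @param prior `"equal"`, `"proportional"`, or a named numeric vector
#'   summing to 1.
#' @return An object of class `lda_model`: `class_means`,
#'   `pooled_within_cov`, `priors`, `discriminant_axes`, `eigenvalues`,
#'   `levels`, `grand_mean`.
#' @export
fit_lda <- function(table, labels = NULL, variables = NULL,
                    prior = c("equal", "proportional")) {
  labels <- labels %||% table$context
  x <- if (is.matrix(table)) table
  else feature_matrix(as.data.frame(table), variables)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (anyNA(x)) stop("missing values in analysis variables", call. = FALSE)
  g <- factor(labels)
  lev <- levels(g)
  if (length(lev) < 2) stop("need at least 2 contexts", call. = FALSE)
  n_g <- setNames(tabulate(g, nbins = length(lev)), lev)
  if (any(n_g < 2)) stop("every context needs at least 2 calls",
                         call. = FALSE)
  V <- ncol(x)
  if (any(n_g < V + 1))
    warning("context(s) with fewer calls than variables + 1: ",
            paste(lev[n_g < V + 1], collapse = ", "))
  if (is.character(prior)) {
    prior <- match.arg(prior)
    priors <- if (prior == "equal") setNames(rep(1 / length(lev),
                                                 length(lev)), lev)
    else setNames(as.numeric(n_g) / length(g), lev)
  } else {
    stopifnot(abs(sum(prior) - 1) < 1e-8)
    priors <- prior[lev]
  }

  means <- matrix(vapply(lev, function(l)
    colMeans(x[g == l, , drop = FALSE]), numeric(V)),
    nrow = length(lev), byrow = TRUE,
    dimnames = list(lev, colnames(x)))
  W <- matrix(0, V, V)
  for (l in lev) {
    xc <- sweep(x[g == l, , drop = FALSE], 2, means[l, ])
    W <- W + crossprod(xc)
  }
  W <- W / (nrow(x) - length(lev))
  # conditioning is judged scale-free (on the within-class correlation
  # matrix) so that affine rescaling of a variable cannot trigger the ridge
  dw <- sqrt(diag(W))
  if (any(dw == 0) || rcond(W / tcrossprod(dw)) < 1e-12) {
    eps <- 1e-8 * mean(diag(W))
    if (eps == 0) eps <- 1e-8
    W <- W + diag(eps, V)
    message("pooled within-class covariance near-singular; ridge ", eps,
            " applied (consider reducing variables)")
    dw <- sqrt(diag(W))
    if (rcond(W / tcrossprod(dw)) < 1e-14)
      stop("pooled within-class covariance singular even after ridge; ",
           "reduce the variable set", call. = FALSE)
  }

  gm <- colMeans(means)                 # unweighted grand mean of class means
  B <- crossprod(sweep(means, 2, gm) * sqrt(as.numeric(n_g))) /
    max(length(lev) - 1, 1)
  # canonical axes: eigen of W^-1 B, symmetrized via Cholesky whitening
  cw <- chol(W)
  M <- backsolve(cw, t(backsolve(cw, t(B), transpose = TRUE)),
                 transpose = TRUE)
  eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
  r <- min(length(lev) - 1, V)
  axes <- backsolve(cw, eig$vectors[, seq_len(r), drop = FALSE])
  # scale to unit within-class variance along each axis
  scl <- sqrt(diag(t(axes) %*% W %*% axes))
  axes <- sweep(axes, 2, scl, "/")
  dimnames(axes) <- list(colnames(x), paste0("DF", seq_len(r)))

  structure(list(class_means = means, pooled_within_cov = W,
                 priors = priors, discriminant_axes = axes,
                 eigenvalues = eig$values[seq_len(r)], levels = lev,
                 grand_mean = gm, variables = colnames(x)),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d contexts, %d variables, %d axes\n",
              length(x$levels), length(x$variables),
              ncol(x$discriminant_axes)))
  invisible(x)
}

#' Predict contexts and discriminant scores
#'
#' Classifies by the linear discriminant rule (Mahalanobis distance to the
#' class means under the pooled covariance, plus log prior) and returns the
#' scores on the canonical axes.
#'
#' @param object An `lda_model`.
#' @param newdata Feature table or matrix.
#' @param ... Unused.
#' @return List with `class` (factor) and `scores` (matrix, columns
#'   `DF1`, `DF2`, ...).
#' @export
predict.lda_model <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) {
    if (is.null(colnames(newdata))) newdata
    else newdata[, object$variables, drop = FALSE]
  } else feature_matrix(as.data.frame(newdata), object$variables)
  W <- object$pooled_within_cov
  dw <- sqrt(diag(W))                 # equilibrated, scale-free inverse
  Winv <- solve(W / tcrossprod(dw)) / tcrossprod(dw)
  M <- object$class_means
  # delta_g(x) = x' W^-1 m_g - 0.5 m_g' W^-1 m_g + log prior_g
  lin <- x %*% Winv %*% t(M)
  const <- -0.5 * rowSums((M %*% Winv) * M) + log(object$priors)
  delta <- sweep(lin, 2, const, "+")
  cls <- factor(object$levels[max.col(delta, ties.method = "first")],
                levels = object$levels)
  scores <- sweep(x, 2, object$grand_mean) %*% object$discriminant_axes
  list(class = cls, scores = scores)
}

#' Leave-one-out (jackknifed) classification
#'
#' Cross-validated context classification: each call is classified by a
#' discriminant model refitted on all other calls (exact refits, no
#' downdating shortcut), and the held-out predictions are accumulated into
#' a confusion table.
#'
#' @inheritParams fit_lda
#' @return A `confusion_table` (see [confusion_report()]) with attribute
#'   `"predicted"` (per-call held-out predictions).
#' @export
classify_loo <- function(table, labels = NULL, variables = NULL,
                         prior = "equal") {
  labels <- labels %||% table$context
  x <- if (is.matrix(table)) table
  else feature_matrix(as.data.frame(table), variables)
  g <- factor(labels)
  if (any(tabulate(g) < 3))
    stop("leave-one-out requires at least 3 calls per context ",
         "(hold-out must leave 2)", call. = FALSE)
  pred <- factor(rep(NA_character_, nrow(x)), levels = levels(g))
  for (i in seq_len(nrow(x))) {
    fit <- fit_lda(x[-i, , drop = FALSE], g[-i], prior = prior)
    pred[i] <- predict(fit, x[i, , drop = FALSE])$class
  }
  counts <- as.matrix(stats::xtabs(~ true + predicted,
                                   data.frame(true = g, predicted = pred)))
  out <- confusion_report(counts)
  attr(out, "predicted") <- pred
  out
}

#' Confusion table with row percentages and overall accuracy
#'
#' Formats a square classification count matrix (rows = true context,
#' columns = predicted) the way discriminant classification results are
#' conventionally reported: per-row percentages and the overall percent
#' correct, both rounded half-up to one decimal.
#'
#' @param counts Square matrix of non-negative integers.
#' @return An object of class `confusion_table`: `counts`, `row_percent`,
#'   `overall_percent_correct`.
#' @export
confusion_report <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), all(counts >= 0))
  storage.mode(counts) <- "integer"
  rs <- rowSums(counts)
  pct <- counts / rs * 100
  if (any(rs == 0)) {
    warning("context(s) with zero calls: percentage rows undefined")
    pct[rs == 0, ] <- NA_real_
  }
  structure(list(counts = counts,
                 row_percent = round_half_up(pct, 1),
                 overall_percent_correct =
                   round_half_up(100 * sum(diag(counts)) / sum(counts), 1)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat("Classification counts (rows = true context):\n")
  print(x$counts)
  cat("\nRow percentages:\n")
  print(x$row_percent)
  cat(sprintf("\nOverall percent correct (cross-validated): %.1f\n",
              x$overall_percent_correct))
  invisible(x)
}
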