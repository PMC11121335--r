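#' Fit linear epsilon-insensitive support-vector regression
#'
#' Minimizes the soft-interval objective
#' \deqn{\tfrac12\|\omega\|^2 + C\sum_i(\xi_i + \hat\xi_i)}
#' subject to every training pair lying within \eqn{\varepsilon} of the
#' regression line up to its slack, i.e. the standard linear
#' \eqn{\varepsilon}-SVR quadratic program. The solver works on the dual in
#' \eqn{\beta_i = \alpha_i - \hat\alpha_i} by deterministic pairwise
#' coordinate descent with exact line search, so refitting identical input
#' reproduces the model bit-for-bit. The intercept is recovered exactly from
#' the interior support vectors (or, if none, by minimizing the
#' piecewise-linear loss in the intercept alone over its breakpoints).
#'
#' @param x A `ddcm_hybrid` training matrix, or a plain numeric matrix.
#' @param y Response vector; ignored (taken from `x$labels`) when `x` is a
#'   `ddcm_hybrid`. In the repositioning pipeline labels are 1 for known
#'   therapeutic pairs and 0 for sampled non-known pairs.
#' @param epsilon Half-width of the insensitive tube (default 0.1).
#' @param cost Box constraint C > 0 on the dual variables (default 1).
#' @param tol Convergence tolerance on the maximal KKT violation.
#' @param max_iter Iteration cap for the dual solver.
#' @return A `ddcm_svr` model: `weights` (named by feature column),
#'   `intercept`, `epsilon`, `cost`, `columns`, `beta` (dual solution),
#'   `objective` (primal value at the solution), and convergence metadata.
#' @export
#' @examples
#' m <- fit_svr(matrix(c(0, 10), ncol = 1), c(0, 20), cost = 1000)
#' c(m$weights, m$intercept)  # ~ (1.98, 0.1)
fit_svr <- function(x, y = NULL, epsilon = 0.1, cost = 1,
                    tol = 1e-8, max_iter = 1000000L) {
  if (inherits(x, "ddcm_hybrid")) {
    if (is.null(x$labels)) stop("fit_svr: hybrid matrix has no labels")
    y <- x$labels
    X <- x$X
  } else {
    X <- as.matrix(x)
  }
  if (is.null(y)) stop("fit_svr: no response supplied")
  if (nrow(X) < 2L) stop("fit_svr: need at least 2 training rows")
  if (length(y) != nrow(X)) stop("fit_svr: length(y) != nrow(x)")
  if (!all(is.finite(X))) stop("fit_svr: non-finite feature values")
  if (!all(is.finite(y))) stop("fit_svr: non-finite response values")
  if (epsilon < 0) stop("fit_svr: epsilon must be >= 0")
  if (cost <= 0) stop("fit_svr: cost must be > 0")

  K <- tcrossprod(X)
  sol <- svr_smo_cpp(K, as.numeric(y), cost, epsilon, tol, as.integer(max_iter))
  if (!sol$converged)
    stop("fit_svr: dual solver did not converge within ", max_iter,
         " iterations (final problem size ", nrow(X), " x ", ncol(X), ")")
  beta <- sol$beta
  w <- drop(crossprod(X, beta))
  names(w) <- colnames(X)

  # Intercept: interior support vectors pin f(x_i) = y_i - eps * sign(beta_i)
  fx <- drop(X %*% w)
  interior <- which(abs(beta) > 1e-8 & abs(beta) < cost - 1e-8)
  if (length(interior)) {
    phi <- mean(y[interior] - epsilon * sign(beta[interior]) - fx[interior])
  } else {
    bp <- sort(unique(c(y - fx - epsilon, y - fx + epsilon)))
    loss <- vapply(bp, function(b) sum(pmax(abs(fx + b - y) - epsilon, 0)), 0)
    flat <- bp[loss <= min(loss) + 1e-12]
    phi <- mean(range(flat))
  }

  structure(list(
    weights = w, intercept = phi, epsilon = epsilon, cost = cost,
    columns = colnames(X), beta = beta,
    objective = svr_objective(w, phi, X, y, cost, epsilon),
    iterations = sol$iterations, n_train = nrow(X)
  ), class = "ddcm_svr")
}

#' Primal objective of a linear epsilon-SVR solution
#'
#' \eqn{\tfrac12\|\omega\|^2 + C\sum_i \max(|f(x_i) - y_i| - \varepsilon, 0)}.
#' Exposed so independent solvers can be compared on equal footing.
#'
#' @param w Weight vector.
#' @param phi Intercept.
#' @param X Feature matrix.
#' @param y Response vector.
#' @param cost,epsilon SVR parameters.
#' @return The objective value.
#' @export
svr_objective <- function(w, phi, X, y, cost, epsilon) {
  r <- abs(drop(X %*% w) + phi - y) - epsilon
  0.5 * sum(w^2) + cost * sum(pmax(r, 0))
}

#' @export
print.ddcm_svr <- function(x, ...) {
  cat("ddcm_svr: linear eps-SVR, ", length(x$weights), " features, eps = ",
      x$epsilon, ", C = ", x$cost, "\n", sep = "")
  cat("  trained on ", x$n_train, " rows; objective ",
      format(x$objective, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Predict disease-drug correlation scores
#'
#' Scores are the fitted linear form \eqn{f(x) = \langle\omega, x\rangle + \varphi}
#' applied to each feature row.
#'
#' @param object A `ddcm_svr` model.
#' @param newdata A `ddcm_hybrid` query matrix or a plain matrix with the
#'   model's column layout.
#' @param ... Unused.
#' @return Numeric vector of scores, one per row.
#' @export
predict.ddcm_svr <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "ddcm_hybrid")) newdata$X else as.matrix(newdata)
  if (ncol(X) != length(object$weights))
    stop("predict.ddcm_svr: feature dimension mismatch (",
         ncol(X), " vs ", length(object$weights), ")")
  if (!is.null(colnames(X)) && !identical(colnames(X), object$columns))
    stop("predict.ddcm_svr: column layout differs from the fitted model")
  drop(X %*% object$weights) + object$intercept
}

#' Score every drug for one disease
#'
#' Builds the query rows for the disease against the given drugs, applies
#' the fitted model, and de-redundantly aggregates: when a drug receives
#' multiple scores (duplicate candidate rows), the highest correlation score
#' is kept.
#'
#' @param model A fitted `ddcm_svr`.
#' @param disease_id Query disease.
#' @param drug_sim,disease_sim Combined similarity matrices (same layout the
#'   model was trained on).
#' @param drugs Drug IDs to score; default all drugs in `drug_sim`.
#' @return A `ddcm_scores` data frame: `disease_id`, `drug_id`, `score`,
#'   one row per drug, ordered by descending score with ties broken by
#'   ascending drug ID.
#' @export
score_disease <- function(model, disease_id, drug_sim, disease_sim,
                          drugs = NULL) {
  drugs <- drugs %||% drug_sim$ids
  q <- build_query_matrix(disease_id, drugs, drug_sim, disease_sim)
  s <- predict(model, q)
  agg <- tapply(s, q$pairs$drug_id, max)
  out <- data.frame(disease_id = disease_id,
                    drug_id = names(agg),
                    score = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$drug_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ddcm_scores", "data.frame")
  out
}

#' Serialize a fitted model to JSON
#'
#' @param model A `ddcm_svr`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(list(
    weights = as.list(stats::setNames(as.numeric(model$weights), model$columns)),
    intercept = model$intercept, epsilon = model$epsilon, cost = model$cost,
    n_train = model$n_train, objective = model$objective
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
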