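# Classifiers: L2-penalised logistic regression and a random forest.
#
# No random-forest dependency exists in the target environment, so the forest
# is implemented in C++ (src/rf.cpp): fully grown CART trees, Gini splits,
# bootstrap resampling, mtry features per split, per-tree majority vote
# averaged to a positive-class score. Logistic regression minimises
# sum_i log(1 + exp(-y_i eta_i)) + ||w||^2 / (2C) (intercept unpenalised)
# by L-BFGS, matching the usual inverse-regularization C parameterisation.

LR_SOLVERS <- c("saga", "lbfgs")

#' Build a model specification
#'
#' `tuned = FALSE` gives the conventional library defaults (logistic
#' regression: C = 1, max_iter = 100, solver "lbfgs"; random forest:
#' 100 trees, max_features "sqrt"). `tuned = TRUE` gives the optimized
#' configurations found by randomized search: logistic regression with
#' C = 11.29, max_iter = 2500 and the "saga" solver; random forest with
#' max_features "sqrt" and 1000 trees.
#'
#' The solver name is carried as metadata; one deterministic L-BFGS
#' optimizer is used for fitting either way (see the methods vignette).
#'
#' @param family "logistic_regression" or "random_forest".
#' @param tuned use the tuned configuration (default FALSE).
#' @param seed integer seed stored in the spec; governs all fitting
#'   randomness.
#' @return A `model_spec` object.
#' @export
make_spec <- function(family = c("logistic_regression", "random_forest"),
                      tuned = FALSE, seed = 1L) {
  if (is.character(family) && !family[1] %in%
      c("logistic_regression", "random_forest"))
    stop("unknown-model error: ", family[1], call. = FALSE)
  family <- match.arg(family)
  hp <- if (family == "logistic_regression") {
    if (tuned) list(C = 11.29, max_iter = 2500L, solver = "saga")
    else list(C = 1, max_iter = 100L, solver = "lbfgs")
  } else {
    if (tuned) list(n_estimators = 1000L, max_features = "sqrt")
    else list(n_estimators = 100L, max_features = "sqrt")
  }
  model_spec(family, hp, seed = seed, tuned = tuned)
}

#' Assemble a model specification from explicit hyperparameters
#'
#' @param family model family.
#' @param hyperparameters named list — logistic regression: `C` (> 0),
#'   `max_iter` (>= 1), `solver` ("saga" or "lbfgs"); random forest:
#'   `n_estimators` (>= 1), `max_features` ("sqrt", "log2", "all", or a
#'   fraction in (0, 1]).
#' @param seed integer seed.
#' @param tuned bookkeeping flag.
#' @return A `model_spec` object.
#' @export
model_spec <- function(family, hyperparameters, seed = 1L, tuned = FALSE) {
  family <- match.arg(family, c("logistic_regression", "random_forest"))
  hp <- hyperparameters
  if (family == "logistic_regression") {
    stopifnot(hp$C > 0, hp$max_iter >= 1)
    if (!hp$solver %in% LR_SOLVERS)
      stop("unknown solver: ", hp$solver, call. = FALSE)
  } else {
    stopifnot(hp$n_estimators >= 1)
    mf <- hp$max_features
    ok <- (is.character(mf) && mf %in% c("sqrt", "log2", "all")) ||
      (is.numeric(mf) && mf > 0 && mf <= 1)
    if (!ok) stop("invalid max_features rule: ", mf, call. = FALSE)
  }
  structure(list(family = family, hyperparameters = hp,
                 seed = as.integer(seed), tuned = isTRUE(tuned)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  hp <- paste(names(x$hyperparameters),
              vapply(x$hyperparameters, format, ""), sep = "=",
              collapse = ", ")
  cat(sprintf("%s (%s) [%s, seed %d]\n", x$family,
              if (x$tuned) "tuned" else "default", hp, x$seed))
  invisible(x)
}

# Number of candidate features per split under a max_features rule.
resolve_mtry <- function(rule, p) {
  m <- if (identical(rule, "sqrt")) floor(sqrt(p))
  else if (identical(rule, "log2")) floor(log2(p))
  else if (identical(rule, "all")) p
  else floor(rule * p)
  max(1L, min(p, as.integer(m)))
}

fm_values <- function(X) {
  if (inherits(X, "feature_matrix")) X$values else as.matrix(X)
}

fm_labels <- function(X, labels) {
  if (!is.null(labels)) as.integer(labels)
  else if (inherits(X, "feature_matrix")) as.integer(X$labels)
  else stop("labels required when X is a bare matrix", call. = FALSE)
}

#' Fit a classifier
#'
#' Deterministic for a fixed `(spec$seed, X)`: logistic regression starts from
#' zero coefficients, and the forest uses its own seeded RNG stream
#' independent of R's global RNG.
#'
#' @param spec a `model_spec`.
#' @param X a `feature_matrix` (or a bare numeric matrix with `labels`
#'   supplied).
#' @param labels optional 0/1 vector overriding `X$labels`.
#' @return A `fitted_model`.
#' @export
fit <- function(spec, X, labels = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  vals <- fm_values(X)
  y <- fm_labels(X, labels)
  if (nrow(vals) < 2L) stop("need at least 2 records", call. = FALSE)
  if (length(y) != nrow(vals))
    stop("labels/rows mismatch", call. = FALSE)
  if (!all(y %in% c(0L, 1L)) || length(unique(y)) < 2L)
    stop("missing-class error: training set must contain both classes",
         call. = FALSE)
  if (!all(is.finite(vals)))
    stop("invalid-feature error: non-finite feature values", call. = FALSE)

  state <- if (spec$family == "logistic_regression") {
    fit_logreg(vals, y, C = spec$hyperparameters$C,
               max_iter = spec$hyperparameters$max_iter)
  } else {
    mtry <- resolve_mtry(spec$hyperparameters$max_features, ncol(vals))
    .rf_fit_cpp(vals, y, as.integer(spec$hyperparameters$n_estimators),
                mtry, 2L, as.double(spec$seed))
  }
  structure(list(spec = spec, state = state,
                 n_features_expected = ncol(vals)),
            class = "fitted_model")
}

fit_logreg <- function(X, y, C, max_iter) {
  yt <- ifelse(y == 1L, 1, -1)
  p <- ncol(X)
  # stable log(1 + exp(z))
  log1pexp <- function(z) ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
  obj <- function(par) {
    w <- par[-1L]
    eta <- drop(X %*% w) + par[1L]
    sum(log1pexp(-yt * eta)) + sum(w^2) / (2 * C)
  }
  grad <- function(par) {
    w <- par[-1L]
    eta <- drop(X %*% w) + par[1L]
    r <- -yt * stats::plogis(-yt * eta)   # d loss / d eta
    c(sum(r), drop(crossprod(X, r)) + w / C)
  }
  res <- optim(rep(0, p + 1L), obj, grad, method = "L-BFGS-B",
               control = list(maxit = as.integer(max_iter)))
  list(intercept = res$par[1L], coef = res$par[-1L],
       converged = res$convergence == 0L)
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("fitted %s on %d features\n", x$spec$family,
              x$n_features_expected))
  invisible(x)
}

#' Positive-class scores
#'
#' Logistic regression returns the fitted sigmoid probability; the random
#' forest returns the fraction of trees voting positive. Hard labels are
#' obtained downstream by thresholding at 0.5.
#'
#' @param model a `fitted_model`.
#' @param X a `feature_matrix` or numeric matrix with matching feature count.
#' @return numeric score vector in \[0, 1\].
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "fitted_model"))
  vals <- fm_values(X)
  if (ncol(vals) != model$n_features_expected)
    stop("dimension error: model expects ", model$n_features_expected,
         " features, got ", ncol(vals), call. = FALSE)
  if (model$spec$family == "logistic_regression") {
    stats::plogis(drop(vals %*% model$state$coef) + model$state$intercept)
  } else {
    .rf_predict_cpp(model$state, vals)
  }
}

# Hyperparameter search spaces (the source study states none; these contain
# the winning tuned points). LR: C log-uniform on [1e-2, 1e3], max_iter in
# {500,1000,2500,5000}, solver in {saga, lbfgs}. RF: n_estimators in
# {100,250,500,1000}, max_features in {sqrt, log2, 0.5}.
sample_search_point <- function(family) {
  if (family == "logistic_regression") {
    list(C = 10^runif(1, -2, 3),
         max_iter = sample(c(500L, 1000L, 2500L, 5000L), 1),
         solver = sample(LR_SOLVERS, 1))
  } else {
    list(n_estimators = sample(c(100L, 250L, 500L, 1000L), 1),
         max_features = sample(list("sqrt", "log2", 0.5), 1)[[1]])
  }
}

#' Randomized hyperparameter search
#'
#' Samples `n_iter` hyperparameter points from the documented space, scores
#' each by mean k-fold cross-validated accuracy on `X`, and returns the best
#' spec together with the full search table. Deterministic given `seed`.
#'
#' @param family model family.
#' @param X a `feature_matrix` with labels.
#' @param n_iter number of sampled points (default 25).
#' @param seed integer RNG seed.
#' @param folds number of CV folds (default 5).
#' @return list with `best_spec` (a `model_spec`) and `table` (a data frame
#'   of sampled points and their mean CV accuracy).
#' @export
randomized_search <- function(family = c("logistic_regression",
                                         "random_forest"),
                              X, n_iter = 25L, seed = 1L, folds = 5L) {
  family <- match.arg(family)
  stopifnot(inherits(X, "feature_matrix"), n_iter >= 1L, folds >= 2L)
  points <- with_local_seed(seed, lapply(seq_len(n_iter), function(i)
    sample_search_point(family)))
  rows <- vector("list", n_iter)
  scores <- rep(NA_real_, n_iter)
  for (i in seq_len(n_iter)) {
    spec_i <- model_spec(family, points[[i]], seed = seed, tuned = TRUE)
    acc <- tryCatch(
      cv_accuracy_fm(X, spec_i, k = folds, seed = seed),
      error = function(e) NA_real_)
    scores[i] <- acc
    rows[[i]] <- data.frame(iter = i,
                            lapply(points[[i]], function(v)
                              if (is.numeric(v)) v else as.character(v)),
                            mean_cv_accuracy = acc,
                            stringsAsFactors = FALSE)
  }
  if (all(is.na(scores)))
    stop("search-failed error: every sampled point failed", call. = FALSE)
  best <- which.max(scores)
  list(best_spec = model_spec(family, points[[best]], seed = seed,
                              tuned = TRUE),
       table = do.call(rbind, rows))
}

#' Persist a model specification (or search table) as JSON
#' @param spec a `model_spec`.
#' @param path output path, or NULL to return the JSON string.
#' @return JSON string (invisibly when written).
#' @export
spec_to_json <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  js <- jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
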