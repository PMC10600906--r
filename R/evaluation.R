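# Evaluation: confusion counts, the five metrics, stratified k-fold CV,
# and the cross-species transfer protocol.

#' Tabulate a 2x2 confusion matrix
#'
#' Class 1 is the positive (6mA) class.
#'
#' @param y_true 0/1 true labels.
#' @param y_pred 0/1 predicted labels.
#' @return A `confusion_counts` list with TP, TN, FP, FN.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("dimension error: y_true and y_pred lengths differ", call. = FALSE)
  if (length(y_true) < 1L) stop("empty-evaluation error", call. = FALSE)
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  structure(list(TP = sum(y_true == 1L & y_pred == 1L),
                 TN = sum(y_true == 0L & y_pred == 0L),
                 FP = sum(y_true == 0L & y_pred == 1L),
                 FN = sum(y_true == 1L & y_pred == 0L)),
            class = "confusion_counts")
}

#' Threshold-based classification metrics
#'
#' Acc = (TP+TN)/total, Sens = TP/(TP+FN), Spec = TN/(TN+FP),
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' A metric whose denominator is zero is reported as 0 and flagged in
#' `degenerate`, so reports stay finite and serializable.
#'
#' @param counts a `confusion_counts`.
#' @return list with `Acc`, `Sens`, `Spec`, `MCC`, and `degenerate` (character
#'   vector naming zero-denominator metrics, possibly empty).
#' @export
metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- as.numeric(counts$TP); tn <- as.numeric(counts$TN)
  fp <- as.numeric(counts$FP); fn <- as.numeric(counts$FN)
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty-evaluation error", call. = FALSE)
  degenerate <- character(0)
  acc <- (tp + tn) / total
  sens <- if (tp + fn > 0) tp / (tp + fn) else {
    degenerate <- c(degenerate, "Sens"); 0
  }
  spec <- if (tn + fp > 0) tn / (tn + fp) else {
    degenerate <- c(degenerate, "Spec"); 0
  }
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else {
    degenerate <- c(degenerate, "MCC"); 0
  }
  list(Acc = acc, Sens = sens, Spec = spec, MCC = mcc,
       degenerate = degenerate)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator: the probability that a random
#' positive outscores a random negative, with ties counted one half. Equals
#' the trapezoidal area under the ROC curve.
#'
#' @param y_true 0/1 labels containing both classes.
#' @param scores numeric scores.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(y_true, scores) {
  if (length(y_true) != length(scores))
    stop("dimension error: labels and scores lengths differ", call. = FALSE)
  y_true <- as.integer(y_true)
  n_pos <- sum(y_true == 1L)
  n_neg <- sum(y_true == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("undefined-AUC error: both classes required", call. = FALSE)
  r <- rank(scores)  # average ranks handle ties at 1/2
  (sum(r[y_true == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Stratified k-fold assignment
#'
#' Per-class seeded shuffle followed by round-robin assignment, so folds
#' partition the records and per-class counts across folds differ by at
#' most 1. Deterministic given `seed`.
#'
#' @param labels 0/1 label vector (or a `seq_records` data frame).
#' @param k number of folds (>= 2).
#' @param seed integer RNG seed.
#' @return integer vector of fold ids in 1..k, one per record.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  if (inherits(labels, "seq_records")) labels <- labels$label
  labels <- as.integer(labels)
  stopifnot(k >= 2L)
  folds <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    if (length(idx) < k)
      stop("stratification error: class ", cls, " has ", length(idx),
           " members for k=", k, call. = FALSE)
    shuffled <- with_local_seed(seed + cls, sample(idx))
    folds[shuffled] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# Per-fold evaluation shared by cross_validate and randomized_search.
# Returns a data frame of per-fold counts + metrics.
fold_eval <- function(vals, y, spec, folds) {
  k <- max(folds)
  rows <- lapply(seq_len(k), function(f) {
    test <- folds == f
    m <- fit(spec, vals[!test, , drop = FALSE], labels = y[!test])
    s <- predict_scores(m, vals[test, , drop = FALSE])
    pred <- as.integer(s > 0.5)
    cc <- confusion(y[test], pred)
    met <- metrics(cc)
    a <- tryCatch(auc(y[test], s), error = function(e) NA_real_)
    data.frame(fold = f, TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN,
               Acc = met$Acc, Sens = met$Sens, Spec = met$Spec,
               MCC = met$MCC, AUC = if (is.na(a)) 0 else a,
               degenerate = paste(c(met$degenerate,
                                    if (is.na(a)) "AUC"), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

cv_accuracy_fm <- function(fm, spec, k = 5L, seed = 1L) {
  folds <- stratified_kfold(fm$labels, k = k, seed = seed)
  mean(fold_eval(fm$values, as.integer(fm$labels), spec, folds)$Acc)
}

make_report <- function(per_fold, scheme, spec, protocol, seed,
                        aggregate = c("mean", "pooled")) {
  aggregate <- match.arg(aggregate)
  metric_cols <- c("Acc", "Sens", "Spec", "MCC", "AUC")
  agg <- if (aggregate == "mean") {
    as.list(colMeans(per_fold[, metric_cols, drop = FALSE]))
  } else {
    cc <- structure(list(TP = sum(per_fold$TP), TN = sum(per_fold$TN),
                         FP = sum(per_fold$FP), FN = sum(per_fold$FN)),
                    class = "confusion_counts")
    met <- metrics(cc)
    c(met[c("Acc", "Sens", "Spec", "MCC")], list(AUC = mean(per_fold$AUC)))
  }
  structure(list(per_fold = per_fold, aggregate = agg, scheme = scheme,
                 model = spec, protocol = protocol, seed = as.integer(seed),
                 aggregation = aggregate),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("%s evaluation: %s + %s (%s)\n", x$protocol,
              scheme_label(x$scheme), x$model$family,
              if (x$model$tuned) "tuned" else "default"))
  cat(sprintf("  Acc %.3f  Sens %.3f  Spec %.3f  MCC %.3f  AUC %.3f  (%d folds)\n",
              x$aggregate$Acc, x$aggregate$Sens, x$aggregate$Spec,
              x$aggregate$MCC, x$aggregate$AUC, nrow(x$per_fold)))
  invisible(x)
}

#' Stratified k-fold cross-validation of one scheme/model cell
#'
#' Encodes all records once with the scheme (the encodings are unsupervised
#' per-sequence summaries, so no information leaks across folds), then for
#' each fold fits on the remaining k-1 folds, scores the held-out fold at
#' threshold 0.5, and records the confusion counts and the five metrics.
#' The aggregate is the unweighted mean of the per-fold metrics; a
#' pooled-counts mode is available via `aggregate = "pooled"`.
#'
#' @param records a `seq_records` data frame with both classes.
#' @param scheme an `encoding_scheme`.
#' @param spec a `model_spec`.
#' @param k number of folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @param aggregate "mean" (default) or "pooled".
#' @return An `evaluation_report` with `protocol = "cv"`.
#' @export
cross_validate <- function(records, scheme, spec, k = 5L, seed = 1L,
                           aggregate = c("mean", "pooled")) {
  fm <- encode_dataset(records, scheme)
  folds <- stratified_kfold(fm$labels, k = k, seed = seed)
  per_fold <- fold_eval(fm$values, as.integer(fm$labels), spec, folds)
  make_report(per_fold, scheme, spec, protocol = "cv", seed = seed,
              aggregate = match.arg(aggregate))
}

#' Cross-species transfer evaluation
#'
#' Fits once on all training records and evaluates once on all test records
#' (one "fold"), after normalizing both sets to a common alphabet. For the
#' positional schemes (binary, enac, ncp) the train and test lengths must be
#' equal. A single-class test set yields degenerate-flagged metrics rather
#' than an error.
#'
#' @param train training `seq_records`.
#' @param test test `seq_records`.
#' @param scheme an `encoding_scheme`.
#' @param spec a `model_spec`.
#' @param target_alphabet common alphabet, default "DNA".
#' @return An `evaluation_report` with `protocol = "transfer"`.
#' @export
cross_species <- function(train, test, scheme, spec,
                          target_alphabet = "DNA") {
  train <- normalize_alphabet(train, target_alphabet)
  test <- normalize_alphabet(test, target_alphabet)
  l_train <- unique(nchar(train$sequence))
  l_test <- unique(nchar(test$sequence))
  positional <- scheme$family %in% c("binary", "enac", "ncp")
  if (positional && !identical(l_train, l_test))
    stop("incompatible-length error: train L=", paste(l_train, collapse = ","),
         " vs test L=", paste(l_test, collapse = ","), " under positional scheme ",
         scheme_label(scheme), call. = FALSE)
  fm_train <- encode_dataset(train, scheme)
  fm_test <- encode_dataset(test, scheme)
  model <- fit(spec, fm_train)
  s <- predict_scores(model, fm_test)
  y <- as.integer(fm_test$labels)
  cc <- confusion(y, as.integer(s > 0.5))
  met <- metrics(cc)
  a <- tryCatch(auc(y, s), error = function(e) NA_real_)
  per_fold <- data.frame(fold = 1L, TP = cc$TP, TN = cc$TN, FP = cc$FP,
                         FN = cc$FN, Acc = met$Acc, Sens = met$Sens,
                         Spec = met$Spec, MCC = met$MCC,
                         AUC = if (is.na(a)) 0 else a,
                         degenerate = paste(c(met$degenerate,
                                              if (is.na(a)) "AUC"),
                                            collapse = ";"),
                         stringsAsFactors = FALSE)
  make_report(per_fold, scheme, spec, protocol = "transfer",
              seed = spec$seed)
}

#' Serialize an evaluation report as JSON
#' @param report an `evaluation_report`.
#' @param path output path, or NULL to return the JSON string.
#' @return JSON string (invisibly when written).
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  x <- list(protocol = report$protocol,
            scheme = list(family = report$scheme$family,
                          param = report$scheme$param),
            model = unclass(report$model),
            seed = report$seed,
            aggregation = report$aggregation,
            aggregate = report$aggregate,
            per_fold = report$per_fold)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Flatten an evaluation report to one summary-CSV row
#'
#' Columns: species, scheme, param, model, tuned, protocol, Acc, Sens, Spec,
#' MCC, AUC, seed — the layout needed to rebuild scheme-by-model comparison
#' figures.
#'
#' @param report an `evaluation_report`.
#' @param species species tag for the row.
#' @return one-row data frame.
#' @export
report_to_csv_row <- function(report, species = "unknown") {
  stopifnot(inherits(report, "evaluation_report"))
  data.frame(species = species,
             scheme = report$scheme$family,
             param = report$scheme$param,
             model = report$model$family,
             tuned = report$model$tuned,
             protocol = report$protocol,
             Acc = report$aggregate$Acc, Sens = report$aggregate$Sens,
             Spec = report$aggregate$Spec, MCC = report$aggregate$MCC,
             AUC = report$aggregate$AUC, seed = report$seed,
             stringsAsFactors = FALSE)
}
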