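# Hold-out classifier evaluation over a validated marker panel.
#
# A pluggable classifier contract (any model emitting a probability in
# [0, 1]) with a regularized linear reference implementation (ridge
# logistic regression on standardized log10 abundances). Evaluation is a
# stratified 70/30 hold-out repeated over random states; the operating
# threshold for sensitivity/specificity is Youden-optimal on the training
# scores and frozen before the test set is touched.

#' Hold-out evaluation configuration
#'
#' @param train_fraction Fraction of each class used for training.
#' @param random_states Integer vector of random states (default 5).
#' @param stratified Stratify the split by class (default TRUE; an
#'   unstratified mode is available).
#' @param classifier A classifier spec: either the name
#'   `"ridge_logistic"` with an optional `lambda`, or a list with `fit(x,
#'   y)` and `predict(model, x)` functions returning probabilities.
#' @param lambda Ridge penalty for the reference classifier.
#' @return An object of class `eval_config`.
#' @export
eval_config <- function(train_fraction = 0.7, random_states = 1:5,
                        stratified = TRUE, classifier = "ridge_logistic",
                        lambda = 0.01) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  }
  if (!length(random_states)) stop("need >= 1 random state", call. = FALSE)
  structure(list(train_fraction = train_fraction,
                 random_states = as.integer(random_states),
                 stratified = stratified, classifier = classifier,
                 lambda = lambda),
            class = "eval_config")
}

#' Stratified hold-out split that keeps technical replicates together
#'
#' Splits at the biological-sample level (so technical replicates of one
#' sample never straddle the train/test boundary) and maps back to matrix
#' rows. Deterministic for a given random state.
#'
#' @param qm A [quant_matrix()].
#' @param cfg An [eval_config()].
#' @param state Random state.
#' @return List with `train` and `test` row indices into `qm$values`.
#' @export
split_holdout <- function(qm, cfg = eval_config(), state = 1L) {
  stopifnot(inherits(qm, "quant_matrix"))
  meta <- qm$sample_meta
  keep <- meta$group %in% c("case", "control")
  bio <- meta[keep & !duplicated(meta$replicate_of), c("replicate_of", "group")]
  if (length(unique(bio$group)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  if (any(table(bio$group) < 2L)) {
    stop("need >= 2 biological samples per class", call. = FALSE)
  }
  train_bio <- with_seed(state, {
    if (cfg$stratified) {
      unlist(lapply(split(bio$replicate_of, bio$group), function(ids) {
        n_train <- floor(cfg$train_fraction * length(ids))
        sample(ids, n_train)
      }), use.names = FALSE)
    } else {
      sample(bio$replicate_of, floor(cfg$train_fraction * nrow(bio)))
    }
  })
  test_bio <- setdiff(bio$replicate_of, train_bio)
  list(train = which(meta$replicate_of %in% train_bio),
       test = which(meta$replicate_of %in% test_bio))
}

#' Train a classifier on a marker panel
#'
#' The reference model is ridge-penalised logistic regression fit by
#' glmnet's iterative coordinate optimization on standardized features.
#' Zero-variance features are dropped with a warning. A custom classifier
#' spec (`list(fit =, predict =)`) replaces the reference model.
#'
#' @param x Numeric feature matrix (samples x markers).
#' @param y Labels: `"case"`/`"control"` (case is the positive class).
#' @param cfg An [eval_config()].
#' @return An object of class `mrm_classifier` with a [predict][stats::predict]
#'   method returning case probabilities.
#' @export
train_classifier <- function(x, y, cfg = eval_config()) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  y01 <- as.integer(y == "case")
  if (length(unique(y01)) < 2L) stop("both classes required", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  drop <- which(!is.finite(sds) | sds == 0)
  if (length(drop)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(x)[drop], collapse = ", "))
    x <- x[, -drop, drop = FALSE]
  }
  if (is.list(cfg$classifier)) {
    model <- cfg$classifier$fit(x, y01)
    return(structure(list(model = model, kept = colnames(x),
                          predict_fun = cfg$classifier$predict),
                     class = "mrm_classifier"))
  }
  lam <- cfg$lambda
  # glmnet requires >= 2 columns; pad single-marker panels with a constant
  padded <- ncol(x) < 2L
  xfit <- if (padded) cbind(x, .pad = 0) else x
  fit <- glmnet::glmnet(xfit, y01, family = "binomial", alpha = 0,
                        lambda = c(100 * lam, 10 * lam, lam),
                        standardize = TRUE)
  structure(list(model = fit, kept = colnames(x), lambda = lam,
                 padded = padded, predict_fun = NULL),
            class = "mrm_classifier")
}

#' @export
predict.mrm_classifier <- function(object, newdata, ...) {
  if (is.null(colnames(newdata))) {
    colnames(newdata) <- paste0("V", seq_len(ncol(newdata)))
  }
  x <- newdata[, object$kept, drop = FALSE]
  if (!is.null(object$predict_fun)) {
    return(as.numeric(object$predict_fun(object$model, x)))
  }
  if (isTRUE(object$padded)) x <- cbind(x, .pad = 0)
  as.numeric(stats::predict(object$model, newx = x, s = object$lambda,
                            type = "response"))
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve via the Mann-Whitney identity
#' `AUC = U / (n1 * n0)` with midranks, which equals trapezoidal
#' integration over all score thresholds (ties counted as half
#' concordant).
#'
#' @param scores Numeric classifier scores.
#' @param labels `"case"`/`"control"` (or logical, TRUE = positive).
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "case"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Youden-optimal threshold on (typically training) scores: candidate cuts
# are midpoints between adjacent distinct scores; prediction is positive
# when score >= threshold.
youden_threshold <- function(scores, labels) {
  pos <- labels == "case"
  s <- sort(unique(scores))
  cand <- if (length(s) > 1L) c(s[1] - 1, (s[-1] + s[-length(s)]) / 2)
          else s
  j <- vapply(cand, function(th) {
    sens <- mean(scores[pos] >= th)
    spec <- mean(scores[!pos] < th)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' ROC metrics at an operating threshold
#'
#' @param scores Classifier scores.
#' @param labels `"case"`/`"control"`.
#' @param threshold Operating point: predictions are positive when
#'   `score >= threshold`.
#' @return List with `auc`, `sensitivity`, `specificity`, `accuracy`,
#'   `threshold_used`.
#' @export
roc_metrics <- function(scores, labels, threshold = 0.5) {
  pos <- labels == "case"
  if (!any(pos) || all(pos)) stop("both classes required", call. = FALSE)
  pred <- scores >= threshold
  list(auc = auc_rank(scores, labels),
       sensitivity = mean(pred[pos]),
       specificity = mean(!pred[!pos]),
       accuracy = mean(pred == pos),
       threshold_used = threshold)
}

#' Repeated hold-out evaluation of a marker panel
#'
#' For each random state: stratified 70/30 split (replicates kept
#' together), technical replicates aggregated, features log10-transformed,
#' the classifier trained on the training block only, the operating
#' threshold chosen by Youden on training scores, and AUC / sensitivity /
#' specificity / accuracy measured on the held-out block. Samples whose
#' group is neither case nor control (e.g. an other-cancer group) are
#' excluded from training and metrics but are scored by every state's
#' model; their score distributions are returned in the `group_scores`
#' attribute.
#'
#' @param qm A [quant_matrix()] restricted to the marker panel (columns).
#' @param cfg An [eval_config()].
#' @return An object of class `panel_evaluation`: data frame with one row
#'   per random state plus an `"average"` row (arithmetic mean of the
#'   per-state metrics).
#' @export
evaluate_panel <- function(qm, cfg = eval_config()) {
  stopifnot(inherits(qm, "quant_matrix"))
  agg <- aggregate_replicates(qm)
  feats <- log10(pmax(agg$values, .Machine$double.xmin))
  groups <- agg$sample_meta$group
  binary <- groups %in% c("case", "control")

  rows <- list()
  extra_scores <- list()
  for (state in cfg$random_states) {
    idx <- split_holdout(agg, cfg, state)
    model <- train_classifier(feats[idx$train, , drop = FALSE],
                              groups[idx$train], cfg)
    train_scores <- predict(model, feats[idx$train, , drop = FALSE])
    th <- youden_threshold(train_scores, groups[idx$train])
    test_scores <- predict(model, feats[idx$test, , drop = FALSE])
    m <- roc_metrics(test_scores, groups[idx$test], th)
    rows[[length(rows) + 1L]] <- data.frame(
      random_state = state, auc = m$auc, sensitivity = m$sensitivity,
      specificity = m$specificity, accuracy = m$accuracy,
      threshold_used = m$threshold_used, stringsAsFactors = FALSE
    )
    all_scores <- predict(model, feats)
    extra_scores[[length(extra_scores) + 1L]] <- data.frame(
      random_state = state, sample_id = agg$sample_meta$sample_id,
      group = groups, score = all_scores,
      in_test = seq_along(groups) %in% idx$test & binary,
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  avg <- data.frame(random_state = NA_integer_,
                    auc = mean(tab$auc), sensitivity = mean(tab$sensitivity),
                    specificity = mean(tab$specificity),
                    accuracy = mean(tab$accuracy),
                    threshold_used = NA_real_, stringsAsFactors = FALSE)
  out <- rbind(tab, avg)
  out$label <- c(paste0("state_", tab$random_state), "average")
  rownames(out) <- NULL
  attr(out, "group_scores") <- do.call(rbind, extra_scores)
  class(out) <- c("panel_evaluation", class(out))
  out
}

#' @export
print.panel_evaluation <- function(x, ...) {
  cat("hold-out panel evaluation (case vs control):\n")
  df <- as.data.frame(x)[, c("label", "specificity", "sensitivity",
                             "auc", "accuracy")]
  df[, -1] <- round(df[, -1], 4)
  print(df, row.names = FALSE)
  invisible(x)
}
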