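# Logistic-regression benchmark on windowed ERP-mean features: the
# conventional baseline the network is compared against.

#' Windowed ERP-mean features
#'
#' Per trial and channel, the arithmetic mean of all samples whose
#' timestamps fall inside the window (inclusive); the classical P300
#' feature is the 350-400 ms mean.
#'
#' @param es an [epoch_set()].
#' @param window inclusive window in ms.
#' @return numeric matrix `n_trials x n_channels`, channel-named.
#' @export
extract_erp_features <- function(es, window = c(350, 400)) {
  sel <- which(es$times >= window[1] & es$times <= window[2])
  if (!length(sel)) stopf("feature window outside the epoch")
  n <- dim(es$data)[1]
  feats <- vapply(seq_along(es$layout$names), function(ch)
    rowMeans(matrix(es$data[, ch, sel], nrow = n)), numeric(n))
  if (is.null(dim(feats))) feats <- matrix(feats, nrow = n)
  colnames(feats) <- es$layout$names
  feats
}

#' Fit and evaluate the logistic-regression baseline
#'
#' Maximum-likelihood binary logistic regression with intercept on the
#' feature matrix. On (quasi-)perfect separation the fit is re-run with a
#' small L2 ridge penalty and a note is issued.
#'
#' @param train_features,train_labels training data.
#' @param test_features,test_labels evaluation data (defaults to training
#'   data for apparent metrics).
#' @return list with `model` (coefficients), `metrics`
#'   ([confusion_metrics()] output) and `separation` flag.
#' @export
lr_fit_evaluate <- function(train_features, train_labels,
                            test_features = train_features,
                            test_labels = train_labels) {
  if (length(unique(train_labels)) < 2L) stopf("need both classes to fit")
  df <- as.data.frame(train_features)
  df$.y <- train_labels
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- coef(fit)
  if (separation || !fit$converged) {
    # ridge-stabilized refit by iteratively reweighted least squares
    message("lr_fit_evaluate: separation detected; using ridge-stabilized fit")
    X <- cbind(1, as.matrix(train_features))
    beta <- ridge_logistic(X, train_labels, lambda = 1e-3)
  }
  eta <- cbind(1, as.matrix(test_features)) %*% beta
  pred <- as.integer(eta > 0)
  list(model = beta, metrics = confusion_metrics(pred, test_labels),
       separation = separation)
}

ridge_logistic <- function(X, y, lambda = 1e-3, iter = 50) {
  beta <- rep(0, ncol(X))
  pen <- diag(lambda, ncol(X)); pen[1, 1] <- 0   # don't penalize intercept
  for (i in seq_len(iter)) {
    p <- 1 / (1 + exp(-drop(X %*% beta)))
    w <- pmax(p * (1 - p), 1e-8)
    H <- crossprod(X, X * w) + pen
    g <- crossprod(X, y - p) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-10) break
  }
  drop(beta)
}

#' Leave-one-subject-out evaluation of the LR baseline
#'
#' The same partitioning protocol as the network's LOSO evaluation, so the
#' two models' per-subject accuracies are paired.
#'
#' @param ds an [epoch_set()] with `subject` metadata.
#' @param window feature window in ms.
#' @return list with `per_cell`, `per_subject` tables (as in
#'   [evaluate_loso()]).
#' @export
lr_evaluate_loso <- function(ds, window = c(350, 400)) {
  feats <- extract_erp_features(ds, window)
  subjects <- sort(unique(ds$meta$subject))
  if (length(subjects) < 2L) stopf("LOSO needs at least 2 subjects")
  per_cell <- list(); per_subject <- list()
  for (s in subjects) {
    tr <- ds$meta$subject != s
    fit <- lr_fit_evaluate(feats[tr, , drop = FALSE], ds$labels[tr],
                           feats[!tr, , drop = FALSE], ds$labels[!tr])
    te_idx <- which(!tr)
    eta <- cbind(1, feats[te_idx, , drop = FALSE]) %*% fit$model
    pred <- as.integer(eta > 0)
    cells <- split(seq_along(te_idx),
                   list(ds$meta$session[te_idx], ds$meta$scenario[te_idx]),
                   drop = TRUE)
    for (nm in names(cells)) {
      ci <- cells[[nm]]
      m <- confusion_metrics(pred[ci], ds$labels[te_idx][ci])
      per_cell[[length(per_cell) + 1L]] <- data.frame(
        subject = s, session = ds$meta$session[te_idx][ci[1]],
        scenario = ds$meta$scenario[te_idx][ci[1]],
        accuracy = m$accuracy, sensitivity = m$sensitivity,
        specificity = m$specificity, n = length(ci))
    }
    ms <- confusion_metrics(pred, ds$labels[te_idx])
    per_subject[[length(per_subject) + 1L]] <- data.frame(
      subject = s, accuracy = ms$accuracy, sensitivity = ms$sensitivity,
      specificity = ms$specificity, n = length(te_idx))
  }
  list(per_cell = do.call(rbind, per_cell),
       per_subject = do.call(rbind, per_subject))
}

#' Compare two models' per-subject accuracies
#'
#' Independent two-sample pooled-variance t-test (two-sided), the
#' convention for comparing decoding-accuracy distributions.
#'
#' @param acc_a,acc_b per-subject accuracy vectors.
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
compare_models <- function(acc_a, acc_b) {
  ttest2(acc_a, acc_b)
}
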