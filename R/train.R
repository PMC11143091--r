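#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with learning rate
#' 1.25e-4, beta1 = 0.9, beta2 = 0.999, mini-batches of 128, up to 300
#' epochs with early stopping on validation loss (patience 20, best weights
#' restored), focal loss with gamma = 2.
#'
#' @param learning_rate,beta1,beta2,epsilon Adam hyper-parameters.
#' @param batch_size mini-batch size.
#' @param max_epochs maximum number of passes over the training set.
#' @param patience early-stopping patience in epochs (monitoring val loss).
#' @param focal_gamma focusing parameter of the focal loss (`>= 0`).
#' @param val_fraction stratified fraction of training trials held out for
#'   validation when no validation set is supplied.
#' @param seed integer seed controlling initialization, shuffling, the
#'   validation split and dropout.
#' @param verbose print per-epoch progress?
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1.25e-4, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, batch_size = 128L, max_epochs = 300L,
                         patience = 20L, focal_gamma = 2,
                         val_fraction = 0.2, seed = 1L, verbose = FALSE) {
  if (focal_gamma < 0) stopf("focal_gamma must be >= 0")
  if (batch_size < 1) stopf("batch_size must be >= 1")
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), focal_gamma = focal_gamma,
                 val_fraction = val_fraction, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, tc) {
  state$t <- state$t + 1L
  corr1 <- 1 - tc$beta1^state$t
  corr2 <- 1 - tc$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- tc$beta1 * state$m[[nm]] + (1 - tc$beta1) * g
    state$v[[nm]] <- tc$beta2 * state$v[[nm]] + (1 - tc$beta2) * g * g
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - tc$learning_rate * mhat / (sqrt(vhat) + tc$epsilon)
  }
  list(params = params, state = state)
}

# mean focal loss + accuracy of a fitted model on an epoch set (eval mode)
eval_loss <- function(model, es, gamma) {
  probs <- predict_eegnet(model, es)
  pt <- pmax(probs[cbind(seq_along(es$labels), es$labels + 1L)], 1e-12)
  list(loss = mean(-(1 - pt)^gamma * log(pt)),
       acc = mean((probs[, 2] > 0.5) == (es$labels == 1L)))
}

stratified_split <- function(labels, val_fraction) {
  val <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_val <- max(1L, round(length(idx) * val_fraction))
    val <- c(val, sample(idx, n_val))
  }
  sort(val)
}

#' Train the network
#'
#' Mini-batch Adam on the focal loss with early stopping on validation loss;
#' the best-validation weights are restored at the end. Deterministic given
#' `tcfg$seed`.
#'
#' @param train_es training [epoch_set()] (must contain both classes).
#' @param cfg an [eegnet_config()].
#' @param tcfg a [train_config()].
#' @param val_es optional validation [epoch_set()]; by default a stratified
#'   `val_fraction` of the training trials is held out.
#' @param model optional pre-built `eegnet_model` to continue training.
#' @return a trained `eegnet_model`; `$history` holds per-epoch train/val
#'   loss and accuracy.
#' @export
train_eegnet <- function(train_es, cfg = eegnet_config(), tcfg = train_config(),
                         val_es = NULL, model = NULL) {
  if (length(unique(train_es$labels)) < 2L)
    stopf("training set must contain both classes")
  if (is.null(model)) model <- build_eegnet(cfg, seed = derive_seed(tcfg$seed, 1L))
  cfg <- model$cfg
  set.seed(derive_seed(tcfg$seed, 2L))

  if (is.null(val_es) && tcfg$val_fraction > 0 && tcfg$max_epochs > 0L) {
    val_idx <- stratified_split(train_es$labels, tcfg$val_fraction)
    val_es <- epochs_subset(train_es, val_idx)
    train_es <- epochs_subset(train_es, setdiff(seq_along(train_es$labels), val_idx))
  }

  n <- dim(train_es$data)[1]
  opt <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params, running = model$running,
               epoch = 0L)
  hist <- list()
  wait <- 0L

  for (ep in seq_len(tcfg$max_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_n <- 0L; ep_correct <- 0L
    for (at in seq(1L, n, by = tcfg$batch_size)) {
      idx <- ord[at:min(at + tcfg$batch_size - 1L, n)]
      Xb <- train_es$data[idx, , , drop = FALSE]
      yb <- train_es$labels[idx]
      fw <- eegnet_forward(model, Xb, training = TRUE, keep_cache = TRUE)
      model$running <- fw$running
      fl <- focal_loss_grad(fw$logits, yb, tcfg$focal_gamma)
      bw <- eegnet_backward(model, fw$cache, fl$dlogits, want_dx = FALSE)
      upd <- adam_step(model$params, bw$grads, opt, tcfg)
      model$params <- upd$params; opt <- upd$state
      ep_loss <- ep_loss + fl$loss * length(idx)
      ep_n <- ep_n + length(idx)
      ep_correct <- ep_correct + sum((fl$probs[2, ] > 0.5) == (yb == 1L))
    }
    row <- data.frame(epoch = ep, train_loss = ep_loss / ep_n,
                      train_acc = ep_correct / ep_n,
                      val_loss = NA_real_, val_acc = NA_real_)
    if (!is.null(val_es)) {
      ev <- eval_loss(model, val_es, tcfg$focal_gamma)
      row$val_loss <- ev$loss; row$val_acc <- ev$acc
      if (ev$loss < best$loss - 1e-6) {
        best <- list(loss = ev$loss, params = model$params,
                     running = model$running, epoch = ep)
        wait <- 0L
      } else wait <- wait + 1L
    }
    hist[[ep]] <- row
    if (tcfg$verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.3f  val %.4f/%.3f",
                      ep, row$train_loss, row$train_acc,
                      row$val_loss, row$val_acc))
    if (!is.null(val_es) && wait >= tcfg$patience) break
  }
  if (!is.null(val_es) && is.finite(best$loss)) {
    model$params <- best$params
    model$running <- best$running
  }
  model$trained <- tcfg$max_epochs > 0L
  model$history <- if (length(hist)) do.call(rbind, hist) else
    data.frame(epoch = integer(0), train_loss = numeric(0),
               train_acc = numeric(0), val_loss = numeric(0),
               val_acc = numeric(0))
  model
}

#' Confusion-matrix classification metrics
#'
#' Accuracy, sensitivity (`TP/(TP+FN)`) and specificity (`TN/(TN+FP)`) in
#' percent, plus the raw counts. Degenerate denominators yield `NaN` with a
#' flag rather than an error.
#'
#' @param predicted predicted 0/1 labels.
#' @param labels true 0/1 labels.
#' @return list with `accuracy`, `sensitivity`, `specificity` (percent),
#'   `counts` (TP/FP/TN/FN) and `degenerate` flag.
#' @export
confusion_metrics <- function(predicted, labels) {
  if (length(predicted) != length(labels)) stopf("length mismatch")
  if (!length(labels)) stopf("empty input")
  predicted <- as.integer(predicted); labels <- as.integer(labels)
  tp <- sum(predicted == 1L & labels == 1L)
  fp <- sum(predicted == 1L & labels == 0L)
  tn <- sum(predicted == 0L & labels == 0L)
  fn <- sum(predicted == 0L & labels == 1L)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NaN
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NaN
  list(accuracy = 100 * (tp + tn) / length(labels),
       sensitivity = sens, specificity = spec,
       counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
       degenerate = is.nan(sens) || is.nan(spec))
}

#' Leave-one-subject-out evaluation
#'
#' For each subject: train on all other subjects' epochs and test on the
#' held-out subject, reporting metrics per session and scenario (the layout
#' of a subjects-by-sessions accuracy table) plus pooled per-subject rows.
#'
#' @param ds an [epoch_set()] whose `meta` has `subject`, `session`,
#'   `scenario` columns.
#' @param cfg an [eegnet_config()].
#' @param tcfg a [train_config()]; each fold derives its own seed.
#' @return list with `per_cell` (subject x session x scenario metrics),
#'   `per_subject` (pooled over cells), and `models` (one per fold).
#' @export
evaluate_loso <- function(ds, cfg = eegnet_config(), tcfg = train_config()) {
  subjects <- sort(unique(ds$meta$subject))
  if (length(subjects) < 2L) stopf("LOSO needs at least 2 subjects")
  per_cell <- list(); per_subject <- list(); models <- list()
  for (s in subjects) {
    test_idx <- which(ds$meta$subject == s)
    if (!length(test_idx)) stopf("subject %s has an empty test partition", s)
    train_set <- epochs_subset(ds, ds$meta$subject != s)
    fold_tc <- tcfg
    fold_tc$seed <- derive_seed(tcfg$seed, 500L, s)
    model <- train_eegnet(train_set, cfg, fold_tc)
    models[[as.character(s)]] <- model
    test_set <- epochs_subset(ds, test_idx)
    probs <- predict_eegnet(model, test_set)
    pred <- as.integer(probs[, 2] > 0.5)
    cells <- split(seq_along(test_set$labels),
                   list(test_set$meta$session, test_set$meta$scenario),
                   drop = TRUE)
    for (nm in names(cells)) {
      ci <- cells[[nm]]
      m <- confusion_metrics(pred[ci], test_set$labels[ci])
      per_cell[[length(per_cell) + 1L]] <- data.frame(
        subject = s, session = test_set$meta$session[ci[1]],
        scenario = test_set$meta$scenario[ci[1]],
        accuracy = m$accuracy, sensitivity = m$sensitivity,
        specificity = m$specificity, n = length(ci))
    }
    ms <- confusion_metrics(pred, test_set$labels)
    per_subject[[length(per_subject) + 1L]] <- data.frame(
      subject = s, accuracy = ms$accuracy, sensitivity = ms$sensitivity,
      specificity = ms$specificity, n = length(test_idx))
  }
  per_cell <- do.call(rbind, per_cell)
  per_subject <- do.call(rbind, per_subject)
  list(per_cell = per_cell, per_subject = per_subject, models = models)
}

#' Subjects-by-sessions accuracy table
#'
#' Pivots LOSO per-cell metrics into the conventional report layout: one row
#' per subject, one column per session, with Mean and SD rows appended.
#'
#' @param per_cell the `per_cell` table from [evaluate_loso()].
#' @param scenario which scenario to tabulate.
#' @param metric which metric column to spread.
#' @return a data.frame.
#' @export
accuracy_table <- function(per_cell, scenario, metric = "accuracy") {
  sub <- per_cell[per_cell$scenario == scenario, ]
  sessions <- sort(unique(sub$session))
  subjects <- sort(unique(sub$subject))
  tab <- matrix(NA_real_, length(subjects), length(sessions),
                dimnames = list(subjects, paste0("session", sessions)))
  for (i in seq_len(nrow(sub)))
    tab[as.character(sub$subject[i]), paste0("session", sub$session[i])] <-
      sub[[metric]][i]
  out <- as.data.frame(tab)
  out <- rbind(out, Mean = colMeans(tab), SD = apply(tab, 2, sd))
  cbind(subject = rownames(out), out, row.names = NULL)
}
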