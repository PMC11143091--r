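test_that("elu, softmax and focal loss match their closed forms", {
  # elu
  expect_identical(elu(0), 0)
  expect_identical(elu(2), 2)
  expect_equal(elu(-1), exp(-1) - 1, tolerance = 1e-12)
  x <- seq(-3, 3, by = 0.25)
  expect_equal(elu(x), ifelse(x >= 0, x, exp(x) - 1))
  expect_equal(elu(1e-12) - elu(-1e-12), 0, tolerance = 1e-10) # continuity

  # softmax
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax(c(1, 0)), c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-12)
  expect_equal(softmax(c(1, 0)), c(0.73106, 0.26894), tolerance = 1e-5)
  for (c0 in c(-100, 0, 57.3)) # shift invariance
    expect_equal(softmax(c(c0 + 1, c0)), softmax(c(1, 0)), tolerance = 1e-12)
  expect_error(softmax(c(Inf, 0)), "finite")

  # focal loss
  expect_equal(focal_loss(0.5, gamma = 0), log(2), tolerance = 1e-12)
  expect_equal(focal_loss(1, gamma = 0), 0)
  expect_equal(focal_loss(1, gamma = 2), 0)
  expect_equal(focal_loss(0.9, gamma = 2), 0.01 * -log(0.9), tolerance = 1e-12)
  expect_equal(focal_loss(0.9, gamma = 2), 1.0536e-3, tolerance = 1e-4)
  # gamma = 0 reduces to cross-entropy on a grid; gamma > 0 never exceeds it
  pt <- seq(0.01, 1, by = 0.01)
  expect_equal(focal_loss(pt, gamma = 0), -log(pt), tolerance = 1e-12)
  for (g in c(0.5, 1, 2, 5))
    expect_true(all(focal_loss(pt, g) <= -log(pt) + 1e-15))
  # monotone decreasing in p_t
  expect_true(all(diff(focal_loss(pt, gamma = 2)) < 0))
  expect_warning(focal_loss(0, gamma = 2), "clamped")
  expect_error(focal_loss(0.5, gamma = -1), "gamma")
})

test_that("architecture dimensions follow the pooling recurrence", {
  shp <- layer_shapes(build_eegnet(eegnet_config(), seed = 1))
  get <- function(nm) shp$dims[[match(nm, shp$layer)]]
  expect_identical(get("avgpool_1"), c(16L, 1L, 50L))
  expect_identical(get("avgpool_2"), c(16L, 1L, 6L))
  expect_identical(get("flatten"), 96L)
  expect_identical(get("dense"), 2L)
  # apply the dimension recurrence to a different input length
  shp2 <- layer_shapes(eegnet_config(n_samples = 100L))
  expect_identical(shp2$dims[[match("flatten", shp2$layer)]],
                   16L * ((100L %/% 4L) %/% 8L))
  expect_identical(shp2$dims[[match("flatten", shp2$layer)]], 48L)
  expect_error(eegnet_config(n_samples = 10L, pool1 = 4L, pool2 = 8L),
               "zero-length")
  expect_error(eegnet_config(F1 = 8L, D = 2L, F2 = 8L), "must equal")
})

test_that("forward probabilities are a distribution; dropout only in training", {
  m <- build_eegnet(seed = 5)
  set.seed(2)
  X <- array(rnorm(6 * 8 * 201), c(6, 8, 201))
  p <- predict_eegnet(m, X)
  expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-6)
  expect_true(all(p > 0 & p < 1))
  # inference is deterministic (no dropout)
  expect_identical(predict_eegnet(m, X), p)
})

test_that("input gradients match central finite differences", {
  m <- build_eegnet(seed = 3)
  set.seed(4)
  X <- array(rnorm(3 * 8 * 201), c(3, 8, 201))
  g <- input_gradient(m, X, class_index = 2L)
  score <- function(Xa) p300net:::eegnet_forward(m, Xa)$logits[2, ]
  set.seed(5)
  for (k in 1:20) {
    i <- sample(3, 1); ch <- sample(8, 1); t <- sample(201, 1)
    eps <- 1e-4
    Xp <- X; Xp[i, ch, t] <- Xp[i, ch, t] + eps
    Xm <- X; Xm[i, ch, t] <- Xm[i, ch, t] - eps
    num <- (score(Xp)[i] - score(Xm)[i]) / (2 * eps)
    expect_lt(abs(num - g[i, ch, t]) / max(abs(num), 1e-8), 1e-3)
  }
  expect_error(input_gradient(m, X, class_index = 5L), "out of range")
})

test_that("every parameter gradient matches finite differences", {
  m <- build_eegnet(eegnet_config(dropout_rate = 0), seed = 6)
  set.seed(7)
  X <- array(rnorm(4 * 8 * 201), c(4, 8, 201))
  y <- c(0L, 1L, 0L, 1L)
  lossfun <- function(mm) {
    fw <- p300net:::eegnet_forward(mm, X, training = TRUE, keep_cache = TRUE)
    p300net:::focal_loss_grad(fw$logits, y, 2)$loss
  }
  fw <- p300net:::eegnet_forward(m, X, training = TRUE, keep_cache = TRUE)
  fl <- p300net:::focal_loss_grad(fw$logits, y, 2)
  bw <- p300net:::eegnet_backward(m, fw$cache, fl$dlogits, want_dx = FALSE)
  set.seed(8)
  for (nm in names(m$params)) {
    for (j in sample(length(m$params[[nm]]), min(3, length(m$params[[nm]])))) {
      eps <- 1e-5
      mp <- m; mp$params[[nm]][j] <- mp$params[[nm]][j] + eps
      mm2 <- m; mm2$params[[nm]][j] <- mm2$params[[nm]][j] - eps
      num <- (lossfun(mp) - lossfun(mm2)) / (2 * eps)
      expect_lt(abs(num - bw$grads[[nm]][j]) / max(abs(num), 1e-6), 1e-3,
                label = sprintf("grad check %s[%d]", nm, j))
    }
  }
})

test_that("training solves a linearly separable toy set and is deterministic", {
  es <- toy_separable()
  tc <- fast_train(seed = 3L, epochs = 50L)
  m <- train_eegnet(es, eegnet_config(), tc)
  p <- predict_eegnet(m, es)
  acc <- mean((p[, 2] > 0.5) == (es$labels == 1L))
  expect_equal(acc, 1)
  expect_true(all(c("epoch", "train_loss", "val_loss") %in% names(m$history)))
  # same seed, same model
  m2 <- train_eegnet(es, eegnet_config(), tc)
  expect_identical(m$params, m2$params)

  # zero max_epochs: initialized model, empty history
  m0 <- train_eegnet(es, eegnet_config(),
                     train_config(max_epochs = 0L, seed = 3L))
  expect_false(m0$trained)
  expect_identical(nrow(m0$history), 0L)
  expect_error(train_eegnet(epochs_subset(es, es$labels == 0L)),
               "both classes")
})

test_that("focusing the loss does not hurt minority-class sensitivity", {
  # imbalanced, noisy set; paired seeds, identical initialization
  cfg <- tiny_sim(seed = 13L, blocks = 4L, runs = 8L, sigma = 5)
  ds <- generate_dataset(cfg, scenarios = "social")
  tr <- epochs_subset(ds, ds$meta$block <= 3)
  te <- epochs_subset(ds, ds$meta$block == 4)
  sens <- sapply(c(0, 2), function(g) {
    m <- train_eegnet(tr, eegnet_config(),
                      fast_train(seed = 17L, epochs = 12L, focal_gamma = g))
    cm <- confusion_metrics(as.integer(predict_eegnet(m, te)[, 2] > 0.5),
                            te$labels)
    cm$sensitivity
  })
  expect_gte(sens[2], sens[1])
})

test_that("confusion_metrics matches hand arithmetic and flags degeneracy", {
  m <- confusion_metrics(rep(1, 10), rep(1, 10))
  expect_equal(m$accuracy, 100)
  expect_equal(m$sensitivity, 100)
  expect_true(is.nan(m$specificity))

  # TP=7 FN=3 TN=80 FP=10
  pred <- c(rep(1, 7), rep(0, 3), rep(0, 80), rep(1, 10))
  lab <- c(rep(1, 10), rep(0, 90))
  m <- confusion_metrics(pred, lab)
  expect_equal(m$sensitivity, 70)
  expect_equal(m$specificity, 100 * 80 / 90, tolerance = 1e-10)
  expect_equal(round(m$specificity, 1), 88.9)
  expect_equal(m$accuracy, 87)
  expect_equal(sum(m$counts), 100)

  m <- confusion_metrics(rep(0, 5), rep(0, 5))
  expect_equal(m$specificity, 100)
  expect_true(is.nan(m$sensitivity))
  expect_true(m$degenerate)
  expect_error(confusion_metrics(integer(0), integer(0)), "empty")
})

test_that("LOSO runs one fold per subject and its metrics are consistent", {
  # two subjects with identical noise-free separable data
  es1 <- toy_separable(n_target = 8L, n_standard = 24L, seed = 7L)
  es2 <- es1
  es2$meta$subject <- 2L
  es1$meta$session <- es2$meta$session <- 1L
  es1$meta$scenario <- es2$meta$scenario <- "social"
  ds <- epochs_bind(es1, es2)
  res <- evaluate_loso(ds, eegnet_config(),
                       fast_train(seed = 5L, epochs = 30L, val_fraction = 0.25))
  expect_identical(nrow(res$per_subject), 2L)     # k folds for k subjects
  expect_identical(length(res$models), 2L)
  expect_equal(res$per_subject$accuracy, c(100, 100))
  # metrics recomputed from stored confusion counts match to 0.1%
  for (i in 1:2) {
    s <- res$per_subject$subject[i]
    model <- res$models[[as.character(s)]]
    sub <- epochs_subset(ds, ds$meta$subject == s)
    cm <- confusion_metrics(
      as.integer(predict_eegnet(model, sub)[, 2] > 0.5), sub$labels)
    expect_equal(cm$accuracy, res$per_subject$accuracy[i], tolerance = 1e-3)
  }
  expect_error(evaluate_loso(es1), "2 subjects")
})
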