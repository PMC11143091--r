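oracle_times <- epoch_times(sim_config())

test_that("linear-model oracle: saliency equals the weight vector exactly", {
  set.seed(1)
  W <- matrix(rnorm(8 * 201), 8, 201)
  om <- linear_oracle(W, bias = 0.3)
  es <- epoch_set(array(rnorm(2 * 8 * 201), c(2, 8, 201)), c(0L, 1L),
                  times = oracle_times)
  maps <- compute_saliency(om, es, average = FALSE, normalize = FALSE)
  expect_identical(unname(maps[[1]]$values), W)    # bit-exact, input-free
  expect_identical(unname(maps[[2]]$values), W)
  # opposite class score: negated weights
  m0 <- compute_saliency(om, es, class_index = 1L, average = FALSE,
                         normalize = FALSE)[[1]]
  expect_identical(unname(m0$values), -W)
  # constant (zero-weight) model: all-zero map
  z <- compute_saliency(linear_oracle(matrix(0, 8, 201)), es,
                        average = FALSE, normalize = FALSE)[[1]]
  expect_true(all(z$values == 0))
})

test_that("network saliency is the reshaped input gradient", {
  m <- build_eegnet(seed = 2)
  set.seed(3)
  es <- epoch_set(array(rnorm(3 * 8 * 201), c(3, 8, 201)), c(1L, 0L, 1L),
                  times = oracle_times)
  maps <- compute_saliency(m, es, average = FALSE, normalize = FALSE)
  g <- input_gradient(m, es, class_index = 2L)
  expect_equal(unname(maps[[2]]$values), g[2, , ], tolerance = 1e-12)
})

test_that("normalize_map scales to unit max-|.|, preserves sign", {
  set.seed(4)
  v <- matrix(rnorm(8 * 201), 8, 201)
  v[1, 1] <- 4; v <- v / max(abs(v)) * 4         # max |v| = 4
  m <- saliency_map(v, oracle_times)
  nm <- normalize_map(m)
  expect_equal(max(abs(nm$values)), 1)
  expect_identical(sign(nm$values), sign(m$values))
  expect_identical(normalize_map(nm)$values, nm$values)  # idempotent
  z <- normalize_map(saliency_map(matrix(0, 8, 201), oracle_times))
  expect_true(all(z$values == 0) && z$normalized)
})

test_that("average_maps is the element-wise mean", {
  set.seed(5)
  M <- saliency_map(matrix(rnorm(8 * 201), 8), oracle_times)
  Mneg <- M; Mneg$values <- -M$values
  expect_true(all(average_maps(list(M, Mneg))$values == 0))
  expect_equal(average_maps(list(M, M, M))$values, M$values)
  maps <- lapply(1:4, function(i)
    saliency_map(matrix(rnorm(8 * 201), 8), oracle_times))
  avg <- average_maps(maps)
  brute <- Reduce(`+`, lapply(maps, function(m) m$values)) / 4
  expect_equal(unname(avg$values), unname(brute), tolerance = 1e-12)
  expect_error(average_maps(list()), "empty")
  bad <- saliency_map(matrix(0, 8, 10), oracle_times[1:10])
  expect_error(average_maps(list(M, bad)), "mismatch")
})

test_that("spatial/temporal profiles reduce |values| along the right axes", {
  layout <- channel_layout()
  v <- matrix(0, 8, 201)
  v[6, ] <- rnorm(201)                            # only Pz
  m <- saliency_map(v, oracle_times, layout)
  sp <- spatial_profile(m)
  expect_identical(names(which.max(sp)), "Pz")
  expect_true(all(sp[-6] == 0))

  v2 <- matrix(0, 8, 201)
  cols <- which(oracle_times >= 300 & oracle_times <= 400)
  v2[, cols] <- rnorm(8 * length(cols))
  tp <- temporal_profile(saliency_map(v2, oracle_times, layout))
  expect_true(all(tp$value[-cols] == 0))
  expect_gt(max(tp$value[cols]), 0)

  set.seed(6)
  v3 <- matrix(rnorm(8 * 201), 8)
  m3 <- saliency_map(v3, oracle_times, layout)
  expect_equal(unname(spatial_profile(m3)), unname(apply(abs(v3), 1, mean)),
               tolerance = 1e-12)
  expect_equal(temporal_profile(m3)$value, unname(apply(abs(v3), 2, mean)),
               tolerance = 1e-12)

  # profiles commute with channel relabeling
  perm <- c(3L, 1L, 2L, 5L, 4L, 8L, 6L, 7L)
  lay_p <- channel_layout(layout$names[perm], layout$positions[perm, ])
  mp <- saliency_map(v3[perm, ], oracle_times, lay_p)
  expect_equal(unname(spatial_profile(mp)), unname(spatial_profile(m3)[perm]))
  expect_equal(temporal_profile(mp)$value, temporal_profile(m3)$value)
})

test_that("peak_gradient: peak, tie and window rules", {
  prof <- data.frame(time = oracle_times, value = 0)
  prof$value[oracle_times == 352] <- 2
  pk <- peak_gradient(prof, c(300, 400))
  expect_equal(pk$latency, 352)
  expect_equal(pk$value, 2)
  # flat profile: earliest sample of the window
  flat <- data.frame(time = oracle_times, value = 1)
  expect_equal(peak_gradient(flat, c(300, 400))$latency, 300)
  # two equal peaks: earliest wins
  two <- data.frame(time = oracle_times, value = 0)
  two$value[oracle_times %in% c(320, 380)] <- 5
  expect_equal(peak_gradient(two, c(300, 400))$latency, 320)
  expect_error(peak_gradient(prof, c(900, 1000)), "empty")
})

test_that("most_varied_interval matches brute-force enumeration", {
  layout <- channel_layout()
  v <- matrix(0, 8, 201)
  v[6, oracle_times >= 350 & oracle_times <= 450] <- 1
  m <- saliency_map(v, oracle_times, layout)
  iv <- most_varied_interval(m, "Pz")
  expect_equal(c(iv$start, iv$end, iv$center), c(350, 450, 400))

  # uniform row: earliest window by the tie rule
  vu <- matrix(1, 8, 201)
  ivu <- most_varied_interval(saliency_map(vu, oracle_times, layout), "Pz")
  expect_equal(c(ivu$start, ivu$end), c(-100, 0))

  # random row: exhaustive oracle over all 121 candidate windows
  set.seed(7)
  vr <- matrix(rnorm(8 * 201)^2, 8)
  mr <- saliency_map(vr, oracle_times, layout)
  for (stat in c("mean", "sum", "max")) {
    iv <- most_varied_interval(mr, "Pz", statistic = stat)
    fun <- get(stat)
    starts <- seq(-100, 600, by = 5)
    vals <- sapply(starts, function(s)
      fun(abs(vr[6, oracle_times >= s & oracle_times <= s + 100])))
    expect_equal(length(starts), 141L)
    expect_equal(iv$start, starts[which.max(vals)])
    expect_equal(iv$value, max(vals))
  }
  expect_error(most_varied_interval(mr, "Oz"), "unknown electrode")
})

test_that("latency_trend reproduces the Pearson closed form", {
  centers <- seq(420, 360, by = -10)
  tr <- latency_trend(centers)
  expect_equal(tr$r, -1)
  expect_lt(tr$p, 1e-10)
  # against a brute-force covariance-formula implementation
  set.seed(8)
  x <- 1:7
  y <- rev(sort(rnorm(7, 400, 20)))
  tr2 <- latency_trend(y, x)
  r_brute <- mean((x - mean(x)) * (y - mean(y))) /
    sqrt(mean((x - mean(x))^2) * mean((y - mean(y))^2))
  expect_equal(tr2$r, r_brute, tolerance = 1e-12)
  # permuted centers: near-zero correlation on average
  set.seed(9)
  rs <- replicate(300, latency_trend(sample(y), x)$r)
  expect_lt(abs(mean(rs)), 0.1)
  expect_error(latency_trend(rep(400, 7)), "constant")
})

test_that("session_intervals recovers oracle-defined windows per session", {
  # oracle whose weights concentrate where the injected P300 lives; the
  # pipeline-level table must locate that window per session cell
  cfg <- sim_config(seed = 51L, n_subjects = 1L, n_sessions = 2L,
                    blocks_per_session = 1L, runs_per_block = 4L,
                    noise = noise_spec(sigma = 1))
  ds <- generate_dataset(cfg, scenarios = "social")
  W <- matrix(0, 8, 201)
  W[6, ds$times >= 330 & ds$times <= 430] <- 1
  tab <- session_intervals(linear_oracle(W), ds)
  expect_identical(nrow(tab), 2L)
  expect_true(all(tab$center == 380))
  expect_true(all(tab$n == 4L))
})
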