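test_that("parameter counts follow the pinned layer stacks", {
  # a single 10 -> 64 affine layer contributes 10*64 + 64
  expect_equal(count_trainable_params(t2relax:::mod_dense(10, 64)), 704)
  # the full 1D stack: 704 + 4*4160 + 130
  expect_equal(count_trainable_params(build_nn1d()), 17474)
  # light U-Net preset: frozen value from an independent layer-by-layer
  # tally (down 5298 + 7026 + 18658, bottom 57794, up 16226 + 7010 + 621)
  expect_equal(count_trainable_params(build_cnn(channels = c(16, 16, 32, 64))),
               112633)
})

test_that("model building is seed-deterministic", {
  a <- build_nn1d(seed = 5)
  b <- build_nn1d(seed = 5)
  expect_identical(t2relax:::get_param_state(a$net),
                   t2relax:::get_param_state(b$net))
  c2 <- build_nn1d(seed = 6)
  expect_false(identical(t2relax:::get_param_state(a$net),
                         t2relax:::get_param_state(c2$net)))
  ca <- build_cnn(channels = c(4, 4, 6, 8), seed = 5)
  cb <- build_cnn(channels = c(4, 4, 6, 8), seed = 5)
  expect_identical(t2relax:::get_param_state(ca$net),
                   t2relax:::get_param_state(cb$net))
})

test_that("the U-Net is fully convolutional and shape-preserving", {
  m <- build_cnn(channels = c(4, 4, 6, 8), seed = 2)
  for (sz in c(16L, 24L)) {
    x <- array(runif(sz * sz * 10 * 1), c(sz, sz, 10, 1))
    y <- t2relax:::nn_forward(m$net, x, training = FALSE)
    expect_equal(dim(y), c(sz, sz, 2L, 1L))
  }
})

test_that("extract_pixel_curves flattens records deterministically", {
  sch <- synth_sched
  s0 <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2)
  tt <- matrix(c(1, 2, 3, 4), 2, 2)
  rec <- synthesize_series_pair(s0, tt, sch, sigma = 0, seed = 1)
  out <- extract_pixel_curves(list(rec))
  expect_equal(dim(out$curves), c(4L, 10L))
  # row-major pixel order: (1,1), (1,2), (2,1), (2,2)
  expect_equal(out$targets[, "s0"], c(0.1, 0.3, 0.2, 0.4))
  expect_equal(out$targets[, "t"], c(1, 3, 2, 4))
  expect_equal(out$curves[1, ], decay_signal(0.1, 1, sch))
  # record-major concatenation, 2 records of 2x2 -> 8 curves
  out2 <- extract_pixel_curves(list(rec, rec))
  expect_equal(dim(out2$curves), c(8L, 10L))
  expect_equal(out2$curves[5:8, ], out$curves)
  # mismatched schedules are an error
  rec2 <- synthesize_series_pair(s0, tt, echo_schedule(c(0.5, 1)), 0)
  expect_error(extract_pixel_curves(list(rec, rec2)), "schedule")
})

test_that("zero-epoch training returns the initial weights and empty history", {
  ds <- build_synthetic_dataset(synth_config(2, size = 8, mode = "urand", seed = 3))
  m <- build_nn1d(seed = 4)
  before <- t2relax:::get_param_state(m$net)
  m2 <- train_model(m, ds, train_config(epochs = 0, batch = 64, seed = 5))
  expect_identical(t2relax:::get_param_state(m2$net), before)
  expect_equal(nrow(m2$history), 0L)
  expect_true(m2$trained)
})

test_that("nn1d training reduces the loss and is reproducible", {
  ds <- build_synthetic_dataset(synth_config(6, size = 16, mode = "urand", seed = 6))
  run <- function() {
    m <- build_nn1d(seed = 7)
    train_model(m, ds, train_config(epochs = 15, batch = 512, seed = 8))
  }
  m1 <- run()
  expect_lt(min(m1$history$val_loss), 0.5 * m1$history$val_loss[1])
  m2 <- run()
  expect_identical(m1$history, m2$history)
  expect_identical(t2relax:::get_param_state(m1$net),
                   t2relax:::get_param_state(m2$net))
})

test_that("nn1d map prediction equals pixelwise application to extracted curves", {
  st <- scaled_study()
  rec <- st$test_corpus$records[[1]]
  pm <- predict_map(st$nn1d, rec$series)
  curves <- t2relax:::series_to_curves(rec$series)
  out <- t2relax:::nn_forward(st$nn1d$net, curves, training = FALSE)
  d <- dim(rec$series$data)
  expect_equal(pm$s0, matrix(out[, 1], d[1], d[2]))
  expect_equal(pm$t, matrix(out[, 2], d[1], d[2]))
  # prediction is deterministic in evaluation mode
  expect_identical(pm, predict_map(st$nn1d, rec$series))
})

test_that("prediction refuses a mismatched echo schedule", {
  st <- scaled_study()
  sch_other <- echo_schedule((1:10) / 10)
  ser <- image_series(array(0.5, c(32, 32, 10)), sch_other)
  expect_error(predict_map(st$cnn, ser), "schedule")
  expect_error(predict_map(st$nn1d, ser), "schedule")
  m <- build_nn1d()
  expect_error(predict_map(m, ser), "train")
})

test_that("supervised training confines predictions to the training range", {
  st <- scaled_study()
  # wild input: decay series whose T lies far outside the training range,
  # the distribution-shift regime where unconstrained fits run away
  wild_t <- matrix(with_seed_test(77, runif(32 * 32, 4, 8)), 32, 32)
  wild_s0 <- matrix(with_seed_test(78, runif(32 * 32, 0.2, 1)), 32, 32)
  wild <- synthesize_series_pair(wild_s0, wild_t, synth_sched,
                                 sigma = 0.05, seed = 79)$series
  for (model in list(st$cnn, st$nn1d)) {
    pm <- predict_map(model, wild)
    inside <- pm$t > -0.5 & pm$t < 5
    expect_gte(mean(inside), 0.99)
  }
})

test_that("accuracy ordering at low SNR: CNN, then NN1D, then unbounded NLLS", {
  st <- scaled_study()
  # per-series median absolute T error over low-SNR pixels (< 15 dB)
  low_snr_err <- function(estimate) {
    v <- vapply(st$test_corpus$records, function(rec) {
      snr <- snr_db(rec$truth$s0, rec$truth$t, rec$sigma, rec$series$schedule)
      sel <- is.finite(snr) & snr < 15
      if (sum(sel) < 50) return(NA_real_)
      pm <- estimate(rec$series)
      median(abs(pm$t - rec$truth$t)[sel])
    }, numeric(1))
    median(v, na.rm = TRUE)
  }
  e_cnn <- low_snr_err(function(s) predict_map(st$cnn, s))
  e_nn1d <- low_snr_err(function(s) predict_map(st$nn1d, s))
  e_nlls <- low_snr_err(function(s) fit_nlls(s)$map)
  expect_lt(e_cnn, e_nn1d)
  expect_lt(e_nn1d, e_nlls)
})
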