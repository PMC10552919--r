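test_that("layer-normalization statistics pool over good-channel entries", {
  seg <- manual_segment(rbind(c(1, 3), c(2, 2), c(9, 9)), target = 3)
  st <- ln_stats(seg)
  expect_equal(st$mu, 2)
  expect_equal(st$sigma, sqrt(0.5))

  seg2 <- manual_segment(rbind(c(5, 5), c(5, 5), c(0, 0)), target = 3)
  st2 <- ln_stats(seg2)
  expect_equal(st2$mu, 5)
  expect_equal(st2$sigma, 0)

  seg3 <- manual_segment(rbind(c(-1, 1), c(7, 7)), target = 2)
  expect_equal(ln_stats(seg3)$mu, 0)
  expect_equal(ln_stats(seg3)$sigma, 1)
})

test_that("layer normalization applies per-channel gain/bias and leaves the target row zero", {
  m <- manual_model(matrix(stats::rnorm(6), 3, 2),
                    gain = c(3, 1, 2), bias = c(1, 0, 1))
  seg <- manual_segment(rbind(c(2, 4), c(9, 9), c(8, 8)), target = 3)
  st <- list(mu = 2, sigma = 1 - 1e-5, epsilon = 1e-5)
  class(st) <- "norm_stats"
  out <- ln_transform(seg, st, m)
  expect_equal(out[1, ], c(1, 7))         # 3*(x-2)/1 + 1
  expect_equal(out[3, ], c(0, 0))         # target untouched

  # identity when g=1, b=0, mu=0, sigma=1
  m1 <- manual_model(matrix(0.1, 2, 2))
  seg1 <- manual_segment(rbind(c(0.5, -0.5), c(0, 0)), target = 2)
  stI <- structure(list(mu = 0, sigma = 1 - 1e-5, epsilon = 1e-5), class = "norm_stats")
  expect_equal(ln_transform(seg1, stI, m1)[1, ], c(0.5, -0.5))
})

test_that("label transform uses good-channel stats with the target's gain and bias", {
  m <- manual_model(matrix(0.1, 3, 2), gain = c(1, 1, 2), bias = c(0, 0, 1))
  seg <- manual_segment(rbind(c(0, 0), c(0, 0), c(1, -1)), target = 3)
  st <- structure(list(mu = 0, sigma = 1 - 1e-5, epsilon = 1e-5), class = "norm_stats")
  expect_equal(transform_label(seg, st, m), c(3, -1))

  # centering: label equal to mu maps to the bias
  seg2 <- manual_segment(rbind(c(2, 2), c(2, 2), c(2, 2)), target = 3)
  st2 <- structure(list(mu = 2, sigma = 1 - 1e-5, epsilon = 1e-5), class = "norm_stats")
  m2 <- manual_model(matrix(0.1, 3, 2))
  expect_equal(transform_label(seg2, st2, m2), c(0, 0))

  # consistency: a label identical to a good row transforms identically
  # when gain/bias match (counterfactual target pass through ln_transform)
  set.seed(1)
  dat <- matrix(stats::rnorm(8 * 20), 8, 20)
  dat[5, ] <- dat[2, ]
  seg3 <- manual_segment(dat, target = 5)
  m3 <- amacw_model(tiny_channels(8), 4, seed = 2)
  m3$gain[5] <- m3$gain[2] <- 1.3
  m3$bias[5] <- m3$bias[2] <- -0.2
  st3 <- ln_stats(seg3)
  expect_equal(transform_label(seg3, st3, m3),
               ln_transform(seg3, st3, m3)[2, ])
})

test_that("channel masking zeroes only good rows, within bounds, reproducibly", {
  set.seed(10)
  dat <- matrix(stats::rnorm(17 * 30), 17, 30)
  seg <- manual_segment(dat, target = 4)

  res0 <- apply_channel_mask(seg, 0, 0)
  expect_identical(res0$segment$input, seg$input)
  expect_length(res0$masked, 0)

  res5 <- apply_channel_mask(seg, 5, 5)
  expect_length(res5$masked, 5)
  expect_false(4 %in% res5$masked)
  expect_true(all(res5$segment$input[res5$masked, ] == 0))
  expect_equal(res5$segment$input[4, ], rep(0, 30))
  expect_identical(res5$segment$label, seg$label)

  set.seed(77); a <- apply_channel_mask(seg, 0, 5)
  set.seed(77); b <- apply_channel_mask(seg, 0, 5)
  expect_identical(a$masked, b$masked)

  seg_small <- manual_segment(matrix(stats::rnorm(4 * 10), 4, 10), target = 1)
  expect_error(apply_channel_mask(seg_small, 0, 3), "at most")
})

test_that("analytic gradients match finite differences", {
  set.seed(3)
  dat <- matrix(stats::rnorm(6 * 30), 6, 30)
  seg <- manual_segment(dat, target = 6)
  m <- amacw_model(tiny_channels(6), 4, seed = 9)
  m$gain <- m$gain + stats::runif(6, -0.2, 0.2)
  m$bias <- m$bias + stats::runif(6, -0.2, 0.2)
  masked <- 2L
  g <- amacw:::segment_grad(m, seg, masked)
  eps <- 1e-6
  fd <- function(set_get) {
    cur <- set_get$get(m)
    out <- cur * 0
    for (i in seq_along(cur)) {
      up <- cur; up[i] <- up[i] + eps
      dn <- cur; dn[i] <- dn[i] - eps
      lu <- amacw:::segment_grad(set_get$set(m, up), seg, masked, want_grad = FALSE)$loss
      ld <- amacw:::segment_grad(set_get$set(m, dn), seg, masked, want_grad = FALSE)$loss
      out[i] <- (lu - ld) / (2 * eps)
    }
    out
  }
  gE_fd <- fd(list(get = function(m) m$embeddings,
                   set = function(m, v) { m$embeddings <- v; m }))
  expect_equal(g$gE, unname(as.matrix(gE_fd)), tolerance = 1e-6)
  # gain/bias gradients: label transform is a data transformation, so the
  # finite difference must also hold the label-side parameters fixed; check
  # only the good, unmasked channels where gradients flow
  gg_fd <- fd(list(get = function(m) m$gain,
                   set = function(m, v) { m$gain <- v; m }))
  gb_fd <- fd(list(get = function(m) m$bias,
                   set = function(m, v) { m$bias <- v; m }))
  good_unmasked <- setdiff(1:5, masked)
  expect_equal(g$gg[good_unmasked], unname(gg_fd[good_unmasked]), tolerance = 1e-6)
  expect_equal(g$gb[good_unmasked], unname(gb_fd[good_unmasked]), tolerance = 1e-6)
  expect_equal(g$gg[masked], 0)
  expect_equal(g$gb[masked], 0)
})

test_that("a perfect prediction yields zero loss; attention on a masked channel forces loss", {
  # two identical channels: target duplicates ch1; one-hot weights on ch1
  dat <- rbind(sin(1:40), cos(1:40), sin(1:40))
  seg <- manual_segment(dat, target = 3)
  E <- rbind(c(1, 0), c(0, 1), c(1, 0))   # target scores: ch1 = 1, ch2 = 0
  m <- manual_model(E)
  expect_lt(amacw:::segment_grad(m, seg, integer(0), want_grad = FALSE)$loss, 1e-20)

  # same model but ch1 masked: prediction is zero, loss = mean(label'^2)
  st <- ln_stats(seg)
  labeln <- transform_label(seg, st, m)
  loss_masked <- amacw:::segment_grad(m, seg, 1L, want_grad = FALSE)$loss
  expect_equal(loss_masked, mean(labeln^2))
  expect_gt(loss_masked, 0.1)
})

test_that("training steps are deterministic under a fixed seed", {
  fx <- linear_target_fixture(C = 6, weights_true = c(0.6, 0.4, 0, 0, 0),
                              T = 1000, seed = 5)
  segs <- make_training_segments(fx$recording, L = 200, seed = 5, target = 6)
  m <- amacw_model(fx$recording$channels, 4, seed = 5)
  cfg <- train_config(seed = 5, mask_max = 3)
  run <- function() {
    set.seed(1)
    s1 <- training_step(m, segs, NULL, cfg)
    s2 <- training_step(s1$model, segs, s1$opt, cfg)
    c(s1$loss, s2$loss)
  }
  expect_identical(run(), run())
})

test_that("validation is deterministic, nonnegative and near zero for an exact family member", {
  fx <- linear_target_fixture(C = 5, weights_true = c(0.6, 0.4, 0, 0),
                              T = 1000, noise_sd = 0, seed = 8)
  segs <- make_training_segments(fx$recording, L = 200, seed = 8, target = 5)
  # model with exact true weights: scores proportional to (0.6, 0.4, 0, 0)
  E <- rbind(c(0.6, 0), c(0.4, 0), c(0, 1e-8), c(0, 1e-8), c(1, 0))
  m <- manual_model(E[, , drop = FALSE])
  m$channels <- fx$recording$channels
  rownames(m$embeddings) <- m$channels$names
  expect_lt(validate(m, segs), 1e-6)
  mr <- amacw_model(fx$recording$channels, 4, seed = 1)
  v1 <- validate(mr, segs)
  expect_identical(v1, validate(mr, segs))
  expect_gte(v1, 0)
})

test_that("training recovers known mixing weights and improves validation loss", {
  fx <- linear_target_fixture(C = 8, weights_true = c(0.5, -0.3, 0.2, rep(0, 4)),
                              T = 6000, noise_sd = 0.01, seed = 21)
  segs <- make_training_segments(fx$recording, L = 200, seed = 21, target = 8)
  m0 <- amacw_model(fx$recording$channels, 8, seed = 21)
  cfg <- train_config(seed = 21, mask_max = 5, max_epochs = 1500)
  fit <- train(m0, segs, cfg)
  w <- channel_weights(fit$model, 8)$weights
  expect_lt(abs(w[1] - 0.5), 0.06)
  expect_lt(abs(w[2] + 0.3), 0.06)
  expect_lt(abs(w[3] - 0.2), 0.06)
  # signed weight recovered with its sign
  expect_lt(w[2], 0)
  # validation loss improved over the initial model
  checks <- fit$history[!is.na(fit$history$val_loss), ]
  expect_gt(nrow(checks), 0)
  expect_lte(min(checks$val_loss), checks$val_loss[1])
  expect_lt(fit$best_val_loss, validate(m0, segs))
  # reproducibility of the full run
  fit2 <- train(amacw_model(fx$recording$channels, 8, seed = 21), segs, cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$model$embeddings, fit2$model$embeddings)
})
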