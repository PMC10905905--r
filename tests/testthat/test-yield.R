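tiny_yield_parts <- function(seed = 3, hidden = 24L, rep_dim = 16L) {
  gin <- tiny_gin(L = 2, hidden = hidden, rep_dim = rep_dim, seed = seed)
  head <- ginyield:::yield_head_init(rep_dim, hidden = 20L, seed = seed + 1)
  list(gin = gin, head = head)
}

test_that("the mixed loss evaluates its limit and plug-in cases exactly", {
  expect_equal(finetune_loss(3, 1, 0.5, alpha = 0), 4)      # pure squared error
  expect_equal(finetune_loss(2, 2, 1, alpha = 1), 0)        # log 1 = 0
  expect_equal(finetune_loss(1, 0, 1, alpha = 0.5), 1)
  for (alpha in c(0, 0.1, 0.5, 0.9, 1)) {
    y <- 1.7; mu <- 0.4; s2 <- 2.3
    expect_equal(finetune_loss(y, mu, s2, alpha),
                 (1 - alpha) * (y - mu)^2 +
                   alpha * ((y - mu)^2 / s2 + log(s2)),
                 tolerance = 1e-12)
  }
  expect_error(finetune_loss(1, 0, 0, 0.5), class = "ginyield_domain_error")
  expect_error(finetune_loss(1, 0, -1, 0.5), class = "ginyield_domain_error")
  expect_error(finetune_loss(1, 0, 1, 1.5), class = "ginyield_domain_error")
})

test_that("the loss is stationary in the mean at a perfect prediction", {
  h <- 1e-6
  for (alpha in c(0, 0.3, 1)) {
    for (s2 in c(0.5, 1, 4)) {
      g <- (finetune_loss(2, 2 + h, s2, alpha) -
              finetune_loss(2, 2 - h, s2, alpha)) / (2 * h)
      expect_equal(g, 0, tolerance = 1e-6)
    }
  }
})

test_that("predictions are invariant to reactant order and the variance is always positive", {
  parts <- tiny_yield_parts()
  reactions <- fixture_reactions()$rxn[1:25]
  for (i in seq_along(reactions)) {
    rx <- reactions[[i]]
    pred <- yield_forward(rx, parts$gin, parts$head)
    expect_gt(pred$sigma2, 0)
    if (length(rx$reactants) > 1) {
      perm <- rev(seq_along(rx$reactants))
      rx2 <- list(reactants = rx$reactants[perm], product = rx$product)
      pred2 <- yield_forward(rx2, parts$gin, parts$head)
      expect_equal(pred2$mu, pred$mu, tolerance = 1e-6)
      expect_equal(pred2$sigma2, pred$sigma2, tolerance = 1e-6)
    }
  }
  # deterministic mode is bit-reproducible
  p1 <- yield_forward(reactions[[1]], parts$gin, parts$head)
  p2 <- yield_forward(reactions[[1]], parts$gin, parts$head)
  expect_identical(p1, p2)
  expect_error(yield_forward(list(reactants = list(),
                                  product = reactions[[1]]$product),
                             parts$gin, parts$head),
               class = "ginyield_input_error")
})

test_that("initialization copies the encoder exactly and re-draws only the head", {
  dat <- fixture_pretrain_data()[1:16, ]
  attr(dat, "eigenvalues") <- attr(fixture_pretrain_data(), "eigenvalues")
  fit <- run_pretraining(dat, gin = tiny_gin(),
                         config = pretrain_config(epochs = 1, batch_size = 8,
                                                  seed = 1))

  init <- init_yield_model(pretrained = fit, head_hidden = 20L,
                           head_init_seed = 5)
  expect_identical(init$gin$w, fit$gin$w)
  # the auxiliary pre-training head is not part of the yield model
  expect_false(any(c("head_W", "head_b") %in% names(init$gin$w)))

  init2 <- init_yield_model(pretrained = fit, head_hidden = 20L,
                            head_init_seed = 6)
  expect_identical(init2$gin$w, init$gin$w)
  expect_false(identical(init2$head$W1, init$head$W1))

  # checkpoint round trip preserves the weight payload exactly
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  init3 <- init_yield_model(pretrained = path,
                            gin_template = fit$gin, head_hidden = 20L)
  expect_identical(init3$gin$w, fit$gin$w)

  # from-scratch mode: same architecture, different (random) weights
  scratch <- init_yield_model(gin_template = fit$gin, head_hidden = 20L,
                              head_init_seed = 5)
  expect_identical(scratch$gin$config, fit$gin$config)
  expect_false(identical(scratch$gin$w$Wn, fit$gin$w$Wn))
})

test_that("zero epochs returns the initialization; training reduces the loss", {
  parts <- tiny_yield_parts(seed = 9)
  rx <- fixture_reactions()[1:40, ]
  cfg0 <- finetune_config(epochs = 0, seed = 1)
  m0 <- run_finetuning(rx, parts, cfg0)
  expect_identical(m0$gin$w, parts$gin$w)
  expect_identical(m0$head$W1, parts$head$W1)

  cfg <- finetune_config(epochs = 12, batch_size = 16,
                         learning_rate = 2e-3, seed = 1)
  m <- run_finetuning(rx, parts, cfg)
  expect_lt(mean(tail(m$history$loss, 3)), mean(head(m$history$loss, 3)))
})

test_that("the model can memorize a handful of reactions", {
  parts <- tiny_yield_parts(seed = 13, hidden = 32L, rep_dim = 24L)
  rx <- fixture_reactions()[1:15, ]
  cfg <- finetune_config(epochs = 400, batch_size = 15,
                         learning_rate = 3e-3, weight_decay = 0,
                         dropout_rate = 0, alpha = 0.1,
                         lr_schedule = list(epochs = c(300L),
                                            rates = c(5e-4)),
                         seed = 2)
  m <- run_finetuning(rx, parts, cfg)
  pred <- predict(m, rx)
  rmse <- sqrt(mean((pred$yield - pred$.pred)^2))
  expect_lt(rmse, 2)
})

test_that("the staged learning-rate schedule is applied at the stated epochs", {
  parts <- tiny_yield_parts(seed = 21)
  rx <- fixture_reactions()[1:10, ]
  cfg <- finetune_config(epochs = 6, batch_size = 10,
                         lr_schedule = list(epochs = c(3L, 5L),
                                            rates = c(5e-5, 5e-6)),
                         seed = 1)
  m <- run_finetuning(rx, parts, cfg)
  expect_equal(m$history$learning_rate,
               c(5e-4, 5e-4, 5e-5, 5e-5, 5e-6, 5e-6))
  # schedule stages beyond the epoch count are dropped at construction
  short <- finetune_config(epochs = 60)
  expect_length(short$lr_schedule$epochs, 0)
  expect_error(finetune_config(lr_schedule = list(epochs = c(450L, 400L),
                                                  rates = c(1e-5, 1e-6))),
               class = "ginyield_config_error")
})

test_that("MC dropout honours its contracts (zero-dropout, T = 1, fixed seed)", {
  parts <- tiny_yield_parts(seed = 17)
  rx <- fixture_reactions()[1:8, ]
  cfg <- finetune_config(epochs = 0, dropout_rate = 0, mc_passes = 30)
  m <- run_finetuning(rx, parts, cfg)

  # dropout 0: all passes identical and equal to the deterministic forward
  p <- predict_mc_dropout(m, rx, passes = 30, seed = 4)
  samples <- attr(p, "mc_samples")
  expect_equal(apply(samples, 1, stats::sd), rep(0, nrow(rx)))
  det <- predict(m, rx)
  expect_equal(p$.pred, det$.pred, tolerance = 1e-12)

  # with dropout active: T = 1 is a single stochastic pass, seeds reproduce
  m$config$dropout_rate <- 0.2
  p1 <- predict_mc_dropout(m, rx, passes = 1, seed = 9)
  expect_equal(p1$.pred, attr(p1, "mc_samples")[, 1])
  p2 <- predict_mc_dropout(m, rx, passes = 7, seed = 9)
  p3 <- predict_mc_dropout(m, rx, passes = 7, seed = 9)
  expect_identical(p2$.pred, p3$.pred)
  p4 <- predict_mc_dropout(m, rx, passes = 7, seed = 10)
  expect_false(identical(p2$.pred, p4$.pred))
})

test_that("evaluation metrics match their definitions", {
  expect_equal(evaluate_predictions(truth = c(1, 2, 3), estimate = c(1, 2, 3)),
               tibble::tibble(rmse = 0, mae = 0, r2 = 1))
  # predicting the mean gives R^2 = 0
  y <- c(2, 4, 6, 8)
  ev <- evaluate_predictions(truth = y, estimate = rep(mean(y), 4))
  expect_equal(ev$r2, 0)
  # hand-computed case
  ev2 <- evaluate_predictions(truth = c(0, 10), estimate = c(0, 0))
  expect_equal(ev2$rmse, sqrt(50))
  expect_equal(ev2$mae, 5)
  expect_equal(ev2$r2, -1)
  # constant truths: R^2 undefined
  ev3 <- evaluate_predictions(truth = c(5, 5, 5), estimate = c(4, 5, 6))
  expect_true(is.na(ev3$r2))
  # norm inequality RMSE >= MAE on random data
  set.seed(77)
  for (i in 1:20) {
    n <- sample(2:50, 1)
    ev4 <- evaluate_predictions(truth = rnorm(n), estimate = rnorm(n))
    expect_gte(ev4$rmse, ev4$mae)
  }
})
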