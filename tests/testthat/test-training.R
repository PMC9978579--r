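test_that("analytic gradients of the full objective match finite differences", {
  set.seed(3)
  n <- 12; f <- 6; k <- 3
  m <- matrix(10^rnorm(n * f, 5, 1), n, f,
              dimnames = list(paste0("s", 1:n), paste0("f", 1:f)))
  b <- data.frame(sample = paste0("s", 1:n), batch = rep(c("A", "B"), each = 6),
                  group = rep(c("g", "g", "", "g", "g", ""), 2))
  pp <- preprocess_intensities(m)
  x <- pp$x
  model <- build_models(f, k, 2, seed = 1)
  yb <- matrix(0, n, 2); yb[cbind(1:n, rep(1:2, each = 6))] <- 1
  lg <- 0.7; ld <- 0.5; lv <- 0.9
  sets <- metabatch:::.replicate_sets(b)
  obj <- function(model) {
    fw <- metabatch:::.forward(model, x)
    recon <- mean((fw$xhat - x)^2)
    ce <- -mean(log(pmax(fw$p[cbind(1:n, max.col(yb))], 1e-12)))
    lvv <- metabatch:::.variation_loss_grad(fw$xhat, pp, sets)$value
    lg * recon - ld * ce + lv * lvv
  }
  fw <- metabatch:::.forward(model, x)
  g_xhat <- lg * 2 * (fw$xhat - x) / length(x) +
    lv * metabatch:::.variation_loss_grad(fw$xhat, pp, sets)$grad
  g_h2 <- g_xhat %*% t(model$W4)
  g_a3 <- g_h2 * metabatch:::.lrelu_grad(fw$a3, model$slope)
  g_z <- g_a3 %*% t(model$W3) - ld * ((fw$p - yb) / n) %*% t(model$W5)
  g_h1 <- g_z %*% t(model$W2)
  g_a1 <- g_h1 * metabatch:::.lrelu_grad(fw$a1, model$slope)
  ana <- list(W1 = crossprod(x, g_a1), b1 = colSums(g_a1),
              W2 = crossprod(fw$h1, g_z), b2 = colSums(g_z),
              W3 = crossprod(fw$z, g_a3), b3 = colSums(g_a3),
              W4 = crossprod(fw$h2, g_xhat), b4 = colSums(g_xhat))
  eps <- 1e-6
  for (nm in names(ana)) {
    num <- ana[[nm]] * 0
    for (i in seq_along(num)) {
      up <- model; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- model; dn[[nm]][i] <- dn[[nm]][i] - eps
      num[i] <- (obj(up) - obj(dn)) / (2 * eps)
    }
    expect_equal(unname(as.vector(ana[[nm]])), unname(as.vector(num)),
                 tolerance = 1e-5, info = nm)
  }
})

test_that("a plain autoencoder descends and runs are seed-reproducible", {
  sim <- simulate_batches(small_design(), seed = 8)
  m <- apply_min_intensity(sim$intensities)
  hp <- hyperparams(lambda_d = 0, lambda_v = 0, epochs = 25, seed = 4,
                    rg_every = 50)
  res <- train_normalizer(m, sim$batch_info, hp)
  expect_lt(res$history$recon[nrow(res$history)], res$history$recon[1])
  expect_identical(dimnames(res$normalized), dimnames(m))
  expect_gt(min(res$normalized), 0)

  res2 <- train_normalizer(m, sim$batch_info, hp)
  expect_equal(res$history, res2$history, tolerance = 1e-12)
  expect_equal(res$normalized, res2$normalized, tolerance = 1e-12)
})

test_that("adversarial training reduces batch predictability", {
  sim <- simulate_batches(small_design(), seed = 15)
  m <- apply_min_intensity(sim$intensities)
  res <- train_normalizer(m, sim$batch_info,
                          hyperparams(epochs = 80, seed = 2, rg_every = 20))
  before <- batch_mixing(m, sim$batch_info, seed = 3)
  after <- batch_mixing(res$normalized, sim$batch_info, seed = 3)
  expect_lt(abs(after$accuracy - after$chance),
            abs(before$accuracy - before$chance))
})

test_that("early stopping fires on the contracted conditions", {
  healthy <- data.frame(l_d = seq(2, 1, length.out = 30),
                        var_ratio = rep(0.8, 30))
  expect_false(early_stop_check(healthy)$stop)

  # classifier loss rising `patience` consecutive epochs after burn-in
  rising <- data.frame(l_d = c(seq(2, 1, length.out = 20), seq(1.1, 1.6, by = 0.1)),
                       var_ratio = 0.8)
  out <- early_stop_check(rising, window = 20, patience = 5)
  expect_true(out$stop)
  expect_equal(out$reason, "early_stop_classifier")
  # same history inside the burn-in window: keep going
  expect_false(early_stop_check(rising[1:10, ], window = 20, patience = 5)$stop)

  # collapse: near-constant decoder output
  collapsed <- data.frame(l_d = rep(1, 3), var_ratio = c(0.5, 0.1, 1e-4))
  out2 <- early_stop_check(collapsed)
  expect_true(out2$stop)
  expect_equal(out2$reason, "early_stop_collapse")
})

test_that("a constant-output model is flagged as collapsed", {
  sim <- simulate_batches(small_design(), seed = 5)
  m <- apply_min_intensity(sim$intensities)
  # force collapse: decoder weights and biases zeroed after a 1-epoch run
  res <- train_normalizer(m, sim$batch_info,
                          hyperparams(epochs = 1, seed = 1, rg_every = 10))
  x <- preprocess_intensities(m)$x
  mod <- res$model
  mod$W4[] <- 0; mod$b4[] <- 0
  xhat <- decode(mod, encode(mod, x))
  expect_lt(var(as.vector(xhat)) / var(as.vector(x)), 1e-3)
  hist <- data.frame(l_d = 1, var_ratio = var(as.vector(xhat)) / var(as.vector(x)))
  expect_equal(early_stop_check(hist)$reason, "early_stop_collapse")
})

test_that("grid search is deterministic and size-1 equals a direct run", {
  sim <- simulate_batches(small_design(), seed = 20)
  m <- apply_min_intensity(sim$intensities)
  cfg <- default_config(grid_size = 1, epochs = 10, seed = 42)
  g <- grid_search(m, sim$batch_info, cfg)
  expect_length(g$results, 1)
  g2 <- grid_search(m, sim$batch_info, cfg)
  expect_identical(g$grid, g2$grid)
  expect_equal(g$results[[1]]$normalized, g2$results[[1]]$normalized,
               tolerance = 1e-12)

  hp <- hyperparams(lambda_g = g$grid$lambda_g[1], lambda_d = g$grid$lambda_d[1],
                    lambda_v = g$grid$lambda_v[1], lr_ae = g$grid$lr_ae[1],
                    lr_cls = g$grid$lr_cls[1], epochs = cfg$epochs,
                    batch_size = cfg$batch_size, seed = g$grid$seed[1])
  direct <- train_normalizer(m, sim$batch_info, hp)
  expect_equal(g$results[[1]]$normalized, direct$normalized, tolerance = 1e-12)
})

test_that("model selection ranks by the four criteria with dominance", {
  fake <- function(between, vc, inflation, acc, chance = 0.2) {
    structure(list(stop_reason = "completed",
                   evaluation = list(
                     between_batch_corr = list(mean = between),
                     mean_batch_vc = vc, vc_inflation = inflation,
                     batch_mixing = list(accuracy = acc, chance = chance))),
              class = "mb_result")
  }
  # single candidate is returned
  one <- select_best(list(fake(0.9, 0.1, 0.0, 0.3)))
  expect_equal(one$evaluation$between_batch_corr$mean, 0.9)

  # dominance on all four criteria wins
  best <- select_best(list(fake(0.95, 0.05, 0.0, 0.22),
                           fake(0.80, 0.20, 0.5, 0.90),
                           fake(0.90, 0.10, 0.1, 0.40)))
  expect_equal(best$evaluation$between_batch_corr$mean, 0.95)

  # two candidates differing only in mean VC: lower VC wins
  win <- select_best(list(fake(0.9, 0.20, 0.1, 0.4),
                          fake(0.9, 0.05, 0.1, 0.4)))
  expect_equal(win$evaluation$mean_batch_vc, 0.05)
  expect_equal(nrow(win$ranking), 2)

  # failed runs are excluded; all-failed errors
  failed <- structure(list(stop_reason = "error", error = "boom"),
                      class = "mb_result")
  expect_equal(select_best(list(failed, fake(0.9, 0.1, 0, 0.3)))$evaluation$mean_batch_vc,
               0.1)
  expect_error(select_best(list(failed)), "all grid-search runs failed")
})

test_that("preprocessing inverts exactly and guarantees positivity", {
  td <- toy_data()
  pp <- preprocess_intensities(td$m)
  expect_equal(inverse_preprocess(pp$x, pp), td$m, tolerance = 1e-12)
  expect_true(all(inverse_preprocess(pp$x - 100, pp) > 0))
  expect_error(preprocess_intensities(td$m * 0), "strictly positive")
})
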