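test_that("replicate correlations split pairs by batch membership", {
  # 3 replicates in 2 batches (2+1): 1 within-batch pair, 2 between
  set.seed(6)
  v <- 10^rnorm(8, 5, 1)
  m <- rbind(r1 = v, r2 = v, r3 = v, other = 10^rnorm(8, 5, 1))
  colnames(m) <- paste0("f", 1:8)
  b <- data.frame(sample = rownames(m), batch = c("A", "A", "B", "B"),
                  group = c("g", "g", "g", ""))
  rc <- replicate_correlations(m, b)
  expect_length(rc$within, 1)
  expect_length(rc$between, 2)
  # duplicate rows correlate perfectly
  expect_equal(unname(c(rc$within, rc$between)), rep(1, 3))

  # reversed ranking gives negative correlation
  m2 <- m
  m2["r3", ] <- max(v) + min(v) - v        # order inverted
  rc2 <- replicate_correlations(m2, b, log_scale = FALSE)
  expect_true(all(rc2$between < 0))
  expect_error(replicate_correlations(m, transform(b, group = "")),
               "no evaluable")
})

test_that("batch VCs share the variation-loss oracle and are scale-free", {
  b <- data.frame(sample = paste0("s", 1:3), batch = "B1", group = "g")
  m <- matrix(c(1, 2, 3), 3, 1, dimnames = list(b$sample, "f1"))
  out <- batch_vc(m, b)
  expect_equal(out$mean, 0.5)
  expect_equal(out$table$vc, 0.5)
  expect_equal(batch_vc(m * 2, b)$mean, out$mean)   # doubling is invariant
  # identical replicates -> 0
  expect_equal(batch_vc(matrix(5, 3, 2, dimnames = list(b$sample, NULL)),
                        b)$mean, 0)
  # agreement with variation_loss on a random instance
  td <- toy_data(n_per_batch = 4, seed = 7)
  expect_equal(batch_vc(td$m, td$b)$mean, variation_loss(td$m, td$b))
})

test_that("VC inflation counts features straddling the 5% cutoff", {
  b <- data.frame(sample = paste0("s", 1:3), batch = "B1", group = "g")
  base <- c(1, 2, 3)                        # VC = 0.5
  stretch <- function(f) 2 + f * (base - 2) # mean 2, VC = 0.5 * f
  before <- cbind(f1 = base, f2 = base)
  rownames(before) <- b$sample
  expect_equal(as.numeric(vc_inflation(before, before, b)), 0)

  # f1 inflates by 10%, f2 shrinks -> fraction 0.5
  after <- cbind(f1 = stretch(1.10), f2 = stretch(0.8))
  rownames(after) <- b$sample
  expect_equal(as.numeric(vc_inflation(before, after, b)), 0.5)

  # straddle the cutoff: +4.9% not inflated, +5.1% inflated
  after2 <- cbind(f1 = stretch(1.049), f2 = stretch(1.051))
  rownames(after2) <- b$sample
  expect_equal(as.numeric(vc_inflation(before, after2, b)), 0.5)
  expect_equal(as.numeric(vc_inflation(before, after2, b, threshold = 0.04)), 1)

  # monotone non-increasing in the threshold; infinite threshold -> 0
  ths <- c(0.01, 0.05, 0.2, 1, Inf)
  fr <- vapply(ths, function(t) as.numeric(vc_inflation(before, after, b, t)),
               numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_equal(fr[length(fr)], 0)
  expect_error(vc_inflation(before, after[1:2, ], b), "shape")
})

test_that("the batch-mixing probe detects separation and its absence", {
  set.seed(5)
  # two batches drawn from the identical distribution: no batch signal
  m <- matrix(10^rnorm(80 * 15, 5, 1), 80, 15)
  rownames(m) <- paste0("s", 1:80)
  base <- m[1:40, ]
  b <- data.frame(sample = rownames(m), batch = rep(c("A", "B"), each = 40),
                  group = "")
  mix <- batch_mixing(m, b, seed = 1)
  expect_equal(mix$chance, 0.5)
  expect_lt(abs(mix$accuracy - mix$chance), 0.2)

  # second batch shifted by a large factor: fully separable
  m2 <- rbind(base, base * 50)
  rownames(m2) <- rownames(m)
  expect_gt(batch_mixing(m2, b, seed = 1)$accuracy, 0.9)

  expect_error(batch_mixing(m, transform(b, batch = "A")), ">= 2 batches")
})

test_that("spectra preservation tracks feature mean-intensity ranking", {
  set.seed(9)
  before <- matrix(10^rnorm(10 * 200, 5, 1), 10, 200)
  ss <- spectra_shift(before, before * 3.7)   # global rescale
  expect_equal(ss$rank_correlation, 1)
  expect_equal(spectra_shift(before, before)$max_z_displacement, 0)
  # permuting features destroys the ranking
  perm <- sample(200)
  expect_lt(abs(spectra_shift(before, before[, perm])$rank_correlation), 0.2)
  expect_error(spectra_shift(before, before[, 1:10]), "feature sets")
})

test_that("the bundled report carries the input baselines", {
  td <- toy_data(n_per_batch = 4, n_features = 6, seed = 2)
  ev <- evaluate_normalization(td$m, td$m * 1.01, td$b, seed = 1)
  expect_s3_class(ev, "mb_eval")
  expect_true(is.finite(ev$between_batch_corr$mean))
  expect_true(ev$vc_inflation >= 0 && ev$vc_inflation <= 1)
  expect_output(print(ev), "between-batch replicate correlation")
})
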