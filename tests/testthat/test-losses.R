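test_that("reconstruction loss behaves like a mean error", {
  x <- matrix(c(0, 0, 1, 2), 2, 2)
  expect_equal(reconstruction_loss(x, x), 0)
  expect_equal(reconstruction_loss(matrix(0, 1, 2), matrix(1, 1, 2)), 1)
  xh <- x + matrix(c(1, -1, 2, 0), 2, 2)
  perm <- c(2, 1)
  expect_equal(reconstruction_loss(x[perm, ], xh[perm, ]),
               reconstruction_loss(x, xh))
  expect_equal(reconstruction_loss(x, xh, type = "mae"), mean(abs(x - xh)))
  expect_error(reconstruction_loss(x, matrix(0, 3, 2)), "shape")
})

test_that("pair co-clustering fraction matches brute-force enumeration", {
  # group of 4 split 3+1: 6 pairs, 3 together -> 0.5
  expect_equal(metabatch:::.pair_separation(c(1, 1, 1, 2), rep("g", 4)), 0.5)
  # perfect co-clustering -> 0; full separation -> 1
  expect_equal(metabatch:::.pair_separation(c(7, 7, 7), rep("g", 3)), 0)
  expect_equal(metabatch:::.pair_separation(1:4, rep("g", 4)), 1)
  # noise points never co-cluster (each its own singleton)
  expect_equal(metabatch:::.pair_separation(c(0, 0), rep("g", 2)), 1)
  # brute-force oracle on a random case
  set.seed(2)
  labs <- sample(0:3, 12, replace = TRUE)
  groups <- sample(c("a", "b", ""), 12, replace = TRUE)
  brute <- local({
    tot <- 0; tog <- 0
    for (i in 1:11) for (j in (i + 1):12) {
      if (groups[i] != "" && groups[i] == groups[j]) {
        tot <- tot + 1
        if (labs[i] == labs[j] && labs[i] != 0) tog <- tog + 1
      }
    }
    1 - tog / tot
  })
  expect_equal(metabatch:::.pair_separation(labs, groups), brute)
})

test_that("grouping term hits its zero point and its ceiling", {
  cl <- clustered_latent()
  expect_identical(grouping_term(cl$latent, cl$b, seed = 5), 0)

  # replicates scattered arbitrarily: far from zero
  set.seed(8)
  scattered <- matrix(rnorm(44 * 6), 44, 6)
  expect_gt(grouping_term(scattered, cl$b, seed = 5), 0.5)

  # no evaluable pairs: 0 with a warning
  b_none <- cl$b; b_none$group <- ""
  expect_warning(r <- grouping_term(cl$latent, b_none), "no evaluable")
  expect_identical(r, 0)
})

test_that("distance-based grouping term is scale-free and zero at coincidence", {
  cl <- clustered_latent()
  # replicates collapsed onto their group centroids -> 0
  lat0 <- cl$latent
  for (g in unique(cl$b$group[cl$b$group != ""])) {
    idx <- cl$b$group == g
    lat0[idx, ] <- matrix(colMeans(lat0[idx, , drop = FALSE]),
                          sum(idx), ncol(lat0), byrow = TRUE)
  }
  expect_equal(grouping_term_distance(lat0, cl$b), 0)
  # invariance under global scaling
  expect_equal(grouping_term_distance(cl$latent * 13, cl$b),
               grouping_term_distance(cl$latent, cl$b))
  # replicates scattered like everything else: ratio near 1 (Monte Carlo)
  set.seed(10)
  vals <- replicate(20, {
    grouping_term_distance(matrix(rnorm(40 * 4), 40, 4),
                           data.frame(sample = paste0("s", 1:40),
                                      batch = "A",
                                      group = rep(c("g", ""), 20)))
  })
  expect_equal(mean(vals), 1, tolerance = 0.1)
  expect_error(grouping_term_distance(lat0, transform(cl$b, group = "")),
               "no evaluable")
})

test_that("classifier loss has the textbook closed forms", {
  unif <- matrix(1 / 4, 6, 4, dimnames = list(NULL, paste0("B", 1:4)))
  expect_equal(classifier_loss(unif, rep(paste0("B", 1:2), 3)), log(4))
  onehot <- diag(3); colnames(onehot) <- paste0("B", 1:3)
  expect_equal(classifier_loss(pmin(pmax(onehot, 1e-15), 1), paste0("B", 1:3)),
               0, tolerance = 1e-10)
  two <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE,
                dimnames = list(NULL, c("B1", "B2")))
  expect_equal(classifier_loss(two, c("B1", "B2")), -log(0.9))
  expect_error(classifier_loss(unif[1:2, ], c("B1", "B1")), ">= 2 batches")
})

test_that("variation loss equals the brute-force VC mean", {
  b <- data.frame(sample = paste0("s", 1:4), batch = "B1",
                  group = c("g", "g", "g", ""))
  m <- matrix(c(1, 2, 3, 50), 4, 1,
              dimnames = list(b$sample, "f1"))
  expect_equal(variation_loss(m, b), 0.5)    # sd 1, mean 2
  # unrelated non-reference sample does not enter
  m2 <- m; m2[4, 1] <- 1e9
  expect_equal(variation_loss(m2, b), 0.5)
  # identical replicates -> 0
  m3 <- m; m3[1:3, 1] <- 7
  expect_equal(variation_loss(m3, b), 0)

  # brute-force triple loop oracle on a random instance
  td <- toy_data(n_per_batch = 4, n_features = 3, seed = 3)
  brute <- local({
    vcs <- c()
    for (g in unique(td$b$group[td$b$group != ""])) {
      for (bt in unique(td$b$batch)) {
        idx <- which(td$b$group == g & td$b$batch == bt)
        if (length(idx) < 2) next
        for (j in seq_len(ncol(td$m))) {
          v <- td$m[idx, j]
          vcs <- c(vcs, sd(v) / mean(v))
        }
      }
    }
    mean(vcs)
  })
  expect_equal(variation_loss(td$m, td$b), brute)
  expect_error(variation_loss(td$m, transform(td$b, group = "")),
               "replicate")
})

test_that("the analytic variation-loss gradient matches finite differences", {
  set.seed(3)
  n <- 6; f <- 4
  m <- matrix(10^rnorm(n * f, 4, 0.5), n, f,
              dimnames = list(paste0("s", 1:n), paste0("f", 1:f)))
  pp <- preprocess_intensities(m)
  sets <- list(c(1L, 2L, 3L), c(4L, 5L))
  xh <- pp$x + matrix(rnorm(n * f, 0, 0.1), n, f)
  an <- metabatch:::.variation_loss_grad(xh, pp, sets)
  num <- xh * 0
  eps <- 1e-6
  for (i in seq_along(xh)) {
    up <- xh; up[i] <- up[i] + eps
    dn <- xh; dn[i] <- dn[i] - eps
    num[i] <- (metabatch:::.variation_loss_grad(up, pp, sets)$value -
               metabatch:::.variation_loss_grad(dn, pp, sets)$value) / (2 * eps)
  }
  expect_equal(an$grad, num, tolerance = 1e-5)
})

test_that("loss aggregation is linear with the adversarial sign", {
  w <- loss_weights(2, 3, 4)
  expect_equal(aggregate_loss(0.5, 0.1, 1.2, 0.3, w),
               2 * 0.6 - 3 * 1.2 + 4 * 0.3)
  expect_equal(aggregate_loss(0.5, 0.1, 1.2, 0.3, loss_weights(0, 0, 0)), 0)
  expect_equal(aggregate_loss(0.5, 0.1, 1.2, 0.3, loss_weights(2, 0, 0)),
               2 * 0.6)
  # increasing L_d strictly decreases L when lambda_d > 0
  expect_lt(aggregate_loss(0.5, 0.1, 2.0, 0.3, w),
            aggregate_loss(0.5, 0.1, 1.2, 0.3, w))
  # linear in each lambda
  l1 <- aggregate_loss(1, 0, 1, 1, loss_weights(1, 1, 1))
  l2 <- aggregate_loss(1, 0, 1, 1, loss_weights(2, 1, 1))
  l3 <- aggregate_loss(1, 0, 1, 1, loss_weights(3, 1, 1))
  expect_equal(l3 - l2, l2 - l1)
  expect_error(loss_weights(-1, 0, 0))
})
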