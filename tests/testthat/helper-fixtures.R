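# Fixtures are generated in code; no data files.

# tiny hand-sized intensity matrix with batch info
toy_data <- function(n_per_batch = 3, n_features = 4, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_batch
  m <- matrix(10^rnorm(n * n_features, 5, 1), n, n_features,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("f%02d", seq_len(n_features))))
  b <- data.frame(sample = rownames(m),
                  batch = rep(c("B1", "B2"), each = n_per_batch),
                  group = rep(c("qc", "qc", ""), length.out = n),
                  stringsAsFactors = FALSE)
  list(m = m, b = b)
}

# small but realistic simulation for training tests
small_design <- function(...) {
  simulation_design(n_batches = 3, n_features = 20, n_nonreference = 6,
                    reference_groups = list(
                      list(name = "qc", n_replicates = 3, batches = 1:3)),
                    ...)
}

# 3 well-separated 5-D blobs (frozen oracle fixture A)
blob_fixture <- function() {
  set.seed(7)
  blob <- function(center, n) {
    sweep(matrix(rnorm(n * 5, 0, 0.3), n, 5), 2, center, "+")
  }
  x <- rbind(blob(c(5, 0, 0, 0, 0), 20), blob(c(0, 5, 0, 0, 0), 20),
             blob(c(0, 0, 5, 0, 0), 20))
  list(x = x, truth = rep(1:3, each = 20))
}

# two blobs of unequal density plus uniform background (fixture B)
noisy_fixture <- function() {
  set.seed(42)
  rbind(matrix(rnorm(60, 0, 0.2), 30, 2),
        sweep(matrix(rnorm(40, 0, 0.6), 20, 2), 2, c(5, 5), "+"),
        matrix(runif(30, -3, 8), 15, 2))
}

# do two label vectors define the same partition (same noise set, same
# co-membership)?  noise is 0 in ours, -1 in the reference labels.
same_partition <- function(a, b, noise_a = 0L, noise_b = -1L) {
  if (!all((a == noise_a) == (b == noise_b))) return(FALSE)
  keep <- a != noise_a
  a <- a[keep]; b <- b[keep]
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# latent-space configuration whose reference groups are unambiguous
# tight, well-separated clumps
clustered_latent <- function(seed = 1) {
  set.seed(seed)
  clump <- function(center) {
    sweep(matrix(rnorm(8 * 6, 0, 0.05), 8, 6), 2, center, "+")
  }
  lat <- rbind(clump(c(10, 0, 0, 0, 0, 0)), clump(c(0, 10, 0, 0, 0, 0)),
               clump(c(0, 0, 10, 0, 0, 0)),
               matrix(rnorm(20 * 6, 0, 0.3), 20, 6))
  b <- data.frame(sample = paste0("s", seq_len(44)),
                  batch = rep(c("A", "B"), 22),
                  group = c(rep("g1", 8), rep("g2", 8), rep("g3", 8),
                            rep("", 20)),
                  stringsAsFactors = FALSE)
  list(latent = lat, b = b)
}
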