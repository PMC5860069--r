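# Construct a large NN-labelled cluster with sample mean (1000, 1000) and
# per-channel sample sd exactly (100, 50), by standardising draws.
make_sd_cluster <- function(n = 200, seed = 4) {
  set.seed(seed)
  z1 <- as.numeric(scale(rnorm(n)))
  z2 <- as.numeric(scale(rnorm(n)))
  droplet_table(1000 + 100 * z1, 1000 + 50 * z2, "NN")
}

test_that("sd rain relabels droplets beyond n_sd per-channel deviations", {
  base <- make_sd_cluster()
  # a droplet ~6 sd out in Ch1 becomes Rain; ~4 sd is retained
  tab <- rbind(base, droplet_table(c(1600, 1400), c(1000, 1000), "NN"))
  out <- sd_rain(tab, n_sd = 5)
  lab <- as.character(out$label)
  expect_equal(lab[nrow(base) + 1L], "Rain")
  expect_equal(lab[nrow(base) + 2L], "NN")
  # limit case: a huge multiplier relabels nothing
  expect_true(all(as.character(sd_rain(tab, n_sd = 1e9)$label) == "NN"))
  # clusters of < 2 droplets are left untouched
  single <- droplet_table(c(1, 5000), c(1, 5000), c("NN", "PP"))
  expect_equal(as.character(sd_rain(single, 5)$label), c("NN", "PP"))
})

test_that("squared Mahalanobis distance matches hand and stats:: oracles", {
  st_id <- make_stats(c(0, 0), diag(2))
  expect_equal(mahalanobis_sq(c(3, 4), st_id), 25)      # identity = Euclidean^2
  expect_equal(mahalanobis_sq(c(0, 0), st_id), 0)
  st_diag <- make_stats(c(0, 0), diag(c(4, 1)))
  expect_equal(mahalanobis_sq(c(2, 1), st_diag), 2)     # 4/4 + 1/1

  set.seed(8)
  for (i in 1:10) {
    A <- matrix(runif(4, -1, 1), 2)
    Sigma <- crossprod(A) + diag(2) * 0.5
    mu <- runif(2, -5, 5)
    x <- runif(2, -5, 5)
    expect_equal(mahalanobis_sq(x, make_stats(mu, Sigma)),
                 unname(stats::mahalanobis(rbind(x), mu, Sigma)),
                 tolerance = 1e-10)
  }
  # near-singular covariance is refused, naming the cluster
  expect_error(mahalanobis_sq(c(1, 1), make_stats(c(0, 0),
               matrix(c(1, 1, 1, 1 + 1e-14), 2), label = "NP")), "NP")
})

test_that("identity-covariance Mahalanobis gating equals a Euclidean ball", {
  mu <- c(5000, 4000)
  tab <- make_whitened_cluster(400, mu, scale = 3, label = "PP", seed = 21)
  out <- mahalanobis_rain(tab, max_distance = 6)
  # centre the oracle on the sample mean, as the ellipse is
  d <- sqrt((tab$ch1_amplitude - mean(tab$ch1_amplitude))^2 +
            (tab$ch2_amplitude - mean(tab$ch2_amplitude))^2)
  expect_identical(as.character(out$label) == "Rain", d > sqrt(6))
  expect_gt(sum(d > sqrt(6)), 0)  # the case actually exercises removal
})

test_that("Mahalanobis rain matches a brute-force loop on rotated clusters", {
  set.seed(31)
  for (case in 1:8) {
    shear <- runif(1, 0.2, 1)
    covs <- default_cluster_covariances(sd = 400, shear = shear)
    means <- default_cluster_means()
    parts <- lapply(c("NN", "NP", "PN", "PP"), function(cl) {
      Z <- matrix(rnorm(2 * 80), ncol = 2)
      A <- sweep(Z %*% chol(covs[[cl]]), 2, means[[cl]], "+")
      droplet_table(A[, 1], A[, 2], cl)
    })
    tab <- do.call(rbind, parts)
    m_c <- sample(c(4, 6, 9), 1)
    got <- mahalanobis_rain(tab, max_distance = m_c)
    expect_identical(as.character(got$label),
                     oracle_mahalanobis_rain(tab, m_c))
  }
})

test_that("per-class radii are honoured and labels only move towards Rain", {
  blobs <- make_blobs(n_per = 100, sd = 300, seed = 41)
  tab <- blobs$table
  tab$label <- factor(blobs$truth, levels = droplet_classes())
  out <- mahalanobis_rain(tab, max_distance = list(PP = 1e6, default = 4))
  lab <- as.character(out$label)
  expect_true(all(lab[blobs$truth == "PP"] == "PP"))  # huge radius: untouched
  expect_gt(sum(lab == "Rain"), 0)
  # direction property: Rain only ever gains members, classes only lose
  changed <- lab != blobs$truth
  expect_true(all(lab[changed] == "Rain"))
  expect_error(mahalanobis_rain(tab, max_distance = -1), "positive")
})

test_that("rain sets shrink monotonically as the radius grows", {
  blobs <- make_blobs(n_per = 80, sd = 500, seed = 51)
  tab <- blobs$table
  tab$label <- factor(blobs$truth, levels = droplet_classes())
  rain_at <- function(m) which(as.character(mahalanobis_rain(tab, m)$label) == "Rain")
  r4 <- rain_at(4); r9 <- rain_at(9); r30 <- rain_at(30)
  expect_true(all(r9 %in% r4))
  expect_true(all(r30 %in% r9))
  # limit: enormous radius relabels nothing
  expect_length(rain_at(1e12), 0)

  sd_at <- function(n) which(as.character(sd_rain(tab, n)$label) == "Rain")
  s2 <- sd_at(2); s3 <- sd_at(3); s5 <- sd_at(5)
  expect_true(all(s3 %in% s2))
  expect_true(all(s5 %in% s3))
})

test_that("Mahalanobis distances are invariant under affine maps", {
  set.seed(61)
  blobs <- make_blobs(n_per = 40, sd = 300, seed = 61)
  tab <- blobs$table
  tab$label <- factor(blobs$truth, levels = droplet_classes())
  st <- cluster_stats(tab)
  for (i in 1:6) {
    repeat {
      A <- matrix(runif(4, -2, 2), 2)
      if (abs(det(A)) > 0.1) break
    }
    b <- runif(2, -1000, 1000)
    X <- cbind(tab$ch1_amplitude, tab$ch2_amplitude) %*% t(A)
    t2 <- droplet_table(X[, 1] + b[1], X[, 2] + b[2], tab$label)
    st2 <- cluster_stats(t2)
    for (cl in names(st)) {
      p <- c(tab$ch1_amplitude[1], tab$ch2_amplitude[1])
      p2 <- as.numeric(A %*% p + b)
      expect_equal(mahalanobis_sq(p2, st2[[cl]]),
                   mahalanobis_sq(p, st[[cl]]), tolerance = 1e-6)
    }
  }
})

test_that("Mahalanobis rain refuses classes too small for a covariance", {
  tab <- droplet_table(c(1, 2, 1000, 1001, 1002), c(1, 2, 1000, 1001, 1002),
                       c("NN", "NN", "PP", "PP", "PP"))
  expect_error(mahalanobis_rain(tab, 30), "class NN")
})
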