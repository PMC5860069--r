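test_that("threshold gating composes labels with >= at the boundary", {
  th <- c(ch1 = 6789, ch2 = 3000)
  tab <- droplet_table(c(7000, 7000, 2000, 2000, 6789),
                       c(3500, 2000, 3500, 2000, 3000))
  out <- threshold_classify(tab, th)
  expect_equal(as.character(out$label), c("PP", "PN", "NP", "NN", "PP"))
  expect_equal(out$ch1_amplitude, tab$ch1_amplitude)  # partition property
})

test_that("threshold gating is monotone in the thresholds", {
  set.seed(3)
  tab <- droplet_table(runif(300, 0, 10000), runif(300, 0, 10000))
  pos1_at <- function(t) {
    lab <- threshold_classify(tab, c(ch1 = t, ch2 = 3000))$label
    as.character(lab) %in% c("PN", "PP")
  }
  lo <- pos1_at(4000)
  hi <- pos1_at(6000)
  expect_true(all(lo | !hi))  # raising ch1 never converts negative -> positive
})

test_that("centre naming follows geometry and ignores input order", {
  m <- rbind(c(1000, 1000), c(1000, 8000), c(9000, 1000), c(9000, 8000))
  expect_equal(assign_centres_to_classes(m), c("NN", "NP", "PN", "PP"))
  set.seed(5)
  for (i in 1:10) {
    perm <- sample(4)
    lab <- assign_centres_to_classes(m[perm, ])
    expect_equal(lab[order(perm)], c("NN", "NP", "PN", "PP"))
  }
  expect_error(assign_centres_to_classes(m[c(1, 1, 3, 4), ]), "distinct")
})

test_that("k-means is a fixed point on well-separated blobs seeded at truth", {
  blobs <- make_blobs(n_per = 60, seed = 11)
  means <- do.call(rbind, default_cluster_means())
  fit <- kmeans_classify(blobs$table, centres = means)
  expect_equal(as.character(fit$table$label), blobs$truth)
  expect_lt(max(abs(fit$centres - means)), 50)  # centres near the truth
  expect_equal(nrow(fit$table), nrow(blobs$table))
})

test_that("k-means matches the brute-force Lloyd oracle exactly", {
  set.seed(20)
  for (case in 1:20) {
    n <- sample(50:500, 1)
    blobs <- make_blobs(n_per = ceiling(n / 4), sd = runif(1, 100, 600),
                        seed = 100 + case)
    tab <- blobs$table[seq_len(n), ]
    centres <- default_centres(tab)
    fit <- try(kmeans_classify(tab, centres = centres), silent = TRUE)
    orc <- try(oracle_lloyd(cbind(tab$ch1_amplitude, tab$ch2_amplitude),
                            centres), silent = TRUE)
    if (inherits(fit, "try-error") || inherits(orc, "try-error")) {
      # both must agree that a cluster emptied
      expect_true(inherits(fit, "try-error") && inherits(orc, "try-error"))
      next
    }
    map <- assign_centres_to_classes(orc$centres)
    expect_identical(as.character(fit$table$label), unname(map[orc$assign]))
  }
})

test_that("k-means WCSS is non-increasing and degenerate input is refused", {
  blobs <- make_blobs(n_per = 40, seed = 9)
  fit <- kmeans_classify(blobs$table)
  expect_true(all(diff(fit$wcss) <= 1e-8))
  expect_error(kmeans_classify(droplet_table(1:3, 1:3)), "at least 4")
  same <- droplet_table(rep(5, 10), rep(5, 10))
  expect_error(kmeans_classify(same), "distinct")
})

test_that("k-means errors name the seed of an emptied cluster", {
  set.seed(2)
  tab <- droplet_table(rnorm(50, 1000, 10), rnorm(50, 1000, 10))
  centres <- rbind(c(1000, 1000), c(1001, 1000), c(50000, 50000),
                   c(1000, 1001))
  expect_error(kmeans_classify(tab, centres = centres), "50000")
})

test_that("k-NN follows the vote rule and matches the exhaustive oracle", {
  train <- droplet_table(c(0, 10), c(0, 10), c("NN", "PP"))
  # coincident query, k = 1
  q <- knn_classify(droplet_table(0, 0), train, k = 1)
  expect_equal(as.character(q$label), "NN")
  # k = 2, split vote 1-1 below min_vote_fraction
  q2 <- knn_classify(droplet_table(5, 5), train, k = 2,
                     min_vote_fraction = 0.6)
  expect_equal(as.character(q2$label), "Unclassified")
  expect_error(knn_classify(droplet_table(1, 1), train, k = 3), "k must be")
  expect_error(knn_classify(droplet_table(1, 1),
                            droplet_table(1, 1, "Rain"), k = 1),
               "training labels")

  set.seed(77)
  for (case in 1:20) {
    nq <- sample(20:400, 1)
    k <- sample(1:7, 1)
    blobs <- make_blobs(n_per = 30, sd = 400, seed = 200 + case)
    tr <- blobs$table
    tr$label <- factor(blobs$truth, levels = droplet_classes())
    query <- make_blobs(n_per = ceiling(nq / 4), sd = 700,
                        seed = 300 + case)$table[seq_len(nq), ]
    got <- knn_classify(query, tr, k = k, min_vote_fraction = 0.51)
    want <- oracle_knn(cbind(query$ch1_amplitude, query$ch2_amplitude),
                       cbind(tr$ch1_amplitude, tr$ch2_amplitude),
                       as.character(tr$label), k, 0.51)
    expect_identical(as.character(got$label), want)
  }
})

test_that("cluster statistics are sample moments with n-1 denominator", {
  tab <- droplet_table(c(0, 2), c(0, 2), "PP")
  st <- cluster_stats(tab)
  expect_named(st, "PP")
  expect_equal(unname(st$PP$mean), c(1, 1))
  expect_equal(unname(st$PP$covariance), matrix(2, 2, 2))
  expect_equal(st$PP$count, 2L)

  # singleton: zero covariance, flagged; empty classes omitted
  one <- cluster_stats(droplet_table(5, 7, "NP"))
  expect_true(one$NP$singleton)
  expect_equal(unname(one$NP$covariance), matrix(0, 2, 2))
  expect_false("NN" %in% names(one))

  # Rain and Unclassified are excluded
  mix <- droplet_table(c(1, 2, 3), c(1, 2, 3), c("PP", "Rain", "Unclassified"))
  expect_named(cluster_stats(mix), "PP")
})
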