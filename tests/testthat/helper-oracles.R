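# Independent brute-force oracles and fixture builders. These deliberately
# use plain loops and scalar arithmetic, sharing no code path with the
# package implementations they check.

# Plain-loop Lloyd k-means: assign each point to the nearest of 4 centres
# (squared Euclidean, ties to the lowest index), recompute centres as means,
# stop when the largest centre movement is below tol; final assignment
# against the final centres.
oracle_lloyd <- function(X, centres, max_iter = 100, tol = 1e-6) {
  C <- centres
  n <- nrow(X)
  assign <- integer(n)
  for (it in seq_len(max_iter)) {
    for (i in seq_len(n)) {
      best <- 1L
      bestd <- (X[i, 1] - C[1, 1])^2 + (X[i, 2] - C[1, 2])^2
      for (j in 2:4) {
        d <- (X[i, 1] - C[j, 1])^2 + (X[i, 2] - C[j, 2])^2
        if (d < bestd) { best <- j; bestd <- d }
      }
      assign[i] <- best
    }
    newC <- C
    for (j in 1:4) {
      members <- which(assign == j)
      if (!length(members)) stop("oracle: empty cluster")
      newC[j, ] <- c(mean(X[members, 1]), mean(X[members, 2]))
    }
    move <- 0
    for (j in 1:4) {
      move <- max(move, sqrt(sum((newC[j, ] - C[j, ])^2)))
    }
    C <- newC
    if (move < tol) break
  }
  for (i in seq_len(n)) {
    best <- 1L
    bestd <- (X[i, 1] - C[1, 1])^2 + (X[i, 2] - C[1, 2])^2
    for (j in 2:4) {
      d <- (X[i, 1] - C[j, 1])^2 + (X[i, 2] - C[j, 2])^2
      if (d < bestd) { best <- j; bestd <- d }
    }
    assign[i] <- best
  }
  list(assign = assign, centres = C)
}

# Exhaustive k-NN with distance ties broken by training-row order and the
# vote-fraction rule applied per query.
oracle_knn <- function(Xq, Xt, labels, k, min_vote_fraction) {
  out <- character(nrow(Xq))
  classes <- c("NN", "NP", "PN", "PP")
  for (i in seq_len(nrow(Xq))) {
    d <- numeric(nrow(Xt))
    for (j in seq_len(nrow(Xt))) {
      d[j] <- (Xq[i, 1] - Xt[j, 1])^2 + (Xq[i, 2] - Xt[j, 2])^2
    }
    nb <- order(d)[seq_len(k)]
    votes <- vapply(classes, function(cl) sum(labels[nb] == cl), numeric(1))
    win <- which.max(votes)
    out[i] <- if (votes[win] / k >= min_vote_fraction) classes[win]
              else "Unclassified"
  }
  out
}

# Per-droplet squared Mahalanobis against explicitly computed class moments.
oracle_mahalanobis_rain <- function(table, max_distance) {
  lab <- as.character(table$label)
  for (cl in intersect(c("NN", "NP", "PN", "PP"), unique(lab))) {
    idx <- which(lab == cl)
    X <- cbind(table$ch1_amplitude[idx], table$ch2_amplitude[idx])
    mu <- c(mean(X[, 1]), mean(X[, 2]))
    Sinv <- solve(stats::cov(X))
    for (i in idx) {
      d <- c(table$ch1_amplitude[i], table$ch2_amplitude[i]) - mu
      if (drop(t(d) %*% Sinv %*% d) > max_distance) lab[i] <- "Rain"
    }
  }
  lab
}

# Four well-separated Gaussian blobs with known membership.
make_blobs <- function(n_per = 50, means = default_cluster_means(),
                       sd = 150, seed = 1) {
  set.seed(seed)
  classes <- rep(c("NN", "NP", "PN", "PP"), each = n_per)
  ch1 <- ch2 <- numeric(length(classes))
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    ch1[idx] <- rnorm(n_per, means[[cl]][1], sd)
    ch2[idx] <- rnorm(n_per, means[[cl]][2], sd)
  }
  list(table = droplet_table(ch1, ch2, "Unclassified"), truth = classes)
}

# A labelled cluster whose sample covariance is exactly the identity
# (whitened), centred at mu, plus the label to give it.
make_whitened_cluster <- function(n, mu, scale = 3, label = "PP", seed = 1) {
  set.seed(seed)
  X0 <- matrix(rnorm(2 * n, sd = scale), ncol = 2)
  Xc <- scale(X0, center = TRUE, scale = FALSE)
  Xw <- Xc %*% solve(chol(stats::cov(Xc)))
  droplet_table(Xw[, 1] + mu[1], Xw[, 2] + mu[2], label)
}

# Build a cluster_stats object by hand (for mahalanobis_sq unit checks).
make_stats <- function(mean, covariance, label = "PP", count = 10) {
  structure(list(label = label,
                 mean = c(ch1 = mean[1], ch2 = mean[2]),
                 covariance = covariance, count = count, singleton = FALSE),
            class = "cluster_stats")
}
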