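# Droplet gating: linear thresholds, four-centre k-means, k-nearest
# neighbours, and per-class summary statistics.

#' Classify droplets by linear channel thresholds
#'
#' A droplet is Channel-1-positive iff `ch1_amplitude >= thresholds["ch1"]`
#' and Channel-2-positive iff `ch2_amplitude >= thresholds["ch2"]`; the label
#' is composed from the two statuses (so a droplet exactly on a threshold
#' counts as positive). No droplet is labelled `Rain` by this operation.
#'
#' The default thresholds (6789 for Channel 1, 3000 for Channel 2) suit
#' amplitude scales where negative clusters sit near (2000, 1500); they are
#' assay-specific and should normally be set by eye from an amplitude plot.
#'
#' @param table A [droplet_table()].
#' @param thresholds Numeric vector or list with elements `ch1` and `ch2`.
#' @return The table with labels replaced; amplitudes untouched.
#' @export
#' @examples
#' tab <- droplet_table(c(7000, 7000, 2000), c(3500, 2000, 1500))
#' threshold_classify(tab)$label
threshold_classify <- function(table, thresholds = c(ch1 = 6789, ch2 = 3000)) {
  table <- .assert_droplet_table(table)
  th <- unlist(thresholds)
  if (!all(c("ch1", "ch2") %in% names(th))) {
    th <- stats::setNames(th[1:2], c("ch1", "ch2"))
  }
  if (!all(is.finite(th[c("ch1", "ch2")]))) {
    stop("thresholds must be finite", call. = FALSE)
  }
  pos1 <- table$ch1_amplitude >= th[["ch1"]]
  pos2 <- table$ch2_amplitude >= th[["ch2"]]
  table$label <- .class_label(if (nrow(table)) .compose_label(pos1, pos2)
                              else character())
  table
}

#' Name four cluster centres by their geometry
#'
#' Given four candidate cluster centres in (Ch1, Ch2) amplitude space, assigns
#' each the class it must represent: `NN` is the centre with the smallest sum
#' of per-channel ranks, `PP` the largest; of the remaining two, the one with
#' the larger Channel 1 coordinate is `PN` and the other `NP` (falling back to
#' the Channel 2 coordinate when Channel 1 ties). The assignment depends only
#' on the geometry, not on the order in which centres are given.
#'
#' @param centres A 4 x 2 numeric matrix (columns Ch1, Ch2) of distinct
#'   centres.
#' @return Character vector of length 4 mapping centre index to class label.
#' @export
#' @examples
#' m <- rbind(c(1000, 1000), c(1000, 8000), c(9000, 1000), c(9000, 8000))
#' assign_centres_to_classes(m)
assign_centres_to_classes <- function(centres) {
  centres <- as.matrix(centres)
  if (!all(dim(centres) == c(4L, 2L)) || !all(is.finite(centres))) {
    stop("centres must be a finite 4 x 2 matrix", call. = FALSE)
  }
  if (anyDuplicated(asplit(centres, 1L))) {
    stop("cluster centres must be distinct; assign classes manually",
         call. = FALSE)
  }
  rs <- rank(centres[, 1L], ties.method = "average") +
        rank(centres[, 2L], ties.method = "average")
  if (sum(rs == min(rs)) > 1L || sum(rs == max(rs)) > 1L) {
    stop("ambiguous cluster geometry; assign classes manually", call. = FALSE)
  }
  nn <- which.min(rs)
  pp <- which.max(rs)
  rest <- setdiff(seq_len(4L), c(nn, pp))
  a <- rest[1L]; b <- rest[2L]
  if (centres[a, 1L] != centres[b, 1L]) {
    pn <- if (centres[a, 1L] > centres[b, 1L]) a else b
  } else if (centres[a, 2L] != centres[b, 2L]) {
    pn <- if (centres[a, 2L] > centres[b, 2L]) b else a
  } else {
    stop("ambiguous cluster geometry; assign classes manually", call. = FALSE)
  }
  np <- setdiff(rest, pn)
  out <- character(4L)
  out[c(nn, np, pn, pp)] <- c("NN", "NP", "PN", "PP")
  out
}

#' Default k-means starting centres
#'
#' Deterministic seeding for four-cluster gating: the four corner points
#' formed from the per-channel 10th and 90th amplitude percentiles. No random
#' number generation is involved, so repeated runs are identical.
#'
#' @param table A [droplet_table()].
#' @param probs Two probabilities for the per-channel quantiles.
#' @return A 4 x 2 matrix of starting centres.
#' @export
default_centres <- function(table, probs = c(0.1, 0.9)) {
  table <- .assert_droplet_table(table)
  q1 <- stats::quantile(table$ch1_amplitude, probs, names = FALSE)
  q2 <- stats::quantile(table$ch2_amplitude, probs, names = FALSE)
  rbind(c(q1[1L], q2[1L]), c(q1[1L], q2[2L]),
        c(q1[2L], q2[1L]), c(q1[2L], q2[2L]))
}

# Squared Euclidean distances from each row of X to each row of C,
# accumulated per coordinate so results match a naive per-pair loop exactly.
.dist2_to_centres <- function(X, C) {
  out <- vapply(seq_len(nrow(C)), function(j) {
    (X[, 1L] - C[j, 1L])^2 + (X[, 2L] - C[j, 2L])^2
  }, numeric(nrow(X)))
  matrix(out, nrow = nrow(X))  # vapply drops to a vector when nrow(X) == 1
}

#' Gate droplets by four-centre k-means
#'
#' Standard Lloyd iteration on the two-channel amplitudes: each droplet is
#' assigned to its nearest centre by Euclidean distance (ties broken by the
#' lowest centre index), centres are recomputed as cluster means, and the
#' loop stops when the largest centre movement falls below `tol` or after
#' `max_iter` iterations. Final clusters are named by their geometry via
#' [assign_centres_to_classes()]. Distances are computed on raw amplitudes by
#' default; set `standardize = TRUE` to divide each channel by its standard
#' deviation first (centres are interpreted and returned in raw units either
#' way).
#'
#' @param table A [droplet_table()] with at least 4 droplets.
#' @param centres Optional 4 x 2 matrix of distinct starting centres, in raw
#'   amplitude units; defaults to [default_centres()].
#' @param max_iter Maximum number of Lloyd iterations.
#' @param tol Convergence tolerance on centre movement, in amplitude units.
#' @param standardize Divide each channel by its standard deviation before
#'   computing distances.
#' @return A list with components `table` (the relabelled droplet table),
#'   `stats` (per-class [cluster_stats()]), `centres` (final centres, raw
#'   units, rows named by class), `iterations`, and `wcss` (total
#'   within-cluster sum of squares after each assignment step).
#' @export
kmeans_classify <- function(table, centres = NULL, max_iter = 100L,
                            tol = 1e-6, standardize = FALSE) {
  table <- .assert_droplet_table(table)
  if (nrow(table) < 4L) {
    stop("k-means gating needs at least 4 droplets", call. = FALSE)
  }
  X <- .amplitude_matrix(table)
  scale_by <- c(1, 1)
  if (standardize) {
    scale_by <- c(stats::sd(X[, 1L]), stats::sd(X[, 2L]))
    if (any(scale_by == 0)) {
      stop("cannot standardize: a channel has zero variance", call. = FALSE)
    }
    X <- sweep(X, 2L, scale_by, "/")
  }
  if (is.null(centres)) centres <- default_centres(table)
  centres <- as.matrix(centres)
  if (!all(dim(centres) == c(4L, 2L)) || !all(is.finite(centres))) {
    stop("centres must be a finite 4 x 2 matrix", call. = FALSE)
  }
  if (anyDuplicated(asplit(centres, 1L))) {
    stop("starting centres must be distinct (degenerate well?)",
         call. = FALSE)
  }
  C0 <- sweep(centres, 2L, scale_by, "/")

  C <- C0
  wcss <- numeric()
  assign <- integer(nrow(X))
  for (it in seq_len(max_iter)) {
    d2 <- .dist2_to_centres(X, C)
    assign <- max.col(-d2, ties.method = "first")
    wcss <- c(wcss, sum(d2[cbind(seq_len(nrow(X)), assign)]))
    newC <- C
    for (j in seq_len(4L)) {
      members <- assign == j
      if (!any(members)) {
        stop(sprintf(
          "k-means cluster seeded at (%g, %g) became empty; choose different starting centres",
          centres[j, 1L], centres[j, 2L]), call. = FALSE)
      }
      newC[j, ] <- colMeans(X[members, , drop = FALSE])
    }
    move <- max(sqrt(rowSums((newC - C)^2)))
    C <- newC
    if (move < tol) break
  }
  # label against the final centres
  d2 <- .dist2_to_centres(X, C)
  assign <- max.col(-d2, ties.method = "first")
  for (j in seq_len(4L)) {
    if (!any(assign == j)) {
      stop(sprintf(
        "k-means cluster seeded at (%g, %g) became empty; choose different starting centres",
        centres[j, 1L], centres[j, 2L]), call. = FALSE)
    }
  }
  C_raw <- sweep(C, 2L, scale_by, "*")
  map <- assign_centres_to_classes(C_raw)
  table$label <- .class_label(map[assign])
  rownames(C_raw) <- map
  colnames(C_raw) <- c("ch1", "ch2")
  list(table = table, stats = cluster_stats(table),
       centres = C_raw, iterations = it, wcss = wcss)
}

#' Gate droplets by k-nearest neighbours
#'
#' Each query droplet takes the majority label among its `k` nearest training
#' droplets (Euclidean distance on raw amplitudes). Distance ties are broken
#' by training-row order, so the result is deterministic. If the winning vote
#' fraction is below `min_vote_fraction` the droplet is left `Unclassified`;
#' because `min_vote_fraction > 0.5`, split votes never assign a class.
#'
#' @param table Query [droplet_table()].
#' @param train Training [droplet_table()]; every label must be one of
#'   `NN`, `NP`, `PN`, `PP`.
#' @param k Number of neighbours; at most `nrow(train)`.
#' @param min_vote_fraction Minimum winning vote fraction, in (0.5, 1].
#' @return The query table with labels replaced.
#' @export
knn_classify <- function(table, train, k = 1L, min_vote_fraction = 0.51) {
  table <- .assert_droplet_table(table)
  train <- .assert_droplet_table(train)
  if (nrow(train) == 0L) stop("training table is empty", call. = FALSE)
  if (k < 1L || k > nrow(train)) {
    stop("k must be between 1 and the number of training droplets",
         call. = FALSE)
  }
  if (min_vote_fraction <= 0.5 || min_vote_fraction > 1) {
    stop("min_vote_fraction must be in (0.5, 1]", call. = FALSE)
  }
  tl <- as.character(train$label)
  if (!all(tl %in% .CORE_CLASSES)) {
    stop("training labels must all be NN, NP, PN or PP", call. = FALSE)
  }
  if (nrow(table) == 0L) return(table)
  Xq <- .amplitude_matrix(table)
  Xt <- .amplitude_matrix(train)
  d2 <- .dist2_to_centres(Xq, Xt)  # n_query x n_train
  out <- character(nrow(Xq))
  for (i in seq_len(nrow(Xq))) {
    nb <- order(d2[i, ])[seq_len(k)]  # stable: distance ties keep row order
    votes <- table(factor(tl[nb], levels = .CORE_CLASSES))
    win <- which.max(votes)
    out[i] <- if (votes[win] / k >= min_vote_fraction) {
      .CORE_CLASSES[win]
    } else "Unclassified"
  }
  table$label <- .class_label(out)
  table
}

#' Per-class droplet summary statistics
#'
#' For every quantifiable class (`NN`, `NP`, `PN`, `PP`) with at least one
#' droplet, computes the sample mean vector and the sample covariance matrix
#' (denominator n - 1) of the two-channel amplitudes. `Rain` and
#' `Unclassified` droplets are excluded. A class with a single droplet gets a
#' zero covariance matrix and is flagged `singleton`; empty classes are
#' omitted.
#'
#' @param table A labelled [droplet_table()].
#' @return Named list of `cluster_stats` objects, each with elements `label`,
#'   `mean` (length-2, named `ch1`, `ch2`), `covariance` (2 x 2), `count` and
#'   `singleton`.
#' @export
cluster_stats <- function(table) {
  table <- .assert_droplet_table(table)
  lab <- as.character(table$label)
  out <- list()
  for (cl in .CORE_CLASSES) {
    idx <- which(lab == cl)
    if (!length(idx)) next
    X <- .amplitude_matrix(table)[idx, , drop = FALSE]
    mu <- colMeans(X)
    Sigma <- if (length(idx) >= 2L) stats::cov(X) else matrix(0, 2L, 2L)
    dimnames(Sigma) <- list(c("ch1", "ch2"), c("ch1", "ch2"))
    out[[cl]] <- structure(
      list(label = cl, mean = c(ch1 = mu[[1L]], ch2 = mu[[2L]]),
           covariance = Sigma, count = length(idx),
           singleton = length(idx) < 2L),
      class = "cluster_stats")
  }
  out
}

#' @export
print.cluster_stats <- function(x, ...) {
  cat(sprintf("cluster %s: n = %d, mean = (%.1f, %.1f)%s\n",
              x$label, x$count, x$mean[["ch1"]], x$mean[["ch2"]],
              if (x$singleton) " [singleton: zero covariance]" else ""))
  invisible(x)
}
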