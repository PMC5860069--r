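# Rain refinement: demote ambiguous droplets from the four classes to Rain,
# either by per-channel standard-deviation bounds or by squared-Mahalanobis
# ellipses that account for cluster rotation. Both operations compute cluster
# statistics once from the incoming labels and then test every droplet; they
# only ever change labels from {NN, NP, PN, PP} to Rain.

#' Rain removal by per-cluster standard deviation
#'
#' For each of the four classes, per-channel sample mean and standard
#' deviation are computed from the droplets currently carrying that label. A
#' droplet is relabelled `Rain` iff it lies further than `n_sd` standard
#' deviations from its cluster mean in either channel. The bounds are
#' axis-aligned: unlike [mahalanobis_rain()], this method does not account
#' for cluster rotation ("lean"/"lift"). Clusters with fewer than two
#' droplets have no defined standard deviation and are left untouched.
#'
#' @param table A labelled [droplet_table()].
#' @param n_sd Positive standard-deviation multiplier; default 5.
#' @return The table with ambiguous droplets relabelled `Rain`.
#' @export
sd_rain <- function(table, n_sd = 5) {
  table <- .assert_droplet_table(table)
  if (!is.finite(n_sd) || n_sd <= 0) stop("n_sd must be > 0", call. = FALSE)
  lab <- as.character(table$label)
  for (cl in .CORE_CLASSES) {
    idx <- which(lab == cl)
    if (length(idx) < 2L) next
    x1 <- table$ch1_amplitude[idx]
    x2 <- table$ch2_amplitude[idx]
    out <- abs(x1 - mean(x1)) > n_sd * stats::sd(x1) |
           abs(x2 - mean(x2)) > n_sd * stats::sd(x2)
    lab[idx[out]] <- "Rain"
  }
  table$label <- .class_label(lab)
  table
}

# Invert a 2x2 covariance with a relative condition-number guard.
.solve_cov <- function(Sigma, label, kappa_max = 1e10) {
  if (!all(is.finite(Sigma)) ||
      !is.finite(kappa(Sigma, exact = TRUE)) ||
      kappa(Sigma, exact = TRUE) > kappa_max) {
    stop(sprintf(
      "covariance matrix for class %s is singular or near-singular; consider threshold gating instead",
      label), call. = FALSE)
  }
  solve(Sigma)
}

#' Squared Mahalanobis distance to a cluster
#'
#' Distance of an amplitude point from a fitted cluster in units of the
#' cluster's own spread: `(x - mu)' Sigma^-1 (x - mu)`, with `mu` and `Sigma`
#' the cluster's sample mean and covariance. Under identity covariance this
#' equals the squared Euclidean distance; in general the iso-distance
#' contours are ellipses aligned with the cluster, so rotated ("leaning")
#' clusters are measured along their own axes.
#'
#' @param point Length-2 numeric vector (Ch1, Ch2 amplitude).
#' @param stats A `cluster_stats` object (see [cluster_stats()]) with an
#'   invertible covariance.
#' @return Non-negative scalar.
#' @export
#' @examples
#' st <- cluster_stats(droplet_table(c(0, 2, 1), c(0, 2, -1), "PP"))$PP
#' mahalanobis_sq(st$mean, st)  # 0 at the cluster mean
mahalanobis_sq <- function(point, stats) {
  point <- as.numeric(point)
  stopifnot(length(point) == 2L, inherits(stats, "cluster_stats"))
  Sinv <- .solve_cov(stats$covariance, stats$label)
  d <- point - as.numeric(stats$mean)
  drop(t(d) %*% Sinv %*% d)
}

# Normalise the max_distance argument to one radius per core class.
.rain_radii <- function(max_distance) {
  md <- unlist(max_distance)
  if (is.null(names(md)) && length(md) == 1L) {
    md <- c(default = md)
  }
  default <- if ("default" %in% names(md)) md[["default"]] else NA_real_
  radii <- stats::setNames(rep(default, 4L), .CORE_CLASSES)
  for (cl in .CORE_CLASSES) {
    if (cl %in% names(md)) radii[[cl]] <- md[[cl]]
  }
  radii
}

#' Rain removal by Mahalanobis ellipses
#'
#' For each class `c` present in the table, the sample mean and covariance
#' are computed from its droplets, and droplets whose squared Mahalanobis
#' distance exceeds the class radius `m_c` are relabelled `Rain`; droplets
#' with distance at most `m_c` stay in the class. The radius bounds the
#' squared distance: for a well-behaved cluster the squared distance is
#' roughly chi-squared with 2 degrees of freedom, so the default `m_c = 30`
#' keeps essentially all genuine members while trimming intermediate
#' droplets. Radii generally need manual adjustment per assay so that the
#' ellipses are large enough to keep real class members but small enough to
#' exclude ambiguous droplets.
#'
#' @param table A labelled [droplet_table()]; every class present must have
#'   at least 3 droplets (the sample covariance must be invertible).
#' @param max_distance Either a single positive number used for all classes,
#'   or a named vector/list with entries among `NN`, `NP`, `PN`, `PP` and
#'   optionally `default` for the remaining classes.
#' @return The table with out-of-ellipse droplets relabelled `Rain`.
#' @export
mahalanobis_rain <- function(table, max_distance = 30) {
  table <- .assert_droplet_table(table)
  radii <- .rain_radii(max_distance)
  lab <- as.character(table$label)
  st <- cluster_stats(table)
  for (cl in names(st)) {
    m_c <- radii[[cl]]
    if (!is.finite(m_c) || m_c <= 0) {
      stop(sprintf("no positive max_distance for class %s", cl),
           call. = FALSE)
    }
    if (st[[cl]]$count < 3L) {
      stop(sprintf(
        "class %s has only %d droplet(s); at least 3 are needed for a Mahalanobis ellipse",
        cl, st[[cl]]$count), call. = FALSE)
    }
    Sinv <- .solve_cov(st[[cl]]$covariance, cl)
    idx <- which(lab == cl)
    D <- sweep(.amplitude_matrix(table)[idx, , drop = FALSE],
               2L, as.numeric(st[[cl]]$mean))
    d2 <- rowSums((D %*% Sinv) * D)
    lab[idx[d2 > m_c]] <- "Rain"
  }
  table$label <- .class_label(lab)
  table
}
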