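# Synthetic ddPCR wells with known ground truth: Poisson class occupancy,
# bivariate-Gaussian fluorescence clusters (optionally sheared to emulate the
# "lean"/"lift" of the single-positive clusters), and injected rain placed
# between cluster centres. The generator mirrors the statistical model the
# analysis assumes; it does not model PCR chemistry.

#' Default cluster mean fluorescence positions
#'
#' Amplitude-space centres for the four classes, on a scale resembling real
#' two-channel amplitude plots: negatives near (2000, 1500) and fully
#' positive droplets near (9500, 8000). Override to emulate other assays.
#'
#' @return Named list of length-2 numeric vectors (Ch1, Ch2) for
#'   `NN`, `NP`, `PN`, `PP`.
#' @export
default_cluster_means <- function() {
  list(NN = c(2000, 1500), NP = c(2500, 7500),
       PN = c(9000, 1800), PP = c(9500, 8000))
}

#' Default cluster covariance matrices
#'
#' Axis-aligned spread of `sd` fluorescence units per channel, optionally
#' sheared for the single-positive clusters: with `shear = s > 0` the PN
#' cluster "leans" (its Channel 2 amplitude rises with Channel 1) and the NP
#' cluster "lifts" (Channel 1 rises with Channel 2), as seen in real data
#' where probes cross-hybridise. The shear is a phenomenological tilt, not a
#' chemistry model.
#'
#' @param sd Per-channel standard deviation in fluorescence units.
#' @param shear Non-negative shear factor applied to PN and NP.
#' @return Named list of 2 x 2 positive-definite matrices.
#' @export
default_cluster_covariances <- function(sd = 300, shear = 0) {
  base <- diag(c(sd^2, sd^2))
  lean <- rbind(c(1, 0), c(shear, 1))   # PN: ch2 follows ch1
  lift <- rbind(c(1, shear), c(0, 1))   # NP: ch1 follows ch2
  list(NN = base,
       NP = lift %*% base %*% t(lift),
       PN = lean %*% base %*% t(lean),
       PP = base)
}

#' Simulation configuration
#'
#' Bundles the ground truth and geometry for one synthetic well: true target
#' concentrations per channel, droplet count and volume, per-class
#' fluorescence geometry, the fraction of droplets emitted as inter-cluster
#' rain, and the RNG seed.
#'
#' @param conc_ch1,conc_ch2 True target concentrations, copies per
#'   microlitre (Channel 1 is the mutant channel by convention).
#' @param n_droplets Number of droplets in the well; the platform partitions
#'   a sample into roughly 20 000.
#' @param droplet_volume_ul Droplet volume in microlitres (0.85 nl default).
#' @param cluster_means,cluster_covariances Per-class fluorescence geometry;
#'   see [default_cluster_means()] and [default_cluster_covariances()].
#' @param rain_fraction Expected share of droplets emitted as rain, in
#'   `[0, 1)`.
#' @param rain_jitter_sd Gaussian jitter (fluorescence units) orthogonal to
#'   the inter-cluster segment on which rain droplets are placed.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(conc_ch1, conc_ch2, n_droplets = 20000L,
                              droplet_volume_ul = 8.5e-4,
                              cluster_means = default_cluster_means(),
                              cluster_covariances = default_cluster_covariances(),
                              rain_fraction = 0, rain_jitter_sd = 100,
                              seed = NULL) {
  stopifnot(conc_ch1 >= 0, conc_ch2 >= 0, n_droplets > 0,
            droplet_volume_ul > 0, rain_fraction >= 0, rain_fraction < 1)
  for (cl in .CORE_CLASSES) {
    S <- cluster_covariances[[cl]]
    if (is.null(cluster_means[[cl]]) || is.null(S) ||
        any(eigen(S, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
      stop(sprintf("cluster %s needs a mean and a positive-definite covariance",
                   cl), call. = FALSE)
    }
  }
  structure(
    list(conc_ch1 = conc_ch1, conc_ch2 = conc_ch2,
         n_droplets = as.integer(n_droplets),
         droplet_volume_ul = droplet_volume_ul,
         cluster_means = cluster_means,
         cluster_covariances = cluster_covariances,
         rain_fraction = rain_fraction, rain_jitter_sd = rain_jitter_sd,
         seed = seed),
    class = "simulation_config")
}

#' Poisson class occupancy probabilities
#'
#' Molecules of each target are assumed Poisson distributed over droplets, so
#' a droplet is positive for a target of concentration `c` with probability
#' `1 - exp(-c * V)`, independently per channel. The four class probabilities
#' are the products of the per-channel occupancy probabilities and sum to 1.
#'
#' @param conc_ch1,conc_ch2 True concentrations, copies per microlitre.
#' @param V_ul Droplet volume in microlitres.
#' @return Named numeric vector `(NN, NP, PN, PP)` summing to 1.
#' @export
#' @examples
#' class_probabilities(log(2) / 8.5e-4, 0)  # pPN = pNN = 0.5
class_probabilities <- function(conc_ch1, conc_ch2, V_ul = 8.5e-4) {
  stopifnot(conc_ch1 >= 0, conc_ch2 >= 0, V_ul > 0)
  p1 <- 1 - exp(-conc_ch1 * V_ul)
  p2 <- 1 - exp(-conc_ch2 * V_ul)
  c(NN = (1 - p1) * (1 - p2), NP = (1 - p1) * p2,
    PN = p1 * (1 - p2), PP = p1 * p2)
}

# One multivariate normal draw block: n x 2, via the Cholesky factor.
.rmvnorm2 <- function(n, mean, Sigma) {
  Z <- matrix(stats::rnorm(2L * n), ncol = 2L)
  sweep(Z %*% chol(Sigma), 2L, as.numeric(mean), "+")
}

#' Simulate one ddPCR well
#'
#' Each droplet's true class is drawn from [class_probabilities()]; its
#' amplitudes are drawn from the class's bivariate Gaussian. Independently, a
#' `rain_fraction` share of droplets is instead emitted as rain: placed
#' uniformly on the interior of the segment between two randomly chosen
#' distinct class means (the central 40-70% stretch, at relative position
#' `u ~ U(0.3, 0.7)`), with Gaussian jitter orthogonal to the segment, and
#' truth-labelled `Rain`. Rain is kept off the cluster cores deliberately: a
#' droplet within a cluster's own spread is phenotypically a class member,
#' whereas rain is defined by intermediate fluorescence between clusters.
#' With a fixed `seed` the output is bit-identical across calls.
#'
#' @param config A [simulation_config()].
#' @return A [droplet_table()] whose `label` column carries the ground-truth
#'   class of every droplet.
#' @export
simulate_well <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_droplets
  p <- class_probabilities(config$conc_ch1, config$conc_ch2,
                           config$droplet_volume_ul)
  truth <- sample(.CORE_CLASSES, n, replace = TRUE, prob = p)
  if (config$rain_fraction > 0) {
    truth[stats::runif(n) < config$rain_fraction] <- "Rain"
  }
  ch1 <- numeric(n)
  ch2 <- numeric(n)
  for (cl in .CORE_CLASSES) {
    idx <- which(truth == cl)
    if (!length(idx)) next
    A <- .rmvnorm2(length(idx), config$cluster_means[[cl]],
                   config$cluster_covariances[[cl]])
    ch1[idx] <- A[, 1L]
    ch2[idx] <- A[, 2L]
  }
  ridx <- which(truth == "Rain")
  if (length(ridx)) {
    nr <- length(ridx)
    M <- do.call(rbind, config$cluster_means[.CORE_CLASSES])
    from <- sample.int(4L, nr, replace = TRUE)
    to <- (from - 1L + sample.int(3L, nr, replace = TRUE)) %% 4L + 1L
    u <- stats::runif(nr, 0.3, 0.7)  # interior of the segment only
    seg <- M[to, , drop = FALSE] - M[from, , drop = FALSE]
    len <- sqrt(rowSums(seg^2))
    perp <- cbind(-seg[, 2L], seg[, 1L]) / len
    jit <- stats::rnorm(nr, sd = config$rain_jitter_sd)
    pos <- M[from, , drop = FALSE] + seg * u + perp * jit
    ch1[ridx] <- pos[, 1L]
    ch2[ridx] <- pos[, 2L]
  }
  droplet_table(ch1, ch2, truth)
}

# Sequential well names: A01..A12, B01..B12, ...
.well_name_seq <- function(n) {
  i <- seq_len(n) - 1L
  if (n > 96L) stop("a plate has at most 96 wells", call. = FALSE)
  sprintf("%s%02d", LETTERS[i %/% 12L + 1L], i %% 12L + 1L)
}

#' Simulate a mutant-fraction dilution series
#'
#' Emulates a classic rare-mutant validation design: replicate wells at a
#' fixed mutant fraction of the total target, over increasing amounts of
#' input DNA. Per well, the Channel 1 (mutant) truth concentration is
#' `mutant_fraction * total` and Channel 2 (wild type) is
#' `(1 - mutant_fraction) * total`. The default series
#' `c(15, 60, 240, 960)` copies/microlitre corresponds to roughly 1, 4, 16
#' and 64 ng of human genomic DNA in a 20 microlitre reaction (about 303
#' haploid genome copies per ng). Wells are named sequentially (`A01`,
#' `A02`, ...) in series-major order and each well uses its own RNG stream
#' seeded `seed + well index`, so plates are reproducible and wells
#' independent.
#'
#' @param mutant_fraction True mutant fraction of the total, in (0, 1);
#'   default 0.05.
#' @param total_copies_series Total (mutant + wild type) concentrations,
#'   copies per microlitre, one per input level.
#' @param replicates Wells per input level; default 3.
#' @param seed Base integer seed.
#' @param n_droplets Droplets per well.
#' @param droplet_volume_ul Droplet volume in microlitres.
#' @param cluster_sd Per-channel cluster standard deviation.
#' @param shear Lean/lift shear for the single-positive clusters; default
#'   0.3.
#' @param rain_fraction Share of droplets emitted as rain; the default
#'   0.002 (about 40 droplets in a 20 000-droplet well) reflects a clean
#'   assay with a visible but minor rain fringe.
#' @return A [ddpcr_plate()] of `replicates * length(total_copies_series)`
#'   truth-labelled wells; `plate_metadata()` carries a `truth` data frame
#'   with each well's true concentrations.
#' @export
simulate_kras_series <- function(mutant_fraction = 0.05,
                                 total_copies_series = c(15, 60, 240, 960),
                                 replicates = 3L, seed = 1L,
                                 n_droplets = 20000L,
                                 droplet_volume_ul = 8.5e-4,
                                 cluster_sd = 300, shear = 0.3,
                                 rain_fraction = 0.002) {
  stopifnot(mutant_fraction > 0, mutant_fraction < 1, replicates >= 1,
            length(total_copies_series) >= 1)
  totals <- rep(total_copies_series, each = replicates)
  names(totals) <- .well_name_seq(length(totals))
  covs <- default_cluster_covariances(sd = cluster_sd, shear = shear)
  wells <- list()
  for (i in seq_along(totals)) {
    cfg <- simulation_config(
      conc_ch1 = mutant_fraction * totals[[i]],
      conc_ch2 = (1 - mutant_fraction) * totals[[i]],
      n_droplets = n_droplets, droplet_volume_ul = droplet_volume_ul,
      cluster_covariances = covs, rain_fraction = rain_fraction,
      seed = seed + i)
    wells[[names(totals)[i]]] <- simulate_well(cfg)
  }
  truth <- data.frame(Well = names(totals),
                      TotalCopiesPerUl = unname(totals),
                      ConcCh1 = mutant_fraction * unname(totals),
                      ConcCh2 = (1 - mutant_fraction) * unname(totals),
                      stringsAsFactors = FALSE)
  ddpcr_plate(wells, metadata = list(
    truth = truth, mutant_fraction = mutant_fraction, seed = seed,
    cluster_means = default_cluster_means(), cluster_covariances = covs))
}
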