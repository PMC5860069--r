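# droplet_gate(): the front-door model fit. Gates droplets into the four
# classes, optionally demotes ambiguous droplets to Rain, and estimates
# concentrations by Poisson occupancy. Accepts a single well or a whole
# plate; a plate is gated jointly (droplets pooled across wells) so that
# classes too rare to form a cluster in a low-input well are still anchored
# by the wells where they are abundant, then quantified per well.

#' Gate and quantify a ddPCR well or plate
#'
#' Fits the two-channel gating model: droplets are classified into
#' `NN`/`NP`/`PN`/`PP` by the chosen method, ambiguous droplets are
#' optionally relabelled `Rain`, and target concentrations (copies per
#' microlitre) plus fractional abundance are estimated from the gated counts
#' by Poisson occupancy. When `droplets` is a plate, classification and rain
#' refinement run on the pooled droplets of all wells and quantification is
#' reported per well.
#'
#' @param droplets A [droplet_table()] or a [ddpcr_plate()].
#' @param method Gating method: `"kmeans"` (four-centre Lloyd k-means,
#'   default), `"threshold"` (independent linear gates per channel) or
#'   `"knn"` (k-nearest neighbours against labelled training droplets).
#' @param thresholds For `method = "threshold"`: see [threshold_classify()].
#' @param centres For `method = "kmeans"`: optional 4 x 2 starting centres;
#'   defaults to the deterministic percentile corners of [default_centres()].
#' @param max_iter,tol,standardize For `method = "kmeans"`: see
#'   [kmeans_classify()].
#' @param train,k,min_vote_fraction For `method = "knn"`: see
#'   [knn_classify()].
#' @param rain Rain refinement applied after classification: `"none"`
#'   (default), `"sd"` ([sd_rain()]) or `"mahalanobis"`
#'   ([mahalanobis_rain()]).
#' @param n_sd Standard-deviation multiplier for `rain = "sd"`.
#' @param max_distance Squared-Mahalanobis radius (scalar or per-class) for
#'   `rain = "mahalanobis"`.
#' @param droplet_volume_ul Droplet volume in microlitres.
#' @param exclude_rain Exclude `Rain`/`Unclassified` droplets from the
#'   accepted total; see [quantify_well()].
#' @return An object of class `droplet_gate` with methods [print()],
#'   [summary()], [coef()] (concentrations and fractional abundance),
#'   [predict()] (gate new droplets with the fitted rule), [plot()]
#'   (amplitude scatter coloured by class), [simulate()] (draw synthetic
#'   wells at the fitted concentrations and cluster geometry) and
#'   [residuals()] (per-droplet squared Mahalanobis distance to the assigned
#'   cluster).
#' @export
#' @examples
#' cfg <- simulation_config(100, 900, n_droplets = 2000, seed = 7)
#' fit <- droplet_gate(simulate_well(cfg), rain = "mahalanobis")
#' fit
#' coef(fit)
droplet_gate <- function(droplets,
                         method = c("kmeans", "threshold", "knn"),
                         thresholds = c(ch1 = 6789, ch2 = 3000),
                         centres = NULL, max_iter = 100L, tol = 1e-6,
                         standardize = FALSE,
                         train = NULL, k = 1L, min_vote_fraction = 0.51,
                         rain = c("none", "sd", "mahalanobis"),
                         n_sd = 5, max_distance = 30,
                         droplet_volume_ul = 8.5e-4, exclude_rain = TRUE) {
  method <- match.arg(method)
  rain <- match.arg(rain)
  is_plate <- inherits(droplets, "ddpcr_plate")
  if (is_plate) {
    well_sizes <- vapply(droplets, nrow, integer(1))
    pooled <- do.call(rbind, lapply(unname(droplets), as.data.frame))
    pooled <- droplet_table(pooled$ch1_amplitude, pooled$ch2_amplitude,
                            pooled$label)
    well_of <- rep(names(droplets), well_sizes)
  } else {
    pooled <- .assert_droplet_table(droplets)
    well_of <- NULL
  }

  fit_centres <- NULL
  kfit <- NULL
  labelled <- switch(method,
    threshold = threshold_classify(pooled, thresholds),
    kmeans = {
      kfit <- kmeans_classify(pooled, centres = centres, max_iter = max_iter,
                              tol = tol, standardize = standardize)
      fit_centres <- kfit$centres
      kfit$table
    },
    knn = {
      if (is.null(train)) {
        stop("method = 'knn' needs labelled training droplets", call. = FALSE)
      }
      knn_classify(pooled, train, k = k,
                   min_vote_fraction = min_vote_fraction)
    })
  stats <- cluster_stats(labelled)
  refined <- switch(rain,
    none = labelled,
    sd = sd_rain(labelled, n_sd = n_sd),
    mahalanobis = mahalanobis_rain(labelled, max_distance = max_distance))

  if (is_plate) {
    wells <- split(seq_len(nrow(refined)),
                   factor(well_of, levels = names(droplets)))
    plate <- ddpcr_plate(lapply(wells, function(i) refined[i, , drop = FALSE]),
                         metadata = plate_metadata(droplets))
    summary_df <- summarize_plate(plate, V_ul = droplet_volume_ul,
                                  exclude_rain = exclude_rain)
  } else {
    plate <- NULL
    summary_df <- NULL
  }
  quant <- tryCatch(
    quantify_well(refined, V_ul = droplet_volume_ul,
                  exclude_rain = exclude_rain),
    error = function(e) e)

  structure(
    list(droplets = refined, well = well_of, plate = plate,
         method = method, rain_method = rain, stats = stats,
         centres = fit_centres, thresholds = if (method == "threshold")
           thresholds else NULL,
         train = if (method == "knn") train else NULL,
         k = k, min_vote_fraction = min_vote_fraction,
         n_sd = n_sd, max_distance = max_distance,
         droplet_volume_ul = droplet_volume_ul, exclude_rain = exclude_rain,
         quant = quant, summary = summary_df,
         iterations = if (!is.null(kfit)) kfit$iterations else NULL,
         call = match.call()),
    class = "droplet_gate")
}

#' @export
print.droplet_gate <- function(x, ...) {
  cat("Two-channel ddPCR gate\n")
  cat(sprintf("  method: %s%s; droplets: %d%s\n", x$method,
              if (x$rain_method != "none")
                paste0(" + ", x$rain_method, " rain") else "",
              nrow(x$droplets),
              if (!is.null(x$plate))
                sprintf(" in %d wells", length(x$plate)) else ""))
  counts <- class_counts(x$droplets)
  nz <- counts[counts > 0]
  cat("  classes:", paste(sprintf("%s=%d", names(nz), nz), collapse = ", "),
      "\n")
  if (!inherits(x$quant, "error")) {
    cat(sprintf("  pooled concentration: Ch1 %.4g, Ch2 %.4g copies/ul; fractional abundance %s\n",
                x$quant$conc_ch1, x$quant$conc_ch2,
                if (is.na(x$quant$fractional_abundance)) "undefined"
                else sprintf("%.4g", x$quant$fractional_abundance)))
  } else {
    cat("  quantification:", conditionMessage(x$quant), "\n")
  }
  invisible(x)
}

#' @export
summary.droplet_gate <- function(object, ...) {
  structure(list(fit = object), class = "summary.droplet_gate")
}

#' @export
print.summary.droplet_gate <- function(x, ...) {
  print(x$fit)
  cat("\nCluster statistics:\n")
  for (st in x$fit$stats) print(st)
  if (!is.null(x$fit$summary)) {
    cat("\nPer-well quantification:\n")
    out <- x$fit$summary
    out$Ch1ConcCopiesPerUl <- signif(out$Ch1ConcCopiesPerUl, 4)
    out$Ch2ConcCopiesPerUl <- signif(out$Ch2ConcCopiesPerUl, 4)
    out$FractionalAbundance <- signif(out$FractionalAbundance, 4)
    print(out, row.names = FALSE)
  } else if (!inherits(x$fit$quant, "error")) {
    cat("\n")
    print(x$fit$quant)
  }
  invisible(x)
}

#' Concentration estimates from a fitted gate
#'
#' @param object A `droplet_gate` fit.
#' @param ... Unused.
#' @return For a single well, a named vector `conc_ch1`, `conc_ch2`,
#'   `fractional_abundance`; for a plate, a matrix with one row per well.
#' @export
coef.droplet_gate <- function(object, ...) {
  if (!is.null(object$summary)) {
    m <- as.matrix(object$summary[, c("Ch1ConcCopiesPerUl",
                                      "Ch2ConcCopiesPerUl",
                                      "FractionalAbundance")])
    dimnames(m) <- list(object$summary$Well,
                        c("conc_ch1", "conc_ch2", "fractional_abundance"))
    return(m)
  }
  if (inherits(object$quant, "error")) {
    stop(conditionMessage(object$quant), call. = FALSE)
  }
  c(conc_ch1 = object$quant$conc_ch1, conc_ch2 = object$quant$conc_ch2,
    fractional_abundance = object$quant$fractional_abundance)
}

#' Gate new droplets with a fitted rule
#'
#' Applies the fitted classification rule to new amplitudes: fixed
#' thresholds for a threshold fit, nearest fitted centre for a k-means fit,
#' or the stored training set for a k-NN fit. The fit's rain refinement is
#' then applied using the *fitted* cluster statistics (not statistics of
#' `newdata`), so prediction is a pure function of the fit.
#'
#' @param object A `droplet_gate` fit.
#' @param newdata A [droplet_table()].
#' @param ... Unused.
#' @return `newdata` with labels replaced.
#' @export
predict.droplet_gate <- function(object, newdata, ...) {
  newdata <- .assert_droplet_table(newdata)
  out <- switch(object$method,
    threshold = threshold_classify(newdata, object$thresholds),
    kmeans = {
      X <- .amplitude_matrix(newdata)
      d2 <- .dist2_to_centres(X, object$centres)
      lab <- rownames(object$centres)[max.col(-d2, ties.method = "first")]
      newdata$label <- .class_label(if (nrow(newdata)) lab else character())
      newdata
    },
    knn = knn_classify(newdata, object$train, k = object$k,
                       min_vote_fraction = object$min_vote_fraction))
  if (object$rain_method == "none" || nrow(out) == 0L) return(out)
  lab <- as.character(out$label)
  for (cl in intersect(names(object$stats), unique(lab))) {
    st <- object$stats[[cl]]
    idx <- which(lab == cl)
    if (object$rain_method == "sd") {
      if (st$count < 2L) next
      sds <- sqrt(diag(st$covariance))
      bad <- abs(out$ch1_amplitude[idx] - st$mean[["ch1"]]) >
               object$n_sd * sds[[1L]] |
             abs(out$ch2_amplitude[idx] - st$mean[["ch2"]]) >
               object$n_sd * sds[[2L]]
    } else {
      radii <- .rain_radii(object$max_distance)
      Sinv <- .solve_cov(st$covariance, cl)
      D <- sweep(.amplitude_matrix(out)[idx, , drop = FALSE], 2L,
                 as.numeric(st$mean))
      bad <- rowSums((D %*% Sinv) * D) > radii[[cl]]
    }
    lab[idx[bad]] <- "Rain"
  }
  out$label <- .class_label(lab)
  out
}

#' Per-droplet gating residuals
#'
#' The squared Mahalanobis distance of each droplet to the cluster it was
#' assigned, under the fitted cluster statistics. Large values flag droplets
#' on the fringe of their class; `Rain` and `Unclassified` droplets get
#' `NA`.
#'
#' @param object A `droplet_gate` fit.
#' @param ... Unused.
#' @return Numeric vector, one value per droplet.
#' @export
residuals.droplet_gate <- function(object, ...) {
  lab <- as.character(object$droplets$label)
  out <- rep(NA_real_, length(lab))
  for (cl in names(object$stats)) {
    st <- object$stats[[cl]]
    if (st$count < 3L) next
    idx <- which(lab == cl)
    if (!length(idx)) next
    Sinv <- .solve_cov(st$covariance, cl)
    D <- sweep(.amplitude_matrix(object$droplets)[idx, , drop = FALSE], 2L,
               as.numeric(st$mean))
    out[idx] <- rowSums((D %*% Sinv) * D)
  }
  out
}

#' Simulate wells from a fitted gate
#'
#' Draws synthetic wells at the fitted concentrations, using the fitted
#' cluster means and covariances as the fluorescence geometry (classes with
#' too few droplets to estimate a covariance fall back to the package
#' defaults). Useful as a parametric-bootstrap check that the gate's model
#' reproduces data that look like the input.
#'
#' @param object A `droplet_gate` fit with a valid pooled quantification.
#' @param nsim Number of wells to draw.
#' @param seed Integer seed, or `NULL`.
#' @param n_droplets Droplets per simulated well; defaults to the fitted
#'   droplet count (per well, for a plate fit).
#' @param ... Unused.
#' @return A list of `nsim` truth-labelled [droplet_table()]s.
#' @export
simulate.droplet_gate <- function(object, nsim = 1, seed = NULL,
                                  n_droplets = NULL, ...) {
  if (inherits(object$quant, "error")) {
    stop("cannot simulate from a fit without a valid quantification: ",
         conditionMessage(object$quant), call. = FALSE)
  }
  if (is.null(n_droplets)) {
    n_droplets <- if (!is.null(object$plate)) {
      max(1L, round(nrow(object$droplets) / length(object$plate)))
    } else nrow(object$droplets)
  }
  means <- default_cluster_means()
  covs <- default_cluster_covariances()
  for (cl in names(object$stats)) {
    st <- object$stats[[cl]]
    means[[cl]] <- as.numeric(st$mean)
    if (st$count >= 3L &&
        all(eigen(st$covariance, symmetric = TRUE,
                  only.values = TRUE)$values > 0)) {
      covs[[cl]] <- st$covariance
    }
  }
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) {
    simulate_well(simulation_config(
      conc_ch1 = object$quant$conc_ch1, conc_ch2 = object$quant$conc_ch2,
      n_droplets = n_droplets,
      droplet_volume_ul = object$droplet_volume_ul,
      cluster_means = means, cluster_covariances = covs, seed = NULL))
  })
}

.CLASS_COLOURS <- c(NN = "grey60", NP = "#1b9e77", PN = "#7570b3",
                    PP = "#d95f02", Rain = "black", Unclassified = "grey85")

#' Amplitude scatter of a fitted gate
#'
#' Channel 2 amplitude on the x axis and Channel 1 on the y axis (the usual
#' orientation of two-channel amplitude plots), coloured by assigned class.
#'
#' @param x A `droplet_gate` fit.
#' @param pch,cex Plotting character and size.
#' @param legend_pos Legend position keyword, or `NA` to suppress.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.droplet_gate <- function(x, pch = 20, cex = 0.3,
                              legend_pos = "topright", ...) {
  lab <- as.character(x$droplets$label)
  graphics::plot(x$droplets$ch2_amplitude, x$droplets$ch1_amplitude,
                 col = .CLASS_COLOURS[lab], pch = pch, cex = cex,
                 xlab = "Ch2 amplitude", ylab = "Ch1 amplitude", ...)
  if (x$method == "threshold") {
    graphics::abline(h = unlist(x$thresholds)[["ch1"]], lty = 2)
    graphics::abline(v = unlist(x$thresholds)[["ch2"]], lty = 2)
  }
  present <- intersect(names(.CLASS_COLOURS), unique(lab))
  if (!is.na(legend_pos) && length(present)) {
    graphics::legend(legend_pos, legend = present,
                     col = .CLASS_COLOURS[present], pch = pch, cex = 0.8)
  }
  invisible(x)
}
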