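# Poisson occupancy quantification: from gated class counts to target
# concentrations (copies per microlitre) and fractional abundance.

#' Tally droplet class counts
#'
#' @param table A labelled [droplet_table()].
#' @return Named integer vector over all six labels; sums to the droplet
#'   count.
#' @export
class_counts <- function(table) {
  table <- .assert_droplet_table(table)
  counts <- table(factor(table$label, levels = .CLASS_LEVELS))
  stats::setNames(as.integer(counts), .CLASS_LEVELS)
}

#' Poisson concentration estimate
#'
#' Because a positive droplet may contain more than one target molecule, the
#' concentration is not `P / (R * V)` but the Poisson-corrected
#' `-log(1 - P/R) / V`: if molecules are Poisson distributed over droplets of
#' volume `V`, the probability that a droplet is empty is `exp(-c * V)`, and
#' inverting the observed negative fraction `1 - P/R` gives the estimate.
#'
#' @param P Number of positive droplets for the target (integer, `0 <= P < R`).
#' @param R Total accepted droplets in the well.
#' @param V_ul Droplet volume in microlitres; the default `8.5e-4` is the
#'   instrument's nominal 0.85 nl.
#' @return Estimated concentration in copies per microlitre.
#' @export
#' @examples
#' target_concentration(10000, 20000)  # log(2) / 8.5e-4, about 815.5
target_concentration <- function(P, R, V_ul = 8.5e-4) {
  if (!is.finite(V_ul) || V_ul <= 0) stop("V_ul must be > 0", call. = FALSE)
  if (!is.finite(R) || R <= 0) {
    stop("empty well: no accepted droplets (R = 0)", call. = FALSE)
  }
  if (!is.finite(P) || P < 0 || P > R) {
    stop("P must satisfy 0 <= P <= R", call. = FALSE)
  }
  if (P == R) {
    stop("all droplets positive; concentration unbounded (saturated well)",
         call. = FALSE)
  }
  -log(1 - P / R) / V_ul
}

#' Quantify one gated well
#'
#' Counts droplets per class, forms the accepted total
#' `R = NN + NP + PN + PP`, the per-channel positives
#' `P_ch1 = PN + PP` and `P_ch2 = NP + PP`, and converts each to a
#' concentration with [target_concentration()]. By default `Rain` and
#' `Unclassified` droplets are ambiguous and excluded from both the positives
#' and the accepted total; set `exclude_rain = FALSE` to count them as
#' accepted negatives instead. Fractional abundance is the Channel 1 (by
#' convention, mutant) concentration as a fraction of the total,
#' `conc_ch1 / (conc_ch1 + conc_ch2)`; it is `NA` when both concentrations
#' are zero.
#'
#' @param table A labelled [droplet_table()].
#' @param V_ul Droplet volume in microlitres.
#' @param exclude_rain Exclude `Rain`/`Unclassified` from the accepted total.
#' @return A `quant_result` object: list with `counts`, `accepted_total`,
#'   `ch1_positive`, `ch2_positive`, `droplet_volume_ul`, `conc_ch1`,
#'   `conc_ch2`, `fractional_abundance`.
#' @export
quantify_well <- function(table, V_ul = 8.5e-4, exclude_rain = TRUE) {
  counts <- class_counts(table)
  R <- sum(counts[.CORE_CLASSES]) +
    if (exclude_rain) 0L else counts[["Rain"]] + counts[["Unclassified"]]
  P1 <- counts[["PN"]] + counts[["PP"]]
  P2 <- counts[["NP"]] + counts[["PP"]]
  conc1 <- target_concentration(P1, R, V_ul)
  conc2 <- target_concentration(P2, R, V_ul)
  fa <- if (conc1 + conc2 > 0) conc1 / (conc1 + conc2) else NA_real_
  structure(
    list(counts = counts, accepted_total = as.integer(R),
         ch1_positive = P1, ch2_positive = P2, droplet_volume_ul = V_ul,
         conc_ch1 = conc1, conc_ch2 = conc2, fractional_abundance = fa,
         exclude_rain = exclude_rain),
    class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("accepted droplets: %d (Ch1+: %d, Ch2+: %d)\n",
              x$accepted_total, x$ch1_positive, x$ch2_positive))
  cat(sprintf("concentration: Ch1 %.4g, Ch2 %.4g copies/ul\n",
              x$conc_ch1, x$conc_ch2))
  cat(sprintf("fractional abundance (Ch1 / total): %s\n",
              if (is.na(x$fractional_abundance)) "undefined"
              else sprintf("%.4g", x$fractional_abundance)))
  invisible(x)
}

#' Summarise a gated plate
#'
#' One row per well, in plate order, with class counts, accepted totals,
#' per-channel positives and concentrations, and fractional abundance. A well
#' whose quantification fails (e.g. saturated: all droplets positive in a
#' channel) is reported with `NA` concentrations and the error message in the
#' `Status` column rather than aborting the whole plate.
#'
#' @param plate A [ddpcr_plate()] of labelled wells.
#' @param V_ul Droplet volume in microlitres.
#' @param exclude_rain See [quantify_well()].
#' @return A `data.frame` with columns `Well`, the six class counts,
#'   `AcceptedDroplets`, `Ch1Positives`, `Ch2Positives`,
#'   `Ch1ConcCopiesPerUl`, `Ch2ConcCopiesPerUl`, `FractionalAbundance`,
#'   `Status`.
#' @export
summarize_plate <- function(plate, V_ul = 8.5e-4, exclude_rain = TRUE) {
  stopifnot(inherits(plate, "ddpcr_plate"))
  rows <- lapply(names(plate), function(w) {
    counts <- class_counts(plate[[w]])
    q <- tryCatch(quantify_well(plate[[w]], V_ul, exclude_rain),
                  error = function(e) e)
    if (inherits(q, "error")) {
      data.frame(Well = w, NN = counts[["NN"]], NP = counts[["NP"]],
                 PN = counts[["PN"]], PP = counts[["PP"]],
                 Rain = counts[["Rain"]],
                 Unclassified = counts[["Unclassified"]],
                 AcceptedDroplets = sum(counts[.CORE_CLASSES]),
                 Ch1Positives = counts[["PN"]] + counts[["PP"]],
                 Ch2Positives = counts[["NP"]] + counts[["PP"]],
                 Ch1ConcCopiesPerUl = NA_real_,
                 Ch2ConcCopiesPerUl = NA_real_,
                 FractionalAbundance = NA_real_,
                 Status = conditionMessage(q),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(Well = w, NN = counts[["NN"]], NP = counts[["NP"]],
                 PN = counts[["PN"]], PP = counts[["PP"]],
                 Rain = counts[["Rain"]],
                 Unclassified = counts[["Unclassified"]],
                 AcceptedDroplets = q$accepted_total,
                 Ch1Positives = q$ch1_positive, Ch2Positives = q$ch2_positive,
                 Ch1ConcCopiesPerUl = q$conc_ch1,
                 Ch2ConcCopiesPerUl = q$conc_ch2,
                 FractionalAbundance = q$fractional_abundance,
                 Status = "ok", stringsAsFactors = FALSE)
    }
  })
  if (!length(rows)) {
    return(data.frame(Well = character(), NN = integer(), NP = integer(),
                      PN = integer(), PP = integer(), Rain = integer(),
                      Unclassified = integer(), AcceptedDroplets = integer(),
                      Ch1Positives = integer(), Ch2Positives = integer(),
                      Ch1ConcCopiesPerUl = numeric(),
                      Ch2ConcCopiesPerUl = numeric(),
                      FractionalAbundance = numeric(), Status = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a plate summary CSV
#'
#' Concentrations and fractional abundance are rounded to 4 significant
#' figures in the file; the in-memory summary keeps full precision.
#'
#' @param summary A summary as returned by [summarize_plate()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_plate_summary_csv <- function(summary, path) {
  out <- summary
  for (col in c("Ch1ConcCopiesPerUl", "Ch2ConcCopiesPerUl",
                "FractionalAbundance")) {
    out[[col]] <- signif(out[[col]], 4L)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
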