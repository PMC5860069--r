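# Canonical droplet class labels. The first letter encodes Channel 1 status,
# the second Channel 2 status; Rain and Unclassified are never positive.
.CLASS_LEVELS <- c("NN", "NP", "PN", "PP", "Rain", "Unclassified")
.CORE_CLASSES <- c("NN", "NP", "PN", "PP")

#' Droplet class labels
#'
#' Droplets in a two-channel ddPCR experiment are classified by channel
#' positivity: `NN` (negative in both channels), `NP` (positive only in
#' Channel 2), `PN` (positive only in Channel 1) and `PP` (positive in both).
#' The first letter is the Channel 1 status and the second the Channel 2
#' status. Two further labels mark droplets excluded from quantification:
#' `Rain` for ambiguous droplets of intermediate fluorescence lying between
#' the main clusters, and `Unclassified` for droplets not yet gated.
#'
#' @param core_only If `TRUE`, return only the four quantifiable classes
#'   (`NN`, `NP`, `PN`, `PP`).
#' @return Character vector of label names in canonical order.
#' @export
#' @examples
#' droplet_classes()
#' droplet_classes(core_only = TRUE)
droplet_classes <- function(core_only = FALSE) {
  if (core_only) .CORE_CLASSES else .CLASS_LEVELS
}

# Factor constructor for labels; unknown values are an error upstream.
.class_label <- function(x) {
  f <- factor(as.character(x), levels = .CLASS_LEVELS)
  if (anyNA(f) && !anyNA(x)) {
    bad <- unique(as.character(x)[is.na(f)])
    stop("unknown droplet class label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  f
}

# Compose NN/NP/PN/PP from per-channel positivity flags.
.compose_label <- function(ch1_positive, ch2_positive) {
  paste0(ifelse(ch1_positive, "P", "N"), ifelse(ch2_positive, "P", "N"))
}

#' Construct a droplet table
#'
#' A droplet table holds per-droplet two-channel fluorescence amplitudes
#' (arbitrary units) and one class label per droplet. It is an ordinary
#' `data.frame` with columns `ch1_amplitude`, `ch2_amplitude` and `label`,
#' so the usual data-frame tools apply.
#'
#' @param ch1_amplitude,ch2_amplitude Numeric vectors of equal length;
#'   all values must be finite.
#' @param label Class labels, recycled to the number of droplets; one of
#'   [droplet_classes()]. Defaults to `"Unclassified"`.
#' @return A `data.frame` of class `droplet_table`.
#' @export
#' @examples
#' droplet_table(c(7000, 5000), c(3500, 2000))
droplet_table <- function(ch1_amplitude = numeric(),
                          ch2_amplitude = numeric(),
                          label = "Unclassified") {
  ch1 <- as.numeric(ch1_amplitude)
  ch2 <- as.numeric(ch2_amplitude)
  if (length(ch1) != length(ch2)) {
    stop("ch1_amplitude and ch2_amplitude must have the same length",
         call. = FALSE)
  }
  if (length(ch1) && (!all(is.finite(ch1)) || !all(is.finite(ch2)))) {
    stop("droplet amplitudes must be finite", call. = FALSE)
  }
  lab <- .class_label(rep_len(as.character(label), length(ch1)))
  structure(
    data.frame(ch1_amplitude = ch1, ch2_amplitude = ch2, label = lab,
               stringsAsFactors = FALSE),
    class = c("droplet_table", "data.frame")
  )
}

#' Coerce to a droplet table
#'
#' @param x A `data.frame` with columns `ch1_amplitude`, `ch2_amplitude` and
#'   optionally `label`.
#' @return A `droplet_table`.
#' @export
as_droplet_table <- function(x) {
  if (inherits(x, "droplet_table")) return(.assert_droplet_table(x))
  if (!is.data.frame(x)) stop("cannot coerce to droplet_table", call. = FALSE)
  lab <- if ("label" %in% names(x)) x$label else "Unclassified"
  droplet_table(x$ch1_amplitude, x$ch2_amplitude, lab)
}

.assert_droplet_table <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("ch1_amplitude", "ch2_amplitude", "label") %in% names(x)))
  x
}

# Amplitudes as an n x 2 matrix (ch1, ch2).
.amplitude_matrix <- function(table) {
  cbind(ch1 = table$ch1_amplitude, ch2 = table$ch2_amplitude)
}

#' @export
print.droplet_table <- function(x, ...) {
  cat(sprintf("droplet_table: %d droplets\n", nrow(x)))
  if (nrow(x)) {
    counts <- table(factor(x$label, levels = .CLASS_LEVELS))
    nz <- counts[counts > 0]
    cat("  ", paste(sprintf("%s=%d", names(nz), nz), collapse = ", "), "\n")
  }
  NextMethod()
}
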