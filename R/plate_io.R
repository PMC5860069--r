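# Reading and writing QuantaSoft-style per-well droplet amplitude CSV files.

# Normalise a header name for dialect-insensitive matching:
# "Ch1 Amplitude", "Ch1Amplitude" and read.csv's "Ch1.Amplitude" all map to
# "ch1amplitude".
.norm_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Default vendor cluster code map
#'
#' Instrument exports may carry a numeric `Cluster` column. Its semantics are
#' not publicly documented, so the mapping used when reading such files is
#' explicit and overridable: 1 = NN, 2 = PN, 3 = NP, 4 = PP; any other code
#' becomes `Unclassified`.
#'
#' @return Named character vector mapping code (as character) to class label.
#' @export
quantasoft_cluster_map <- function() {
  c("1" = "NN", "2" = "PN", "3" = "NP", "4" = "PP")
}

#' Parse a droplet amplitude CSV
#'
#' Reads a per-well amplitude file as exported by Bio-Rad's QuantaSoft: a
#' comma-separated table with a header row containing at least the two
#' amplitude columns. Header matching is whitespace- and case-insensitive, so
#' both `"Ch1 Amplitude"` and `"Ch1Amplitude"` dialects are accepted. If a
#' `Class` column is present (as written by [write_classified_csv()]) its
#' label names are used directly; otherwise, if a vendor `Cluster` code column
#' is present, codes are mapped through `code_map`; otherwise every droplet is
#' `Unclassified`.
#'
#' @param x A file path, or a character string / vector containing CSV text
#'   (recognised as text when it contains a newline or has length > 1).
#' @param code_map Named character vector mapping vendor cluster codes to
#'   class labels; see [quantasoft_cluster_map()].
#' @return A [droplet_table()].
#' @export
#' @examples
#' parse_amplitude_csv("Ch1 Amplitude,Ch2 Amplitude\n7000,3500\n5000,2000\n")
parse_amplitude_csv <- function(x, code_map = quantasoft_cluster_map()) {
  is_text <- length(x) > 1L || any(grepl("\n", x, fixed = TRUE))
  df <- if (is_text) {
    utils::read.csv(text = paste(x, collapse = "\n"), check.names = FALSE,
                    colClasses = "character", strip.white = TRUE)
  } else {
    utils::read.csv(x, check.names = FALSE, colClasses = "character",
                    strip.white = TRUE)
  }
  hdr <- .norm_header(names(df))
  pick <- function(key) {
    i <- which(hdr == key)
    if (length(i)) i[1L] else NA_integer_
  }
  i1 <- pick("ch1amplitude")
  i2 <- pick("ch2amplitude")
  if (is.na(i1)) stop("amplitude column 'Ch1 Amplitude' not found in header",
                      call. = FALSE)
  if (is.na(i2)) stop("amplitude column 'Ch2 Amplitude' not found in header",
                      call. = FALSE)

  to_num <- function(col, name) {
    v <- suppressWarnings(as.numeric(col))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop(sprintf("non-numeric amplitude '%s' in column '%s' at data row %d",
                   col[bad[1L]], name, bad[1L]), call. = FALSE)
    }
    v
  }
  ch1 <- to_num(df[[i1]], names(df)[i1])
  ch2 <- to_num(df[[i2]], names(df)[i2])

  iclass <- pick("class")
  icluster <- pick("cluster")
  label <- if (nrow(df) == 0L) {
    character()
  } else if (!is.na(iclass)) {
    v <- df[[iclass]]
    ifelse(v %in% .CLASS_LEVELS, v, "Unclassified")
  } else if (!is.na(icluster)) {
    mapped <- unname(code_map[df[[icluster]]])
    ifelse(is.na(mapped), "Unclassified", mapped)
  } else {
    "Unclassified"
  }
  droplet_table(ch1, ch2, if (length(ch1)) label else "Unclassified")
}

#' Extract a well name from an amplitude file name
#'
#' QuantaSoft exports one amplitude file per well with the well name embedded
#' in the file name, e.g. `"EXP_A01_Amplitude.csv"`. The well token must match
#' `[A-H](0?[1-9]|1[0-2])`, delimited by underscores (or the start of the file
#' name / the extension dot). The result is normalised to the canonical
#' zero-padded form (`A1` becomes `A01`).
#'
#' @param filename A file name or path.
#' @return Canonical well name string, e.g. `"A01"`.
#' @export
#' @examples
#' well_name_from_filename("KRAS_A01_Amplitude.csv")
#' well_name_from_filename("exp_H12_Amplitude.csv")
well_name_from_filename <- function(filename) {
  base <- basename(filename)
  m <- regmatches(base,
                  regexpr("(^|_)[A-Ha-h](0?[1-9]|1[0-2])(?=(_|\\.|$))",
                          base, perl = TRUE))
  if (!length(m) || !nzchar(m)) {
    stop(sprintf("cannot find a well name (like A01) in file name '%s'", base),
         call. = FALSE)
  }
  token <- sub("^_", "", m)
  row <- toupper(substr(token, 1L, 1L))
  col <- as.integer(substr(token, 2L, nchar(token)))
  sprintf("%s%02d", row, col)
}

.WELL_RE <- "^[A-H](0[1-9]|1[0-2])$"

#' Construct a ddPCR plate
#'
#' A plate is an ordered, named collection of wells (canonical well name, e.g.
#' `"A01"`, mapped to a [droplet_table()]) plus free-form metadata. Iteration
#' order is insertion order and well names are unique. A plate behaves as a
#' named list: `plate[["A01"]]`, `names(plate)` and `length(plate)` all work.
#'
#' @param wells Named list of droplet tables; names must be canonical well
#'   names and unique.
#' @param metadata Free-form named list (experiment name, assay names, ...).
#' @return An object of class `ddpcr_plate`.
#' @export
ddpcr_plate <- function(wells = list(), metadata = list()) {
  if (length(wells)) {
    nm <- names(wells)
    if (is.null(nm) || any(!nzchar(nm))) {
      stop("every well must be named", call. = FALSE)
    }
    if (anyDuplicated(nm)) {
      stop("duplicate well name(s): ",
           paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
    }
    bad <- nm[!grepl(.WELL_RE, nm)]
    if (length(bad)) {
      stop("invalid well name(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    wells <- lapply(wells, .assert_droplet_table)
  }
  structure(wells, class = "ddpcr_plate", metadata = metadata)
}

#' Plate metadata
#' @param plate A `ddpcr_plate`.
#' @return The metadata list.
#' @export
plate_metadata <- function(plate) attr(plate, "metadata")

#' @export
print.ddpcr_plate <- function(x, ...) {
  n <- vapply(x, nrow, integer(1))
  cat(sprintf("ddpcr_plate: %d well(s), %d droplets\n",
              length(x), if (length(n)) sum(n) else 0L))
  if (length(x)) {
    cat("  wells:", paste(names(x), collapse = " "), "\n")
  }
  invisible(x)
}

#' Load a plate from per-well amplitude files
#'
#' Each file is parsed with [parse_amplitude_csv()] and assigned to the well
#' named in its file name via [well_name_from_filename()]. Wells appear in
#' input order; a duplicated well name is an error, and per-file errors are
#' reported with the offending file name.
#'
#' @param paths Character vector of amplitude CSV file paths.
#' @param code_map Vendor cluster code map, see [parse_amplitude_csv()].
#' @return A [ddpcr_plate()].
#' @export
load_plate <- function(paths, code_map = quantasoft_cluster_map()) {
  wells <- list()
  for (p in paths) {
    well <- tryCatch(well_name_from_filename(p), error = function(e) {
      stop(sprintf("%s: %s", p, conditionMessage(e)), call. = FALSE)
    })
    if (well %in% names(wells)) {
      stop(sprintf("duplicate well %s (file '%s')", well, p), call. = FALSE)
    }
    tab <- tryCatch(parse_amplitude_csv(p, code_map = code_map),
                    error = function(e) {
      stop(sprintf("%s: %s", p, conditionMessage(e)), call. = FALSE)
    })
    wells[[well]] <- tab
  }
  ddpcr_plate(wells)
}

# Render a double so that as.numeric() recovers it exactly.
.num_to_text <- function(x) {
  out <- sprintf("%.17g", x)
  short <- sprintf("%.15g", x)
  ok <- as.numeric(short) == x
  out[ok] <- short[ok]
  out
}

#' Write a classified droplet CSV
#'
#' Writes amplitudes plus a `Class` column of label names. Numeric rendering
#' is chosen so that [parse_amplitude_csv()] recovers the amplitudes exactly
#' (write-then-parse is the identity on droplet count, amplitudes and labels).
#'
#' @param table A [droplet_table()].
#' @param path Output file path, or `NULL` to return the CSV text.
#' @return Invisibly, the CSV text as a single string (returned visibly when
#'   `path` is `NULL`).
#' @export
write_classified_csv <- function(table, path = NULL) {
  table <- .assert_droplet_table(table)
  lines <- c("Ch1 Amplitude,Ch2 Amplitude,Class",
             if (nrow(table)) {
               paste(.num_to_text(table$ch1_amplitude),
                     .num_to_text(table$ch2_amplitude),
                     as.character(table$label), sep = ",")
             })
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(text)
  writeLines(lines, path)
  invisible(text)
}
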