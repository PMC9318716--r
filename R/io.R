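# Plain-text series input and JSON report output.

#' Read a scalar time series from a text file
#'
#' Reads a series from a plain-text file: either one value per line, or a
#' delimited (comma / tab / whitespace) table with an optional header row
#' from which one column is selected. Lines starting with `#` and blank
#' lines are skipped. Every selected token must parse as a finite real;
#' the first offending token is reported with its line number.
#'
#' @param path Path to the file.
#' @param column Column selector for delimited files: a name (requires a
#'   header row) or a 1-based index. `NULL` (default) requires a
#'   single-column file.
#' @return Numeric vector (length `>= 2`) in file order.
#' @export
read_series <- function(path, column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) stop("no data lines in ", path, call. = FALSE)
  body <- trimws(lines[keep])

  delim <- if (any(grepl(",", body, fixed = TRUE))) "," else "[\t ]+"
  fields <- strsplit(body, delim)

  ncols <- lengths(fields)
  if (any(ncols != ncols[1])) {
    bad <- keep[which(ncols != ncols[1])[1]]
    stop(sprintf("inconsistent number of fields at line %d of %s", bad, path),
         call. = FALSE)
  }

  header <- NULL
  first <- suppressWarnings(as.numeric(fields[[1]]))
  if (anyNA(first)) {            # non-numeric first row: treat as header
    header <- fields[[1]]
    fields <- fields[-1]
    keep <- keep[-1]
    if (!length(fields)) stop("no data rows in ", path, call. = FALSE)
  }

  j <- 1L
  if (is.null(column)) {
    if (ncols[1] > 1) {
      stop("file has ", ncols[1], " columns; select one with `column`",
           call. = FALSE)
    }
  } else if (is.character(column)) {
    if (is.null(header)) {
      stop("`column` given by name but the file has no header row",
           call. = FALSE)
    }
    j <- match(column, header)
    if (is.na(j)) {
      stop(sprintf("no column named '%s' (header: %s)", column,
                   paste(header, collapse = ", ")), call. = FALSE)
    }
  } else {
    j <- as.integer(column)
    if (is.na(j) || j < 1 || j > ncols[1]) {
      stop("`column` index out of range", call. = FALSE)
    }
  }

  tokens <- vapply(fields, `[`, character(1), j)
  values <- suppressWarnings(as.numeric(tokens))
  bad <- which(is.na(values) | !is.finite(values))
  if (length(bad)) {
    stop(sprintf("cannot parse '%s' as a finite number at line %d of %s",
                 tokens[bad[1]], keep[bad[1]], path), call. = FALSE)
  }
  if (length(values) < 2) {
    stop("series too short: fewer than 2 samples in ", path, call. = FALSE)
  }
  values
}

#' Write a PE-uncertainty result to a JSON report
#'
#' Serializes a [estimate_pe_with_uncertainty()] result to JSON at full
#' numeric precision, so that [read_report()] reproduces every field
#' bit-exactly. Timestamps live in a separate `metadata` block, keeping the
#' scientific payload reproducible across reruns.
#'
#' @param result A `"pe_uncertainty"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  if (!inherits(result, "pe_uncertainty")) {
    stop("`result` must be a pe_uncertainty object", call. = FALSE)
  }
  e <- result$estimate
  payload <- list(
    h = e$h,
    h_normalized = e$h_normalized,
    plug_in = e$plug_in,
    mm_correction = e$mm_correction,
    sigma = e$sigma,
    sigma_label = e$sigma_label,
    s_surrogate = result$s_surrogate,
    alpha = result$alpha,
    l = result$l,
    m = result$m,
    n = result$n,
    seed = result$seed,
    mean_surrogate_pe = result$mean_surrogate_pe,
    per_surrogate_pe = as.list(result$per_surrogate_pe),
    iterations = as.list(result$iterations),
    converged = as.list(result$converged),
    metadata = list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                    package = as.character(utils::packageVersion("pevar")))
  )
  # I(17) = 17 *significant* digits: enough for doubles to round-trip exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a PE-uncertainty report back
#'
#' Inverse of [write_report()]: reconstructs the `"pe_uncertainty"` object
#' (the `metadata` block is kept in an attribute).
#'
#' @param path Path to a JSON report.
#' @return A `"pe_uncertainty"` object.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  est <- structure(
    list(h = p$h,
         h_normalized = p$h_normalized,
         m = as.integer(p$m),
         n = as.integer(p$n),
         plug_in = p$plug_in,
         mm_correction = p$mm_correction,
         sigma = p$sigma,
         sigma_label = p$sigma_label),
    class = "pe_estimate")
  structure(
    list(estimate = est,
         s_surrogate = p$s_surrogate,
         alpha = p$alpha,
         l = as.integer(p$l),
         m = as.integer(p$m),
         n = as.integer(p$n),
         seed = if (is.null(p$seed)) NULL else as.integer(p$seed),
         mean_surrogate_pe = p$mean_surrogate_pe,
         per_surrogate_pe = as.numeric(p$per_surrogate_pe),
         iterations = as.integer(p$iterations),
         converged = as.logical(p$converged)),
    class = "pe_uncertainty",
    metadata = p$metadata)
}
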