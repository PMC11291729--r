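# Text trace files in an ATF-style dialect: a two-line magic/shape header,
# quoted "key=value" metadata records, quoted column titles with units,
# then tab-separated samples. Human-inspectable and diff-able; one file
# holds one or more sweeps that share a time base.

atf_quote <- function(x) paste0('"', x, '"')
atf_unquote <- function(x) gsub('^"|"$', "", x)

#' Write current traces to an ATF-style text file
#'
#' Writes one sweep, or several sweeps sharing a sampling rate, as
#' tab-separated text with metadata records (sampling rate, filter cutoff,
#' capacitance, seed, model, units). Ramp sweeps gain a per-sample
#' `Voltage (mV)` column; step/hold sweeps record their command voltage in
#' the column title. Values round-trip through [read_trace()] to the
#' written precision (9 significant digits).
#'
#' @param trace a [pq_trace()] or list of them (shared sampling rate).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  traces <- if (inherits(trace, "pq_trace")) list(trace) else trace
  stopifnot(length(traces) >= 1,
            all(vapply(traces, inherits, TRUE, "pq_trace")))
  fs <- unique(vapply(traces, `[[`, numeric(1), "sampling_rate"))
  if (length(fs) != 1) stop("sweeps in one file must share a sampling rate")
  ns <- unique(lengths(lapply(traces, `[[`, "samples")))
  if (length(ns) != 1) stop("sweeps in one file must share a length")
  t1 <- traces[[1]]
  is_ramp <- length(t1$voltage) > 1

  rec <- c(sprintf("sampling_rate_hz=%.10g", fs),
           sprintf("filter_cutoff_hz=%.10g", t1$filter_cutoff),
           sprintf("capacitance_pf=%.10g", t1$capacitance),
           sprintf("seed=%s", t1$seed),
           sprintf("model=%s", t1$model),
           "units=pA")
  titles <- "Time (s)"
  cols <- list(sprintf("%.9g", (seq_len(ns) - 1) / fs))
  if (is_ramp) {
    if (length(traces) > 1) stop("ramp files hold a single sweep")
    titles <- c(titles, "Voltage (mV)")
    cols <- c(cols, list(sprintf("%.9g", t1$voltage)))
  }
  for (k in seq_along(traces)) {
    tk <- traces[[k]]
    titles <- c(titles,
                if (is_ramp) "Current (pA)"
                else sprintf("Current (pA) sweep=%d V=%.10g", k, tk$voltage))
    cols <- c(cols, list(sprintf("%.9g", tk$samples)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ATF\t1.0",
               sprintf("%d\t%d", length(rec), length(cols)),
               atf_quote(rec),
               paste(atf_quote(titles), collapse = "\t")), con)
  writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

#' Read an ATF-style trace file
#'
#' Validates the header (magic line, declared column count, current
#' columns labelled in pA, time-column spacing consistent with the
#' declared sampling rate to within 1 ppm) and returns the sweeps.
#'
#' @param path file written by [write_trace()] (or any conforming file).
#' @return A single [pq_trace()] for one-sweep files, otherwise a list of
#'   traces sharing the file's metadata.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4 || !grepl("^ATF\\b", lines[1]))
    stop("not an ATF-style trace file: ", path)
  shape <- strsplit(lines[2], "\t")[[1]]
  n_rec <- as.integer(shape[1]); n_col <- as.integer(shape[2])
  if (is.na(n_rec) || is.na(n_col)) stop("malformed shape line in ", path)
  if (length(lines) < 3 + n_rec) stop("truncated header in ", path)
  recs <- atf_unquote(lines[3:(2 + n_rec)])
  meta <- list()
  for (r in recs) {
    kv <- strsplit(r, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  if (!is.null(meta$units) && meta$units != "pA")
    stop("unsupported current units '", meta$units, "' (expected pA)")
  titles <- atf_unquote(strsplit(lines[3 + n_rec], "\t")[[1]])
  if (length(titles) != n_col)
    stop(sprintf("declared %d columns but found %d titles", n_col,
                 length(titles)))
  body <- lines[-seq_len(3 + n_rec)]
  body <- body[nzchar(body)]
  if (length(body) == 0) stop("truncated file (no samples): ", path)
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != n_col))
    stop("truncated or ragged data rows in ", path)
  dat <- matrix(as.numeric(unlist(parts)), ncol = n_col, byrow = TRUE)
  if (any(!is.finite(dat))) stop("non-numeric samples in ", path)

  if (!grepl("Time \\(s\\)", titles[1]))
    stop("first column must be Time (s)")
  fs <- as.numeric(meta$sampling_rate_hz)
  if (is.na(fs)) stop("missing sampling_rate_hz record")
  tcol <- dat[, 1]
  if (length(tcol) > 1) {
    dt <- diff(tcol)
    if (any(abs(dt * fs - 1) > 1e-6 + 1e-6))
      stop(sprintf(
        "declared sampling rate %g Hz disagrees with the time column", fs))
  }
  cur_cols <- which(grepl("Current", titles))
  if (length(cur_cols) == 0) stop("no current column found")
  bad <- cur_cols[grepl("\\(mV\\)", titles[cur_cols]) |
                    !grepl("\\(pA\\)", titles[cur_cols])]
  if (length(bad))
    stop("current column '", titles[bad[1]], "' is not in pA")
  vcol <- which(grepl("^Voltage \\(mV\\)", titles))

  num_meta <- function(key) {
    v <- suppressWarnings(as.numeric(meta[[key]]))
    if (length(v) == 0 || is.na(v)) NA_real_ else v
  }
  mk <- function(col, voltage) {
    pq_trace(dat[, col], fs, voltage = voltage,
             capacitance = num_meta("capacitance_pf"),
             filter_cutoff = num_meta("filter_cutoff_hz"),
             seed = suppressWarnings(as.integer(meta$seed)),
             model = if (is.null(meta$model)) NA_character_ else meta$model)
  }
  traces <- lapply(cur_cols, function(cc) {
    v <- if (length(vcol) == 1) dat[, vcol]
    else {
      vm <- regmatches(titles[cc], regexpr("V=[-+0-9.eE]+", titles[cc]))
      if (length(vm)) as.numeric(sub("V=", "", vm)) else num_meta("voltage_mv")
    }
    mk(cc, v)
  })
  if (length(traces) == 1) traces[[1]] else traces
}
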