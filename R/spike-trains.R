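#' Motoneuron spike-train sets
#'
#' A `spike_train_set` holds the discharge times of a set of motor units
#' together with the sampling rate used for binary representations and the
#' recording duration. Discharge times are stored exactly; the binary
#' matrix view quantizes them to the nearest sample.
#'
#' @param times List of numeric vectors, one per MU, of discharge times in
#'   seconds (sorted; may be empty).
#' @param fs Sampling rate in Hz used for the binary-matrix view.
#' @param duration Recording duration in seconds; defaults to the last
#'   discharge time.
#' @return An object of class `spike_train_set`.
#' @examples
#' sts <- spike_train_set(list(c(0.1, 0.2), 0.35), fs = 2048, duration = 0.5)
#' spike_matrix(sts)[, 1:5]
#' @export
spike_train_set <- function(times, fs = 2048, duration = NULL) {
  if (!is.list(times)) times <- list(times)
  times <- lapply(times, function(tt) sort(as.numeric(tt)))
  if (is.null(duration)) {
    mx <- suppressWarnings(max(unlist(times), 0))
    duration <- mx
  }
  bad <- vapply(times, function(tt) length(tt) && (min(tt) < 0 || max(tt) > duration),
                logical(1))
  if (any(bad)) abort("Discharge times must lie within [0, duration].")
  if (fs <= 0) abort("`fs` must be > 0.")
  structure(list(times = times, fs = fs, duration = duration,
                 n_mu = length(times)),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  n <- vapply(x$times, length, integer(1))
  cat(sprintf("<spike_train_set> %d MUs, %.1f s at %g Hz, %d discharges\n",
              x$n_mu, x$duration, x$fs, sum(n)))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @method as_tibble spike_train_set
#' @export
as_tibble.spike_train_set <- function(x, ...) {
  tibble::tibble(
    mu = rep(seq_along(x$times), vapply(x$times, length, integer(1))),
    time = unlist(x$times) %||% numeric(0))
}

#' @rdname spike_train_set
#' @param x A `spike_train_set`.
#' @return `spike_matrix()`: an integer 0/1 matrix, MUs in rows, samples in
#'   columns (sample `k` covers time `(k-1)/fs`).
#' @export
spike_matrix <- function(x) {
  stopifnot(inherits(x, "spike_train_set"))
  n_s <- floor(x$duration * x$fs) + 1L
  m <- matrix(0L, nrow = x$n_mu, ncol = n_s)
  for (k in seq_len(x$n_mu)) {
    idx <- round(x$times[[k]] * x$fs) + 1L
    idx <- pmin(pmax(idx, 1L), n_s)
    m[k, idx] <- 1L
  }
  m
}

#' @rdname spike_train_set
#' @param m Binary matrix (MU x sample).
#' @param fs,duration Sampling rate and duration of the matrix view.
#' @export
spikes_from_matrix <- function(m, fs = 2048, duration = (ncol(m) - 1) / fs) {
  if (!all(m %in% c(0L, 1L))) abort("Spike matrix values must be 0 or 1.")
  times <- lapply(seq_len(nrow(m)), function(k) (which(m[k, ] == 1L) - 1L) / fs)
  spike_train_set(times, fs = fs, duration = duration)
}

#' Read and write spike-train sets
#'
#' Two plain-text dialects are supported. `"tsv"` stores the binary matrix,
#' one row per sample and one column per MU, preceded by `#fs=` and
#' `#duration=` header comments (lossless for binary matrices). `"json"`
#' stores exact discharge-time lists (lossless for discharge times).
#' The format is inferred from the file extension when not given.
#'
#' @param x A [spike_train_set()].
#' @param path File path.
#' @param format `"tsv"` or `"json"`.
#' @return `read_spike_trains()` returns a [spike_train_set()];
#'   `write_spike_trains()` returns `path` invisibly.
#' @export
write_spike_trains <- function(x, path, format = c("auto", "tsv", "json")) {
  stopifnot(inherits(x, "spike_train_set"))
  format <- match.arg(format)
  if (format == "auto") format <- if (grepl("\\.json$", path)) "json" else "tsv"
  if (format == "json") {
    jsonlite::write_json(
      list(fs = x$fs, duration = x$duration, n_mu = x$n_mu,
           times = x$times),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    m <- t(spike_matrix(x))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("#fs=%.10g", x$fs),
                 sprintf("#duration=%.10g", x$duration),
                 paste(paste0("mu", seq_len(ncol(m))), collapse = "\t")), con)
    utils::write.table(m, con, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") format <- if (grepl("\\.json$", path)) "json" else "tsv"
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    times <- obj$times
    if (is.null(times)) abort("Malformed spike JSON: no `times` field.")
    if (!is.list(times)) times <- as.list(times)
    times <- lapply(times, function(tt) as.numeric(tt %||% numeric(0)))
    return(spike_train_set(times, fs = obj$fs, duration = obj$duration))
  }
  lines <- readLines(path)
  if (!length(lines)) abort("Empty spike file: no MUs.")
  hdr <- grep("^#", lines, value = TRUE)
  fs <- as.numeric(sub("^#fs=", "", grep("^#fs=", hdr, value = TRUE)[1]))
  duration <- as.numeric(sub("^#duration=", "",
                             grep("^#duration=", hdr, value = TRUE)[1]))
  if (is.na(fs) || is.na(duration)) {
    abort("Malformed spike TSV header: need #fs= and #duration= lines.")
  }
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 2) abort("Empty spike file: no MUs.")
  dat <- utils::read.table(text = body, header = TRUE, sep = "\t")
  m <- t(as.matrix(dat))
  if (!all(m %in% c(0, 1))) {
    bad <- which(apply(dat, 1, function(r) !all(r %in% c(0, 1))))[1]
    abort(sprintf("Non-binary spike value at data line %d.", bad))
  }
  spikes_from_matrix(m, fs = fs, duration = duration)
}

#' Read and write timed traces
#'
#' Two-column tab-delimited text (`time`, value) with a header row;
#' lines starting with `#` are ignored on read.
#'
#' @param x Data frame with a `time` column and one value column.
#' @param path File path.
#' @return `read_trace()` returns a tibble `(time, value)`.
#' @export
write_trace <- function(x, path) {
  tr <- check_trace(x)
  utils::write.table(tr, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  dat <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  check_trace(dat)
}

#' Read and write MU pool tables
#'
#' Tab-delimited export of a [mu_pool()] tibble with integer-rounded
#' innervation ratios (largest-remainder rounding preserves the fibre
#' total), plus a JSON alternative keeping full precision.
#'
#' @param pool A [mu_pool()] tibble.
#' @param path File path; `.json` selects the JSON dialect.
#' @return `read_mu_pool()` returns a tibble.
#' @export
write_mu_pool <- function(pool, path) {
  out <- tibble::as_tibble(pool)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(out, path, digits = NA)
  } else {
    out$IR <- round_innervation_ratios(out$IR)
    names(out)[names(out) == "T_th"] <- "T_th_pctMVC"
    utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_mu_pool
#' @export
read_mu_pool <- function(path) {
  if (grepl("\\.json$", path)) {
    return(tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE)))
  }
  dat <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  names(dat)[names(dat) == "T_th_pctMVC"] <- "T_th"
  tibble::as_tibble(dat)
}
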