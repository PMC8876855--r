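#' TEVC recording trace
#'
#' Container for a uniformly sampled time-current recording with its
#' acquisition protocol. Current follows the electrophysiology sign
#' convention: inward current is negative. The epoch table describes the
#' bath-solution/ligand history and must tile the recorded time span
#' without gaps or overlap.
#'
#' @param time_s numeric vector of sample times in seconds, strictly
#'   increasing with uniform step `1/sample_rate_hz`.
#' @param current_uA numeric vector of currents in microamperes, same length
#'   as `time_s`.
#' @param holding_mV holding potential in millivolts.
#' @param sample_rate_hz sampling rate in hertz.
#' @param epochs data frame with columns `start_s`, `end_s`, `solution`
#'   (character label, e.g. `"ND96"`, `"HK"`), `ligand_uM` (ligand
#'   concentration, micromolar, >= 0). Consecutive epochs must abut and the
#'   first/last must coincide with the trace extent.
#' @return An object of class `tevc_trace`: a list with the five fields
#'   above, validated.
#' @seealso [read_trace()], [write_trace()], [simulate_application_trace()]
#' @export
#' @examples
#' tr <- tevc_trace(seq(0, 0.02, by = 0.01), c(-0.1, -0.1, -0.1),
#'                  holding_mV = -90, sample_rate_hz = 100,
#'                  epochs = data.frame(start_s = 0, end_s = 0.02,
#'                                      solution = "HK", ligand_uM = 0))
tevc_trace <- function(time_s, current_uA, holding_mV, sample_rate_hz, epochs) {
  x <- structure(
    list(time_s = as.numeric(time_s), current_uA = as.numeric(current_uA),
         holding_mV = as.numeric(holding_mV),
         sample_rate_hz = as.numeric(sample_rate_hz),
         epochs = as.data.frame(epochs)),
    class = "tevc_trace")
  validate_trace(x)
}

# sampling-uniformity tolerance, seconds
.DT_TOL <- 1e-9
# epoch tiling tolerance, seconds
.EPOCH_TOL <- 1e-6

#' @rdname tevc_trace
#' @param x a `tevc_trace` object.
#' @export
validate_trace <- function(x) {
  stopifnot(inherits(x, "tevc_trace"))
  n <- length(x$time_s)
  if (n < 2L) stop("trace must contain at least 2 samples", call. = FALSE)
  if (length(x$current_uA) != n)
    stop("time and current vectors differ in length", call. = FALSE)
  check_number(x$holding_mV, "holding_mV")
  check_number(x$sample_rate_hz, "sample_rate_hz", positive = TRUE)
  dt <- diff(x$time_s)
  if (any(dt <= 0)) {
    i <- which(dt <= 0)[1L]
    stop(sprintf("time must be strictly increasing; violation at index %d (t = %g s)",
                 i + 1L, x$time_s[i + 1L]), call. = FALSE)
  }
  bad <- which(abs(dt - 1 / x$sample_rate_hz) > .DT_TOL)
  if (length(bad))
    stop(sprintf(
      "non-uniform sampling at index %d: step %.12g s, expected %.12g s",
      bad[1L] + 1L, dt[bad[1L]], 1 / x$sample_rate_hz), call. = FALSE)
  ep <- x$epochs
  req <- c("start_s", "end_s", "solution", "ligand_uM")
  if (!all(req %in% names(ep)))
    stop("epochs must have columns start_s, end_s, solution, ligand_uM",
         call. = FALSE)
  if (nrow(ep) < 1L) stop("epochs table is empty", call. = FALSE)
  if (any(ep$ligand_uM < 0))
    stop("ligand_uM must be >= 0 in every epoch", call. = FALSE)
  if (any(ep$end_s <= ep$start_s))
    stop("every epoch must have end_s > start_s", call. = FALSE)
  if (abs(ep$start_s[1L] - x$time_s[1L]) > .EPOCH_TOL ||
      abs(ep$end_s[nrow(ep)] - x$time_s[n]) > .EPOCH_TOL)
    stop("epochs must tile the full trace extent", call. = FALSE)
  if (nrow(ep) > 1L &&
      any(abs(ep$start_s[-1L] - ep$end_s[-nrow(ep)]) > .EPOCH_TOL))
    stop("epochs must abut without gaps or overlap", call. = FALSE)
  x
}

#' @export
print.tevc_trace <- function(x, ...) {
  n <- length(x$time_s)
  cat(sprintf("TEVC trace: %d samples, %.6g s at %g Hz, holding %g mV\n",
              n, x$time_s[n] - x$time_s[1L], x$sample_rate_hz, x$holding_mV))
  cat(sprintf("  current range [%.4g, %.4g] uA\n",
              min(x$current_uA), max(x$current_uA)))
  cat(sprintf("  %d epoch(s):\n", nrow(x$epochs)))
  for (i in seq_len(nrow(x$epochs)))
    cat(sprintf("    %8.6g-%-8.6g s  %-6s ligand %g uM\n",
                x$epochs$start_s[i], x$epochs$end_s[i],
                x$epochs$solution[i], x$epochs$ligand_uM[i]))
  invisible(x)
}

sidecar_path <- function(path)
  paste0(tools::file_path_sans_ext(path), ".meta.yaml")

#' Read and write TEVC traces
#'
#' Traces are stored as a two-column CSV with the mandatory unit-bearing
#' header `time_s,current_uA`, plus a structured-text (YAML) sidecar named
#' `<stem>.meta.yaml` that carries the holding potential, sampling rate and
#' epoch table. Files without the unit-naming header are rejected.
#' `write_trace()` emits a canonical form (15 significant digits) so that
#' write-after-read is byte-stable.
#'
#' @param path path to the trace CSV; the sidecar path is derived from it.
#' @return `read_trace()` returns a validated [tevc_trace()];
#'   `write_trace()` returns `path` invisibly.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("metadata sidecar not found: ", sc, call. = FALSE)
  dat <- read.csv(path, check.names = FALSE)
  if (!identical(names(dat), c("time_s", "current_uA")))
    stop("trace format error: header must be exactly 'time_s,current_uA' ",
         "(units are part of the contract); got: ",
         paste(names(dat), collapse = ","), call. = FALSE)
  meta <- yaml::read_yaml(sc)
  for (f in c("holding_mV", "sample_rate_hz", "epochs"))
    if (is.null(meta[[f]]))
      stop("sidecar is missing field: ", f, call. = FALSE)
  ep <- do.call(rbind, lapply(meta$epochs, function(e)
    data.frame(start_s = e$start_s, end_s = e$end_s,
               solution = e$solution, ligand_uM = e$ligand_uM)))
  tevc_trace(dat$time_s, dat$current_uA, meta$holding_mV,
             meta$sample_rate_hz, ep)
}

#' @rdname read_trace
#' @param trace a [tevc_trace()] object.
#' @export
write_trace <- function(trace, path) {
  validate_trace(trace)
  con <- file(path, open = "wb")  # binary: fixed "\n" on every platform
  on.exit(close(con))
  writeLines("time_s,current_uA", con)
  writeLines(sprintf("%.15g,%.15g", trace$time_s, trace$current_uA), con)
  ep <- trace$epochs
  meta <- list(
    holding_mV = as.numeric(trace$holding_mV),
    sample_rate_hz = as.numeric(trace$sample_rate_hz),
    epochs = lapply(seq_len(nrow(ep)), function(i)
      list(start_s = as.numeric(ep$start_s[i]), end_s = as.numeric(ep$end_s[i]),
           solution = as.character(ep$solution[i]),
           ligand_uM = as.numeric(ep$ligand_uM[i]))))
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Extract the samples falling inside an epoch
#'
#' @param trace a [tevc_trace()].
#' @param epoch epoch row index into `trace$epochs`.
#' @return list with `time_s` and `current_uA` for samples with
#'   `start_s <= t <= end_s`.
#' @keywords internal
epoch_samples <- function(trace, epoch) {
  ep <- trace$epochs[epoch, ]
  keep <- trace$time_s >= ep$start_s - .EPOCH_TOL &
    trace$time_s <= ep$end_s + .EPOCH_TOL
  list(time_s = trace$time_s[keep], current_uA = trace$current_uA[keep])
}
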