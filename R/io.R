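#' @name session_io
#' @title Flat-file session layout
#' @description Sessions are stored as a directory of plain-text files:
#'   `lfp.csv` / `respiration.csv` (columns `time_s,value`; `#`-prefixed
#'   header lines carry `fs`, `label`, `t0`), `immobility.csv`
#'   (`start_s,end_s`), `spikes/unit<k>.csv` (one spike time per line),
#'   `waveforms/unit<k>.csv` (waveform samples, `fs` in the header) and
#'   `truth.json` (the full ground-truth record). All numbers are written
#'   with 15 significant digits, so a round trip reproduces values to within
#'   text precision.
NULL

fmt_num <- function(x) sprintf("%.15g", x)

read_hash_header <- function(path) {
  lines <- readLines(path, n = 50L)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^=]+)=(.*)$", h))[[1L]]
    if (length(m) == 3L) kv[[trimws(m[2L])]] <- trimws(m[3L])
  }
  kv
}

#' Write / read a signal as CSV
#'
#' @param x a [prr_signal()].
#' @param path file path.
#' @return `read_signal_csv` returns a `prr_signal`; `write_signal_csv`
#'   returns `path` invisibly.
#' @export
write_signal_csv <- function(x, path) {
  con <- file(path, "w")
  writeLines(c(sprintf("# fs=%s", fmt_num(x$fs)),
               sprintf("# label=%s", x$label),
               sprintf("# t0=%s", fmt_num(x$t0)),
               "time_s,value"), con)
  close(con)
  t <- x$t0 + (seq_along(x$samples) - 1L) / x$fs
  data.table::fwrite(data.table::data.table(time_s = t, value = x$samples),
                     path, append = TRUE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  kv <- read_hash_header(path)
  d <- data.table::fread(path, skip = "time_s,value", header = TRUE)
  prr_signal(d$value, fs = as.numeric(kv$fs),
             label = if (is.null(kv$label)) "" else kv$label,
             t0 = if (is.null(kv$t0)) 0 else as.numeric(kv$t0))
}

#' Write / read an epoch set as CSV
#' @param epochs a [prr_epochs()].
#' @param path file path.
#' @return `read_epochs_csv` returns a `prr_epochs`.
#' @export
write_epochs_csv <- function(epochs, path) {
  con <- file(path, "w")
  writeLines("start_s,end_s", con)
  if (nrow(epochs))
    writeLines(paste(fmt_num(epochs$start_s), fmt_num(epochs$end_s), sep = ","),
               con)
  close(con)
  invisible(path)
}

#' @rdname write_epochs_csv
#' @export
read_epochs_csv <- function(path) {
  d <- utils::read.csv(path)
  prr_epochs(d$start_s, d$end_s)
}

#' Write a synthetic session to a directory of flat files
#'
#' @param session a `prr_session` from [generate_session()].
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "spikes"), showWarnings = FALSE)
  dir.create(file.path(dir, "waveforms"), showWarnings = FALSE)
  write_signal_csv(session$lfp, file.path(dir, "lfp.csv"))
  write_signal_csv(session$respiration, file.path(dir, "respiration.csv"))
  write_epochs_csv(session$immobility, file.path(dir, "immobility.csv"))
  for (tr in session$spike_trains) {
    sp <- file.path(dir, "spikes", sprintf("%s.csv", tr$unit_id))
    writeLines(c(sprintf("# unit_id=%s", tr$unit_id),
                 fmt_num(tr$spike_times_s)), sp)
    if (!is.null(tr$waveform)) {
      wf <- file.path(dir, "waveforms", sprintf("%s.csv", tr$unit_id))
      writeLines(c(sprintf("# fs=%s", fmt_num(tr$waveform_fs)),
                   fmt_num(tr$waveform)), wf)
    }
  }
  if (!is.null(session$truth)) {
    tr <- unclass(session$truth)
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}

#' Read a session from a directory of flat files
#'
#' @param dir directory written by [write_session()] (or hand-assembled in
#'   the same layout; `truth.json` is optional for real recordings).
#' @return a `prr_session`.
#' @export
read_session <- function(dir) {
  lfp <- read_signal_csv(file.path(dir, "lfp.csv"))
  resp_path <- file.path(dir, "respiration.csv")
  respiration <- if (file.exists(resp_path)) read_signal_csv(resp_path)
  else NULL
  imm_path <- file.path(dir, "immobility.csv")
  immobility <- if (file.exists(imm_path)) read_epochs_csv(imm_path)
  else prr_epochs(lfp$t0, lfp$t0 + signal_duration(lfp))
  spike_files <- sort(list.files(file.path(dir, "spikes"), full.names = TRUE))
  trains <- lapply(spike_files, function(f) {
    kv <- read_hash_header(f)
    ln <- readLines(f)
    tms <- as.numeric(grep("^#", ln, value = TRUE, invert = TRUE))
    tms <- tms[!is.na(tms)]
    uid <- if (is.null(kv$unit_id))
      sub("\\.csv$", "", basename(f)) else kv$unit_id
    wf_path <- file.path(dir, "waveforms", basename(f))
    wf <- NULL; wf_fs <- NA_real_
    if (file.exists(wf_path)) {
      wkv <- read_hash_header(wf_path)
      wln <- readLines(wf_path)
      wf <- as.numeric(grep("^#", wln, value = TRUE, invert = TRUE))
      wf <- wf[!is.na(wf)]
      wf_fs <- as.numeric(wkv$fs)
    }
    prr_spiketrain(tms, uid, wf, wf_fs)
  })
  truth_path <- file.path(dir, "truth.json")
  truth <- NULL
  if (file.exists(truth_path)) {
    tj <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    up <- tj$unit_params
    tj$unit_params <- NULL
    tj <- tj[intersect(names(tj), names(formals(ground_truth)))]
    truth <- do.call(ground_truth, tj)
    truth$unit_params <- up
  }
  structure(list(lfp = lfp, respiration = respiration,
                 immobility = immobility, spike_trains = trains,
                 truth = truth),
            class = "prr_session")
}
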