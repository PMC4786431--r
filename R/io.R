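#' Read and write spike trains as CSV
#'
#' Spike trains are exchanged as two-column CSV files with columns
#' `trial_id` and `spike_time_s`; a file may hold several trials.
#'
#' @param trains a [spike_train()] or list of them.
#' @param path file path.
#' @export
write_spike_train_csv <- function(trains, path) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  df <- do.call(rbind, lapply(trains, function(tr)
    data.frame(trial_id = rep(tr$trial_id, length(tr$times)),
               spike_time_s = tr$times)))
  if (is.null(df))
    df <- data.frame(trial_id = character(0), spike_time_s = numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_train_csv
#' @param protocol optional [stimulus_protocol()] attached to each train.
#' @return `read_spike_train_csv()`: a named list of [spike_train()]s.
#' @export
read_spike_train_csv <- function(path, protocol = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("trial_id", "spike_time_s") %in% names(df)))
  ids <- unique(df$trial_id)
  out <- lapply(ids, function(id)
    spike_train(sort(df$spike_time_s[df$trial_id == id]),
                protocol = protocol, trial_id = id))
  names(out) <- ids
  out
}

#' Read and write voltage traces as CSV
#'
#' Single-column CSV with the sampling metadata in commented header lines
#' (`# fs=10000`, `# t0=0`).
#'
#' @param trace a [voltage_trace()].
#' @param path file path.
#' @export
write_voltage_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "voltage_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs=%g", trace$fs), sprintf("# t0=%g", trace$t0),
               "voltage"), con)
  writeLines(format(trace$samples, digits = 12, trim = TRUE,
                    scientific = FALSE), con)
  invisible(path)
}

#' @rdname write_voltage_trace_csv
#' @return `read_voltage_trace_csv()`: a [voltage_trace()].
#' @export
read_voltage_trace_csv <- function(path) {
  hdr <- readLines(path, n = 10L)
  meta <- hdr[startsWith(hdr, "#")]
  get1 <- function(key, default) {
    m <- grep(paste0("^#\\s*", key, "="), meta, value = TRUE)
    if (length(m)) as.numeric(sub(paste0("^#\\s*", key, "="), "", m[1]))
    else default
  }
  fs <- get1("fs", NA)
  t0 <- get1("t0", 0)
  if (is.na(fs)) stop("missing `# fs=` header")
  df <- utils::read.csv(path, comment.char = "#")
  voltage_trace(df[[1]], fs = fs, t0 = t0)
}

#' Write and read a FRET stack pair as multipage TIFF plus JSON sidecar
#'
#' Each channel is written as one multipage 32-bit float TIFF (intensities
#' scaled to `[0, 1]` by a common factor recorded in the sidecar); frame
#' times, the stimulus window and any ground truth travel in
#' `<prefix>_meta.json`.
#'
#' @param pair an [image_stack_pair()].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return (invisibly) the paths written.
#' @export
write_fret_stack <- function(pair, dir, prefix = "stack") {
  stopifnot(inherits(pair, "image_stack_pair"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scale <- max(pair$cfp, pair$yfp, 1e-12)
  to_pages <- function(a) lapply(seq_len(dim(a)[3]), function(f) a[, , f] / scale)
  p_cfp <- file.path(dir, paste0(prefix, "_cfp.tif"))
  p_yfp <- file.path(dir, paste0(prefix, "_yfp.tif"))
  tiff::writeTIFF(to_pages(pair$cfp), p_cfp, bits.per.sample = 32L)
  tiff::writeTIFF(to_pages(pair$yfp), p_yfp, bits.per.sample = 32L)
  meta <- list(frame_times = pair$frame_times, scale = scale)
  if (!is.null(pair$protocol))
    meta$stim_window <- as.numeric(stim_window(pair$protocol))
  if (!is.null(pair$truth))
    meta$truth <- list(dr = pair$truth$dr,
                       mask = which(pair$truth$mask) - 1L,
                       mask_dim = dim(pair$truth$mask))
  p_meta <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(meta, p_meta, auto_unbox = TRUE, digits = NA)
  invisible(c(cfp = p_cfp, yfp = p_yfp, meta = p_meta))
}

#' @rdname write_fret_stack
#' @return `read_fret_stack()`: an [image_stack_pair()] (the protocol is
#'   restored as an IR epoch spanning the stored stimulus window).
#' @export
read_fret_stack <- function(dir, prefix = "stack") {
  read_one <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  }
  meta <- jsonlite::read_json(file.path(dir, paste0(prefix, "_meta.json")),
                              simplifyVector = TRUE)
  cfp <- read_one(file.path(dir, paste0(prefix, "_cfp.tif"))) * meta$scale
  yfp <- read_one(file.path(dir, paste0(prefix, "_yfp.tif"))) * meta$scale
  protocol <- NULL
  if (!is.null(meta$stim_window))
    protocol <- stimulus_protocol("IR", onset = meta$stim_window[1],
                                  duration = diff(meta$stim_window))
  truth <- NULL
  if (!is.null(meta$truth)) {
    mask <- array(FALSE, meta$truth$mask_dim)
    mask[meta$truth$mask + 1L] <- TRUE
    truth <- list(mask = mask, dr = meta$truth$dr)
  }
  image_stack_pair(cfp, yfp, meta$frame_times, protocol = protocol,
                   truth = truth)
}

#' Serialize calibration models to JSON
#'
#' @param model an [fit_arrhenius()] result.
#' @param path file path.
#' @export
write_arrhenius_json <- function(model, path) {
  stopifnot(inherits(model, "arrhenius_fit"))
  jsonlite::write_json(list(a = model$a, b = model$b,
                            fit_domain = model$fit_domain,
                            residual_sd = model$residual_sd, n = model$n),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_arrhenius_json
#' @export
read_arrhenius_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(a = m$a, b = m$b, fit_domain = m$fit_domain,
                 residual_sd = m$residual_sd, n = m$n, lm = NULL),
            class = "arrhenius_fit")
}
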