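# Dataset I/O: one CSV per recording (header xL,yL,zL,xR,yR,zR, one row per
# 30 Hz sample) plus a manifest CSV and an optional JSON sidecar recording
# seeds and generator parameters.  Readers tolerate LF/CRLF line endings and
# a UTF-8 BOM.

#' Write a dataset to disk
#'
#' @param recordings List of [accel_recording()] objects.
#' @param dir Output directory (created if missing).
#' @param info Optional named list (seeds, generator parameters) dumped to
#'   `dataset_info.json` alongside the data.
#' @return Path to the written `manifest.csv`, invisibly.
#' @export
write_dataset <- function(recordings, dir, info = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    stopifnot(inherits(rec, "accel_recording"))
    fname <- paste0(rec$recording_id, ".csv")
    data.table::fwrite(data.table::as.data.table(rec$samples),
                       file.path(dir, fname))
    rows[[i]] <- data.frame(recording_id = rec$recording_id,
                            user_id = rec$user_id,
                            trial_id = rec$trial_id,
                            n_samples = recording_length(rec),
                            file = fname,
                            stringsAsFactors = FALSE)
  }
  manifest <- file.path(dir, "manifest.csv")
  empty <- data.frame(recording_id = character(), user_id = integer(),
                      trial_id = integer(), n_samples = integer(),
                      file = character(), stringsAsFactors = FALSE)
  data.table::fwrite(if (length(rows)) do.call(rbind, rows) else empty,
                     manifest)
  if (!is.null(info)) {
    jsonlite::write_json(info, file.path(dir, "dataset_info.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' Round-trips values to better than 1e-9 and all metadata exactly.
#'
#' @param manifest Path to a `manifest.csv`.
#' @return List of [accel_recording()] objects in manifest order.
#' @export
read_dataset <- function(manifest) {
  if (!file.exists(manifest)) {
    stop(sprintf("manifest not found: %s", manifest), call. = FALSE)
  }
  man <- data.table::fread(manifest, encoding = "UTF-8")
  need <- c("recording_id", "user_id", "trial_id", "n_samples", "file")
  if (!all(need %in% names(man))) {
    stop(sprintf("malformed manifest %s: missing column(s) %s", manifest,
                 paste(setdiff(need, names(man)), collapse = ", ")),
         call. = FALSE)
  }
  dir <- dirname(manifest)
  lapply(seq_len(nrow(man)), function(i) {
    path <- file.path(dir, man$file[i])
    if (!file.exists(path)) {
      stop(sprintf("recording file missing: %s", path), call. = FALSE)
    }
    x <- data.table::fread(path, encoding = "UTF-8")
    if (ncol(x) != 6L) {
      stop(sprintf("%s: expected 6 channels, found %d", path, ncol(x)),
           call. = FALSE)
    }
    if (!identical(names(x), CHANNELS)) {
      stop(sprintf("%s: malformed header (want %s)", path,
                   paste(CHANNELS, collapse = ",")), call. = FALSE)
    }
    if (nrow(x) != man$n_samples[i]) {
      stop(sprintf("%s: %d rows but manifest says %d", path, nrow(x),
                   man$n_samples[i]), call. = FALSE)
    }
    accel_recording(as.matrix(x),
                    user_id = man$user_id[i],
                    trial_id = man$trial_id[i],
                    recording_id = man$recording_id[i])
  })
}
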