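#' Write a recording to a two-channel delimited-text file
#'
#' Plain CSV with header comment lines `# sampling_rate_hz=<fs>` and
#' `# channels=ecg,vibration`, then one row per sample.
#'
#' @param recording A [synthesize_recording()] result, or any list with
#'   `ecg`, `vibration`, `sampling_rate`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(recording, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sampling_rate_hz=%g", recording$sampling_rate),
               "# channels=ecg,vibration"), con)
  utils::write.table(
    data.frame(ecg = recording$ecg, vibration = recording$vibration),
    con, sep = ",", row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a two-channel recording written by [write_recording_csv()]
#'
#' @param path File path.
#' @return List with `ecg`, `vibration`, `sampling_rate`.
#' @export
read_recording_csv <- function(path) {
  hdr <- readLines(path, n = 10)
  fs_line <- grep("^# sampling_rate_hz=", hdr, value = TRUE)
  if (length(fs_line) != 1) stop("missing '# sampling_rate_hz=' header")
  fs <- as.numeric(sub("^# sampling_rate_hz=", "", fs_line))
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("ecg", "vibration") %in% names(df)))
    stop("expected 'ecg' and 'vibration' columns")
  list(ecg = df$ecg, vibration = df$vibration, sampling_rate = fs)
}

#' Write ground-truth annotations to CSV
#'
#' Long format: `cycle_index,event,sample_index`, where `sample_index` is
#' the 0-based offset from the cycle onset (the R-peak sample).
#'
#' @param recording A [synthesize_recording()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations_csv <- function(recording, path) {
  fs <- recording$sampling_rate
  rows <- do.call(rbind, lapply(recording$schedules, function(s)
    data.frame(cycle_index = s$cycle_index,
               event = names(s$events),
               sample_index = round(unname(s$events) * fs))))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an annotation CSV
#'
#' @param path File path of a [write_annotations_csv()]-format file.
#' @return data.frame with `cycle_index`, `event`, `sample_index`.
#' @export
read_annotations_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cycle_index", "event", "sample_index")
  if (!all(need %in% names(df)))
    stop("annotation file must have columns ", paste(need, collapse = ", "))
  df
}

#' Read a labeled dataset written by [write_dataset_csv()]
#'
#' @param stem Path stem used at write time.
#' @return A `"labeled_dataset"` (with whatever bands were exported).
#' @export
read_dataset_csv <- function(stem) {
  segs_df <- utils::read.csv(paste0(stem, "_segments.csv"))
  labs_df <- utils::read.csv(paste0(stem, "_labels.csv"))
  L <- ncol(segs_df) - 4L
  features <- setdiff(names(labs_df), c("segment", "split"))
  segments <- lapply(sort(unique(segs_df$segment)), function(i) {
    rows <- segs_df[segs_df$segment == i, , drop = FALSE]
    traces <- lapply(seq_len(nrow(rows)), function(r)
      as.numeric(rows[r, -(1:4)]))
    names(traces) <- rows$band
    structure(list(traces = traces, cycle_start = rows$cycle_start[1],
                   cycle_len = rows$cycle_len[1],
                   pad_len = max(0L, L - rows$cycle_len[1]),
                   truncated = rows$cycle_len[1] > L),
              class = "cycle_segment")
  })
  labels <- as.matrix(labs_df[, features, drop = FALSE])
  structure(list(segments = segments, labels = labels,
                 features = features, n_excluded = 0L,
                 split = as.character(labs_df$split),
                 sampling_rate = 2000),
            class = "labeled_dataset")
}

#' Save / load a trained localizer
#'
#' The checkpoint is a serialized weight file plus a small JSON sidecar
#' (`<path>.json`) recording the structure id, depth, target feature and
#' training configuration for provenance.
#'
#' @param model A trained `"cardiovib_localizer"`.
#' @param path Checkpoint path (e.g. `model_AO.rds`).
#' @return `path`, invisibly (for `save_localizer`); the model (for
#'   `load_localizer`).
#' @export
save_localizer <- function(model, path) {
  stopifnot(inherits(model, "cardiovib_localizer"))
  saveRDS(model, path)
  side <- sprintf(paste0(
    '{"feature": "%s", "structure_id": %s, "n_conv": %d, ',
    '"input_length": %d, "epochs_trained": %d, "label_scale": %g}'),
    model$feature,
    ifelse(is.null(model$structure$structure_id), "null",
           model$structure$structure_id),
    model$structure$n_conv, model$input_length, length(model$history),
    model$label_scale)
  writeLines(side, paste0(path, ".json"))
  invisible(path)
}

#' @rdname save_localizer
#' @export
load_localizer <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "cardiovib_localizer"))
  model
}

#' Export a labeled dataset to CSV files
#'
#' Writes `<stem>_segments.csv` (one row per segment per band, wide over
#' the fixed segment length) and `<stem>_labels.csv`. Text-only stand-in
#' for a columnar binary container.
#'
#' @param dataset A [attach_labels()] result.
#' @param stem Output path stem.
#' @param band Which band trace to export (default `"SCG"`); use
#'   `NULL` for all bands.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset_csv <- function(dataset, stem, band = "SCG") {
  bands <- if (is.null(band)) names(dataset$segments[[1]]$traces) else band
  seg_path <- paste0(stem, "_segments.csv")
  lab_path <- paste0(stem, "_labels.csv")
  rows <- do.call(rbind, lapply(seq_along(dataset$segments), function(i) {
    s <- dataset$segments[[i]]
    do.call(rbind, lapply(bands, function(b)
      cbind(data.frame(segment = i, band = b,
                       cycle_start = s$cycle_start,
                       cycle_len = s$cycle_len),
            as.data.frame(t(s$traces[[b]])))))
  }))
  utils::write.csv(rows, seg_path, row.names = FALSE, quote = FALSE)
  lab <- cbind(data.frame(segment = seq_along(dataset$segments),
                          split = dataset$split),
               as.data.frame(dataset$labels))
  utils::write.csv(lab, lab_path, row.names = FALSE, quote = FALSE)
  invisible(c(segments = seg_path, labels = lab_path))
}
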