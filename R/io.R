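## Tabular I/O: plain tab-delimited text with a one-line header.
## Numeric columns are written with 17 significant digits so that a
## write -> read round trip reproduces every double exactly.

.write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), "NA",
                         sprintf("%.17g", out[[j]]))
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE,
                     na = "NA", logical01 = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
}

.require_columns <- function(df, cols, what, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " '", path, "' is missing required column(s): ",
         paste(miss, collapse = ", "))
}

.fail_rows <- function(bad, what, path) {
  if (any(bad)) {
    rows <- which(bad)
    stop(what, " in '", path, "' at row",
         if (length(rows) > 1) "s" else "", " ",
         paste(utils::head(rows, 5), collapse = ", "),
         if (length(rows) > 5) sprintf(" (and %d more)",
                                       length(rows) - 5) else "")
  }
}

#' Read a spike table
#'
#' Columns: `cell_id`, `trial_id`, `epoch_id`, `spike_time_s`. Spike
#' times must be finite, non-negative, and sorted ascending within each
#' (cell, epoch, trial); violations raise an error naming the offending
#' row.
#'
#' @param path Path to a tab-delimited file.
#' @return `data.frame`.
#' @export
readSpikeTable <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("cell_id", "trial_id", "epoch_id",
                         "spike_time_s"), "spike table", path)
  if (!nrow(df)) return(df)
  .fail_rows(!is.finite(df$spike_time_s) | df$spike_time_s < 0,
             "invalid (negative or non-finite) spike time", path)
  key <- paste(df$cell_id, df$epoch_id, df$trial_id, sep = "\r")
  unsorted <- c(FALSE, diff(df$spike_time_s) < 0 &
                  key[-1] == key[-length(key)])
  .fail_rows(unsorted, "unsorted spike time", path)
  df
}

#' Read a stimulus-epoch table
#'
#' Columns: `epoch_id`, `protocol`, `onset_s`, `duration_s`,
#' `trial_duration_s`, `diameter_um`, `contrast`, `direction_deg`,
#' `speed_um_s`, `frequency_hz`. Range violations raise an error naming
#' the offending row.
#'
#' @param path Path to a tab-delimited file.
#' @return `data.frame`.
#' @export
readEpochTable <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("epoch_id", "protocol", "onset_s", "duration_s",
                         "trial_duration_s"), "epoch table", path)
  for (col in c("diameter_um", "contrast", "direction_deg", "speed_um_s",
                "frequency_hz"))
    if (!col %in% names(df)) df[[col]] <- NA_real_
  if (!nrow(df)) return(df)
  .fail_rows(!is.finite(df$onset_s) | df$onset_s < 0,
             "invalid epoch onset", path)
  .fail_rows(!is.finite(df$duration_s) | df$duration_s <= 0,
             "invalid epoch duration", path)
  .fail_rows(df$trial_duration_s < df$onset_s + df$duration_s,
             "trial shorter than stimulus epoch", path)
  .fail_rows(!is.na(df$direction_deg) &
               (df$direction_deg < 0 | df$direction_deg >= 360),
             "direction outside [0, 360)", path)
  .fail_rows(!is.na(df$diameter_um) & df$diameter_um <= 0,
             "non-positive stimulus diameter", path)
  df
}

#' Read a labeled-cell position table
#'
#' Columns: `retina_id`, `x_um`, `y_um`, and one or more logical
#' `label_*` columns (0/1 or TRUE/FALSE). Returns one
#' [LabeledCellMap-class] per retina.
#'
#' @param path Path to a tab-delimited file.
#' @return Named list of [LabeledCellMap-class] objects (one per
#'   `retina_id`).
#' @export
readPositionTable <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("retina_id", "x_um", "y_um"),
                   "position table", path)
  labs <- grep("^label_", names(df), value = TRUE)
  if (!length(labs))
    stop("position table '", path, "' has no 'label_*' column")
  if (nrow(df)) {
    .fail_rows(!is.finite(df$x_um) | !is.finite(df$y_um),
               "non-finite position", path)
    for (lb in labs) df[[lb]] <- as.logical(df[[lb]])
  } else {
    for (lb in labs) df[[lb]] <- logical(0)
  }
  ids <- if (nrow(df)) unique(df$retina_id) else character(0)
  maps <- lapply(ids, function(id) {
    sub <- df[df$retina_id == id,
              c("x_um", "y_um", labs), drop = FALSE]
    rownames(sub) <- NULL
    LabeledCellMap(sub, retinaId = as.character(id))
  })
  names(maps) <- ids
  maps
}

#' Write a labeled-cell position table
#'
#' @param maps A [LabeledCellMap-class] or a list of them.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writePositionTable <- function(maps, path) {
  if (is(maps, "LabeledCellMap")) maps <- list(maps)
  rows <- lapply(maps, function(m)
    cbind(retina_id = m@retinaId, m@cells))
  .write_tsv(do.call(rbind, rows), path)
}

#' Write a generic results table
#'
#' Tab-delimited with a one-line header; numeric columns keep full
#' precision. Optional provenance (seed, settings) is recorded in
#' `<path>.settings.tsv` as a key-value table.
#'
#' @param df `data.frame` to write.
#' @param path Output path.
#' @param settings Optional named list recorded alongside.
#' @return The path, invisibly.
#' @export
writeResultsTable <- function(df, path, settings = NULL) {
  .write_tsv(df, path)
  if (!is.null(settings)) {
    kv <- data.frame(key = names(settings),
                     value = vapply(settings, function(v)
                       paste(format(v, digits = 15), collapse = ","), ""))
    .write_tsv(kv, paste0(path, ".settings.tsv"))
  }
  invisible(path)
}

#' Write a simulated dataset to a directory
#'
#' Writes `spikes.tsv`, `epochs.tsv` and `cells.tsv` (the ground-truth
#' table) in the same formats the readers accept.
#'
#' @param dataset An [RgcDataset-class].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  stopifnot(is(dataset, "RgcDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_tsv(spikeTable(dataset), file.path(dir, "spikes.tsv"))
  .write_tsv(epochTable(dataset), file.path(dir, "epochs.tsv"))
  .write_tsv(cellTable(dataset), file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' Read a dataset directory written by [writeDataset()]
#'
#' @param dir Directory containing `spikes.tsv`, `epochs.tsv`,
#'   `cells.tsv`.
#' @return An [RgcDataset-class].
#' @export
readDataset <- function(dir) {
  spikes <- readSpikeTable(file.path(dir, "spikes.tsv"))
  epochs <- readEpochTable(file.path(dir, "epochs.tsv"))
  cells <- .read_tsv(file.path(dir, "cells.tsv"))
  new("RgcDataset", spikes = spikes, epochs = epochs, cells = cells,
      seed = NA_integer_)
}
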