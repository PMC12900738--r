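# Readers/writers: ratings and norm CSVs, epoch array + sidecar header,
# and the deterministic results report.

#' Read a ratings CSV
#'
#' Expected header: `participant_id,group,sex,age_group,stimulus_id,
#' v1,...,v12` (`age_group` optional, `group` is the cohort). Every row is
#' validated; malformed or out-of-range cells raise an error naming the row
#' and field.
#'
#' @param path Path to the CSV file.
#' @return A validated `rating_records` data.frame.
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stop("ratings file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cn in intersect(rating_item_cols(), names(df))) {
    if (is.character(df[[cn]])) {
      v <- suppressWarnings(as.numeric(df[[cn]]))
      bad <- which(is.na(v) & !is.na(df[[cn]]) & nzchar(trimws(df[[cn]])))
      if (length(bad)) {
        stop("row ", bad[1], ", field ", cn, ": '", df[[cn]][bad[1]],
             "' is not a number", call. = FALSE)
      }
      df[[cn]] <- v
    }
  }
  as_rating_records(df)
}

#' Write a ratings CSV
#'
#' Inverse of [read_ratings()]; round-trips records exactly (items printed
#' at full precision).
#'
#' @param records Rating records.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ratings <- function(records, path) {
  records <- as_rating_records(as.data.frame(records))
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a normative PAD profile CSV
#'
#' Header `label,PN,AN,DN`. The packaged default inventory is available via
#' [pad_norms()] and shipped as `extdata/pad_norms.csv`.
#'
#' @param path Path to the CSV file.
#' @return data.frame with columns `label`, `PN`, `AN`, `DN`.
#' @export
read_norms <- function(path) {
  if (!file.exists(path)) stop("norms file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "PN", "AN", "DN")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("norms file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$label)) stop("norm labels must be unique",
                                    call. = FALSE)
  if (anyNA(df[c("PN", "AN", "DN")])) {
    stop("norms file contains missing values", call. = FALSE)
  }
  df[need]
}

#' Write an epoch set as text (data CSV + JSON sidecar header)
#'
#' The voltage array is written as `<path>.csv` with columns `trial`,
#' `channel`, `s1..sN` (one row per trial x channel) and the metadata
#' (`fs`, `t0`, `channels`, `condition`) as `<path>.json`.
#'
#' @param epochs An `epoch_set`.
#' @param path Path prefix (no extension).
#' @return The prefix, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  nd <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(2L, 1L, 3L)), nd[1] * nd[2], nd[3])
  df <- data.table::data.table(
    trial = rep(seq_len(nd[1]), each = nd[2]),
    channel = rep(epochs$channels, nd[1]))
  df <- cbind(df, data.table::as.data.table(flat))
  data.table::setnames(df, c("trial", "channel", paste0("s", seq_len(nd[3]))))
  data.table::fwrite(df, paste0(path, ".csv"))
  jsonlite::write_json(list(fs = epochs$fs, t0 = epochs$t0,
                            channels = epochs$channels,
                            condition = epochs$condition),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an epoch set written by [write_epochs()]
#'
#' @param path Path prefix (no extension).
#' @return An `epoch_set`.
#' @export
read_epochs <- function(path) {
  csv <- paste0(path, ".csv"); hdr <- paste0(path, ".json")
  if (!file.exists(csv) || !file.exists(hdr)) {
    stop("epoch container incomplete: need ", csv, " and ", hdr,
         call. = FALSE)
  }
  meta <- jsonlite::read_json(hdr, simplifyVector = TRUE)
  df <- data.table::fread(csv)
  n_tr <- length(meta$condition)
  n_ch <- length(meta$channels)
  ns <- ncol(df) - 2L
  flat <- as.matrix(df[, -(1:2)])
  data <- aperm(array(flat, c(n_ch, n_tr, ns)), c(2L, 1L, 3L))
  epoch_set(data, fs = meta$fs, t0 = meta$t0, channels = meta$channels,
            condition = meta$condition)
}

fmt_num <- function(x, digits) {
  ifelse(is.na(x), "", sprintf(paste0("%.", digits, "f"), x))
}

#' Write a preference results report
#'
#' Writes the tidy results CSV at `path` with deterministic column order and
#' the package's rounding conventions (PAD means and proximities at 4
#' decimals); missing cells are rendered empty, never as 0. Re-running on
#' the same results produces a byte-identical file. An optional peak-table
#' set is written alongside as `<path minus extension>_peaks.csv`.
#'
#' @param results A `preference_result` data.frame.
#' @param path Output CSV path.
#' @param peaks Optional named list of `peak_table`s (per condition).
#' @return The path, invisibly.
#' @export
write_report <- function(results, path, peaks = NULL) {
  prox_cols <- grep("^prox_", names(results), value = TRUE)
  cols <- c("group", "stimulus_id", "n", "P", "A", "D", "octant",
            "zero_flag", prox_cols, "nearest_emotion", "nearest_distance",
            "tie_flag", "pleasure_band", "band_out_of_range")
  cols <- intersect(cols, names(results))
  lines <- paste(cols, collapse = ",")
  for (i in seq_len(nrow(results))) {
    row <- vapply(cols, function(cn) {
      v <- results[[cn]][i]
      if (is.numeric(v) && cn != "n") {
        fmt_num(v, 4L)
      } else if (is.logical(v)) {
        if (is.na(v)) "" else tolower(as.character(v))
      } else if (is.na(v)) "" else as.character(v)
    }, character(1))
    lines <- c(lines, paste(row, collapse = ","))
  }
  writeLines(lines, path)
  if (!is.null(peaks)) {
    ppath <- paste0(tools::file_path_sans_ext(path), "_peaks.csv")
    plines <- "condition,channel,amplitude_uv,latency_ms"
    for (cond in names(peaks)) {
      pt <- peaks[[cond]]
      plines <- c(plines, sprintf("%s,%s,%s,%s", cond, pt$channel,
                                  fmt_num(pt$amplitude, 3L),
                                  fmt_num(pt$latency_ms, 1L)))
    }
    writeLines(plines, ppath)
  }
  invisible(path)
}

#' Path to a packaged reference table
#'
#' Convenience accessor for the CSV tables shipped under `extdata`: the
#' normative profiles (`pad_norms.csv`), the published group-level PAD means
#' and emotion labels for eight painting styles (`painting_pad.csv`) and six
#' interior styles (`interior_pad.csv`), the corresponding proximity tables
#' (`painting_proximity.csv`, `interior_proximity.csv`; masked cells are
#' empty, and the interior table's Relaxed column is inconsistent with the
#' distance formula in the source and should not be used as an oracle), and
#' the pleasure-band assignments (`pleasure_bands.csv`).
#'
#' @param file File name under `extdata`; empty lists all files.
#' @return Full path(s) to the installed file(s).
#' @export
pad_extdata <- function(file = "") {
  out <- system.file("extdata", file, package = "padpref", mustWork = FALSE)
  if (!nzchar(out)) stop("no packaged file named '", file, "'", call. = FALSE)
  if (!nzchar(file)) out <- list.files(out, full.names = TRUE)
  out
}
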