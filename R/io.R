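#' Read a frame sequence from a delimited-text file
#'
#' Frame files are plain text: one block per frame, blocks separated by blank
#' lines, each block headed by a `t=<index>` line followed by `rows`
#' comma-separated numeric lines of `cols` values. Lines starting with `#`
#' are comments. The format is deliberately diffable and inspectable.
#'
#' @param path Path to a frame file.
#' @param grid The [grid_spec()] the file is expected to match.
#' @return A [frame_sequence()].
#' @seealso [write_frame_sequence()]
#' @export
read_frame_sequence <- function(path, grid) {
  if (!file.exists(path))
    stop(sprintf("read_frame_sequence: no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[!startsWith(lines, "#")]

  frames <- list()
  ts <- integer(0)
  i <- 1L
  n_lines <- length(lines)
  record <- 0L
  while (i <= n_lines) {
    if (lines[i] == "") { i <- i + 1L; next }
    record <- record + 1L
    if (!grepl("^t=\\d+$", lines[i]))
      stop(sprintf("read_frame_sequence: record %d: expected 't=<index>' header, got '%s'",
                   record, lines[i]), call. = FALSE)
    t_val <- as.integer(sub("^t=", "", lines[i]))
    i <- i + 1L
    if (i + grid$rows - 1L > n_lines ||
        any(lines[i:(i + grid$rows - 1L)] == ""))
      stop(sprintf("read_frame_sequence: record %d (t=%d): expected %d data rows",
                   record, t_val, grid$rows), call. = FALSE)
    mat <- matrix(NA_real_, grid$rows, grid$cols)
    for (r in seq_len(grid$rows)) {
      cells <- strsplit(lines[i + r - 1L], ",", fixed = TRUE)[[1L]]
      if (length(cells) != grid$cols)
        stop(sprintf("read_frame_sequence: record %d row %d: expected %d values, found %d",
                     record, r - 1L, grid$cols, length(cells)), call. = FALSE)
      vals <- suppressWarnings(as.numeric(cells))
      if (anyNA(vals)) {
        bad <- which(is.na(vals))[1L]
        stop(sprintf("read_frame_sequence: record %d: non-numeric cell at row %d, col %d: '%s'",
                     record, r - 1L, bad - 1L, cells[bad]), call. = FALSE)
      }
      mat[r, ] <- vals
    }
    frames[[record]] <- mat
    ts[record] <- t_val
    i <- i + grid$rows
  }
  if (record == 0L)
    stop(sprintf("read_frame_sequence: no frames in %s", path), call. = FALSE)
  ord <- order(ts)
  frame_sequence(frames[ord], grid = grid, t = ts[ord])
}

#' Write a frame sequence to a delimited-text file
#'
#' Inverse of [read_frame_sequence()]: the round trip reproduces the values
#' to full stored precision (17 significant digits).
#'
#' @param seq A [frame_sequence()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frame_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (length(seq$frames) < 1L)
    stop("write_frame_sequence: empty sequence", call. = FALSE)
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e)
                    stop(sprintf("write_frame_sequence: cannot open '%s': %s",
                                 path, conditionMessage(e)), call. = FALSE))
  on.exit(close(con))
  hdr <- sprintf("# somnopose frames: role=%s rows=%d cols=%d n=%d",
                 seq$grid$role, seq$grid$rows, seq$grid$cols,
                 length(seq$frames))
  blocks <- vapply(seq_along(seq$frames), function(i) {
    body <- apply(seq$frames[[i]], 1L, function(row)
      paste(formatC(row, format = "g", digits = 17), collapse = ","))
    paste(c(sprintf("t=%d", seq$t[i]), body), collapse = "\n")
  }, character(1L))
  writeLines(c(hdr, blocks), con = con, sep = "\n\n")
  invisible(path)
}

#' Write a labelled recording manifest
#'
#' The manifest is a CSV with one row per recording listing the recording
#' id, the six-class posture label, the weight class, and the relative paths
#' of the pressure and thermal frame files. Either path may be empty, in
#' which case the pipeline runs on the remaining stream and flags the result
#' as partial.
#'
#' @param manifest Data frame with columns `id`, `label`, `weight_class`,
#'   `pressure_file`, `thermal_file`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  need <- c("id", "label", "weight_class", "pressure_file", "thermal_file")
  if (!all(need %in% names(manifest)))
    stop(sprintf("write_manifest: manifest needs columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  utils::write.csv(manifest[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop(sprintf("read_manifest: no such file: %s", path), call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a recorded dataset from a manifest directory
#'
#' Loads the `manifest.csv` written by [generate_dataset()] (or assembled by
#' hand) and the frame files it lists. A recording with an empty
#' `pressure_file` or `thermal_file` field loads the remaining stream only.
#'
#' @param dir Directory containing `manifest.csv` and frame files.
#' @return A list with `recordings` (elements carrying `pressure`,
#'   `thermal` and `truth`) and `manifest`, compatible with
#'   [evaluate_dataset()].
#' @export
read_dataset <- function(dir) {
  manifest <- read_manifest(file.path(dir, "manifest.csv"))
  recordings <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    pressure <- if (nzchar(row$pressure_file))
      read_frame_sequence(file.path(dir, row$pressure_file), pressure_grid())
    thermal <- if (nzchar(row$thermal_file))
      read_frame_sequence(file.path(dir, row$thermal_file), thermal_grid())
    list(id = row$id, pressure = pressure, thermal = thermal,
         truth = list(label = row$label, weight_class = row$weight_class))
  })
  list(recordings = recordings, manifest = manifest)
}
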