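# Plain-text and binary I/O for the pipeline's tables and signals.

write_tsv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop_arg("input file not found: %s", path)
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write / read an atlas, overlap, or cohort table as TSV
#'
#' Thin wrappers around tab-separated text with a header row; columns are as
#' documented in [make_atlas()], [make_tumor_overlap()] and [cohort_spec()].
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `path` (write) or the data.frame (read), invisibly for writes.
#' @export
write_table_tsv <- function(x, path) write_tsv(x, path)

#' @rdname write_table_tsv
#' @export
read_atlas_tsv <- function(path) validate_atlas(read_tsv(path))

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) read_tsv(path)

#' Write an epoched signal as a binary array with JSON sidecar
#'
#' Little-endian float64, region-major order (regions x epochs x samples,
#' written in R's column-major array layout); the sidecar `<path>.json`
#' records the shape, layout, byte order, sampling rate, subject and group.
#'
#' @param signal epoched-signal object from [simulate_subject()].
#' @param path path of the `.bin` file to create.
#' @return `path`, invisibly.
#' @export
write_signal_bin <- function(signal, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(signal$data), con, size = 8L, endian = "little")
  sidecar <- list(shape = dim(signal$data),
                  layout = "column_major_regions_epochs_samples",
                  dtype = "float64", byte_order = "little",
                  sampling_rate = signal$sampling_rate,
                  subject_id = signal$subject_id, group = signal$group)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_signal_bin
#' @export
read_signal_bin <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n_vals <- prod(meta$shape)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = n_vals, size = 8L, endian = "little")
  structure(list(data = array(vals, dim = meta$shape),
                 sampling_rate = meta$sampling_rate,
                 subject_id = meta$subject_id, group = meta$group),
            class = "gliodev_signal")
}

#' Write / read an epoched signal as long-format CSV
#'
#' Columns `region_id` (0-based), `epoch` (1-based), `sample` (1-based),
#' `value`. Intended for small signals; the binary writer is preferred for
#' full-size data.
#'
#' @param signal epoched-signal object.
#' @param path CSV file path.
#' @param sampling_rate,subject_id,group metadata for the reader (stored in
#'   a header comment on write, required arguments on read only if absent).
#' @return `path` (write) / epoched-signal object (read).
#' @export
write_signal_csv <- function(signal, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  d <- signal$data
  idx <- expand.grid(region_id = 0:(dim(d)[1L] - 1L),
                     epoch = seq_len(dim(d)[2L]),
                     sample = seq_len(dim(d)[3L]))
  df <- cbind(idx, value = as.numeric(d))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate=%s subject_id=%s group=%s",
                     signal$sampling_rate, signal$subject_id, signal$group), con)
  write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec(
    "sampling_rate=([0-9.]+) subject_id=(\\S+) group=(\\S+)", header))[[1L]]
  if (length(m) != 4L) stop_arg("missing metadata header in %s", path)
  df <- read.table(path, sep = ",", header = TRUE, skip = 1L,
                   stringsAsFactors = FALSE)
  dims <- c(max(df$region_id) + 1L, max(df$epoch), max(df$sample))
  d <- array(NA_real_, dim = dims)
  d[cbind(df$region_id + 1L, df$epoch, df$sample)] <- df$value
  structure(list(data = d, sampling_rate = as.numeric(m[2L]),
                 subject_id = m[3L], group = m[4L]),
            class = "gliodev_signal")
}
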