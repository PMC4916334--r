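#' Write a recording to the raw CSV dialect
#'
#' Plain CSV with metadata comment lines (`# subject_id:`, `# fs:`,
#' `# start_time:`) followed by a header and rows `t,x,y,z`, where `t` is
#' seconds since recording start and acceleration is in g.  Numbers are
#' written at full precision so a read-back recording is sample-exact.
#' A `.gz` path writes gzip-compressed output.
#'
#' @param recording A [triax_recording()].
#' @param path Output path (`.csv` or `.csv.gz`).
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "triax_recording"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# subject_id: ", recording$subject_id),
               paste0("# fs: ", format(recording$fs, digits = 17)),
               paste0("# start_time: ",
                      format(recording$start_time,
                             "%Y-%m-%dT%H:%M:%OS6", tz = "UTC")),
               "t,x,y,z"), con)
  n <- length(recording$x)
  if (n > 0) {
    t <- (seq_len(n) - 1) / recording$fs
    writeLines(sprintf("%.17g,%.17g,%.17g,%.17g",
                       t, recording$x, recording$y, recording$z), con)
  }
  invisible(path)
}

#' Read a recording from the raw CSV dialect
#'
#' Parses the dialect written by [write_recording()]: metadata comment
#' lines, a header, and `t,x,y,z` rows (time in seconds, acceleration in
#' g).  The sampling rate comes from the `# fs:` line, from the `fs`
#' argument, or is inferred from the median timestamp step.  Timestamp
#' gaps larger than `gap_tol_s` are detected and attached as the `gaps`
#' attribute (a data.frame of intervals, in seconds since start).
#'
#' @param path Input path (`.csv` or `.csv.gz`).
#' @param fs Sampling rate override in Hz (`NULL`: use header/infer).
#' @param gap_tol_s Smallest timestamp gap reported, in seconds (default:
#'   two sample periods).
#' @return A `triax_recording` with attribute `gaps`.
#' @export
read_recording <- function(path, fs = NULL, gap_tol_s = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  meta <- character(0)
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) { close(con); stop("empty input file: ", path,
                                               call. = FALSE) }
    if (!startsWith(line, "#")) break
    meta <- c(meta, line)
  }
  close(con)
  header <- strsplit(line, ",")[[1]]
  if (!all(c("t", "x", "y", "z") %in% header) &&
      !all(c("timestamp", "x", "y", "z") %in% header))
    stop("unparseable header in ", path, ": need t,x,y,z columns",
         call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = NA, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty input file: ", path, call. = FALSE)
  tcol <- if ("t" %in% names(df)) "t" else "timestamp"
  tv <- df[[tcol]]
  if (is.character(tv))
    tv <- as.numeric(as.POSIXct(tv, tz = "UTC",
                                format = "%Y-%m-%dT%H:%M:%OS"))
  for (axis in c("x", "y", "z"))
    if (!is.numeric(df[[axis]]))
      df[[axis]] <- suppressWarnings(as.numeric(df[[axis]]))
  bad <- which(!is.finite(tv) | !is.finite(df$x) | !is.finite(df$y) |
                 !is.finite(df$z))
  if (length(bad))
    stop("malformed row at data line ", bad[1L], " of ", path,
         call. = FALSE)
  get_meta <- function(key) {
    m <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (length(m)) trimws(sub(paste0("^#\\s*", key, ":"), "", m[1L]))
    else NULL
  }
  fs_hdr <- get_meta("fs")
  fs_hdr <- if (is.null(fs_hdr)) NULL else as.numeric(fs_hdr)
  if (is.null(fs)) {
    fs <- if (!is.null(fs_hdr)) fs_hdr else if (nrow(df) > 1L)
      1 / stats::median(diff(tv)) else 60
  } else if (!is.null(fs_hdr) && abs(fs - fs_hdr) > 1e-6 * fs) {
    stop("fs mismatch: header says ", fs_hdr, ", caller says ", fs,
         call. = FALSE)
  }
  subject_id <- get_meta("subject_id")
  if (is.null(subject_id)) subject_id <- "S01"
  st <- get_meta("start_time")
  start_time <- if (!is.null(st))
    as.POSIXct(st, tz = "UTC", format = "%Y-%m-%dT%H:%M:%OS")
  else as.POSIXct(tv[1L], origin = "1970-01-01", tz = "UTC")
  rec <- triax_recording(df$x, df$y, df$z, fs = fs,
                         subject_id = subject_id, start_time = start_time)
  if (is.null(gap_tol_s)) gap_tol_s <- 2 / fs
  dts <- diff(tv)
  gi <- which(dts > gap_tol_s)
  attr(rec, "gaps") <- data.frame(from_s = tv[gi] - tv[1L],
                                  to_s = tv[gi + 1L] - tv[1L],
                                  gap_s = dts[gi])
  rec
}

#' Run manifest for reproducible pipeline runs
#'
#' Records the configuration snapshot, input file hashes, package version,
#' seeds and a timestamp; two runs with equal manifests (ignoring the
#' timestamp) produce equal outputs.
#'
#' @param config A [pipeline_config()].
#' @param inputs Character vector of input file paths (hashed when they
#'   exist).
#' @param seed Seed(s) used, if any.
#' @param path Output JSON path.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(config, inputs = character(0), seed = NULL,
                           path) {
  hashes <- if (length(inputs))
    as.list(tools::md5sum(inputs[file.exists(inputs)])) else list()
  manifest <- list(
    package = "walkcounts",
    version = as.character(utils::packageVersion("walkcounts")),
    config = unclass(config),
    input_md5 = hashes,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = I(17))
  invisible(manifest)
}
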