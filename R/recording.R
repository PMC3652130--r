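#' Triaxial finger-tapping recording
#'
#' Container for one accelerometer recording of the finger-tapping task:
#' time stamps in seconds and the three acceleration channels in g
#' (1 g = 9.81 m/s2). One recording corresponds to one hand of one subject;
#' `subject_id` plus `hand` is the observation key.
#'
#' Axis convention: the sensor sits on the index fingertip with the z-axis
#' perpendicular to the finger (reads ~1 g with fingers closed and the hand
#' horizontal) and the x-axis parallel to the finger, so that under
#' quasistatic conditions `x = sin(tilt)` g acts as an inclinometer.
#'
#' @param t numeric vector of time stamps, seconds, uniformly increasing.
#' @param ax,ay,az acceleration channels in g, same length as `t`.
#' @param fs sampling rate in Hz (default 167).
#' @param hand `"left"` or `"right"`.
#' @param subject_id opaque subject identifier.
#' @return An object of class `ft_recording`: a list with elements
#'   `t`, `ax`, `ay`, `az`, `fs`, `hand`, `subject_id`.
#' @export
ft_recording <- function(t, ax, ay, az, fs = 167, hand = "right",
                         subject_id = "anon") {
  n <- length(t)
  if (n < 2) stop(ft_error("recording must contain at least 2 samples",
                           "ft_format_error"))
  if (length(ax) != n || length(ay) != n || length(az) != n)
    stop(ft_error("channel lengths differ from time vector", "ft_format_error"))
  if (!all(is.finite(t)) || !all(is.finite(ax)) || !all(is.finite(ay)) ||
      !all(is.finite(az)))
    stop(ft_error("non-finite values in recording", "ft_format_error"))
  dt <- diff(t)
  if (any(dt <= 0)) stop(ft_error("time stamps not strictly increasing",
                                  "ft_format_error"))
  if (any(abs(dt - 1 / fs) >= 1 / (2 * fs)))
    stop(ft_error("time stamps inconsistent with sampling rate",
                  "ft_format_error"))
  if (max(abs(c(ax, ay, az))) > 10)
    stop(ft_error("acceleration outside the +/-10 g sensor range",
                  "ft_format_error"))
  hand <- match.arg(hand, c("left", "right"))
  structure(list(t = t, ax = ax, ay = ay, az = az, fs = fs, hand = hand,
                 subject_id = as.character(subject_id)),
            class = "ft_recording")
}

#' @export
print.ft_recording <- function(x, ...) {
  cat(sprintf("<ft_recording> %s/%s: %d samples @ %g Hz (%.2f s)\n",
              x$subject_id, x$hand, length(x$t), x$fs,
              length(x$t) / x$fs))
  invisible(x)
}

# classed condition helper; all package errors carry a subclass so callers
# (and the CLI) can distinguish validation failures from bugs
ft_error <- function(msg, class = "ft_error", call = sys.call(-1)) {
  structure(class = c(class, "ft_error", "error", "condition"),
            list(message = msg, call = call))
}

#' Read a finger-tapping recording from CSV
#'
#' The on-disk format is a plain CSV with columns
#' `time_s,ax_g,ay_g,az_g` preceded by metadata header lines of the form
#' `# key: value` carrying `fs_hz`, `hand` and `subject_id`.
#'
#' @param path file path.
#' @return An [ft_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop(ft_error(paste("no such file:", path),
                                        "ft_format_error"))
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop(ft_error("empty recording file", "ft_format_error"))
  meta_idx <- grep("^#", lines)
  meta <- list(fs_hz = 167, hand = "right", subject_id = "anon")
  for (ln in lines[meta_idx]) {
    m <- regmatches(ln, regexec("^#\\s*([a-z_]+)\\s*:\\s*(.+?)\\s*$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  body <- lines[setdiff(seq_along(lines), meta_idx)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop(ft_error("empty recording file", "ft_format_error"))
  header <- strsplit(body[1], ",")[[1]]
  required <- c("time_s", "ax_g", "ay_g", "az_g")
  missing <- setdiff(required, trimws(header))
  if (length(missing))
    stop(ft_error(paste("missing column(s):", paste(missing, collapse = ", ")),
                  "ft_format_error"))
  dat <- utils::read.csv(text = paste(body, collapse = "\n"),
                         colClasses = "character")
  num <- lapply(required, function(cn) suppressWarnings(as.numeric(dat[[cn]])))
  bad <- which(Reduce(`|`, lapply(num, is.na)))
  if (length(bad)) {
    # report 1-based line numbers in the original file
    body_line_of <- setdiff(seq_along(lines), meta_idx)[-1]
    stop(ft_error(paste("malformed rows at line(s):",
                        paste(body_line_of[bad], collapse = ", ")),
                  "ft_format_error"))
  }
  ft_recording(t = num[[1]], ax = num[[2]], ay = num[[3]], az = num[[4]],
               fs = as.numeric(meta$fs_hz), hand = meta$hand,
               subject_id = meta$subject_id)
}

#' Write a finger-tapping recording to CSV
#'
#' @param recording an [ft_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "ft_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs_hz: %.10g", recording$fs),
               sprintf("# hand: %s", recording$hand),
               sprintf("# subject_id: %s", recording$subject_id),
               "time_s,ax_g,ay_g,az_g"), con)
  rows <- sprintf("%.10f,%.10f,%.10f,%.10f", recording$t, recording$ax,
                  recording$ay, recording$az)
  writeLines(rows, con)
  invisible(path)
}
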