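#' Construct a session log
#'
#' A session log bundles everything one subject produced during a Go/NoGo
#' game session: the gaze track sampled by the eye tracker, the stimulus
#' events shown on screen, and the spacebar presses. Gaze and stimulus
#' coordinates are normalized to the unit square (pixel coordinates divided
#' by the window extent), and all times are milliseconds since session start.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param group Group label: one of `"typical"`, `"asd_no_adhd"`, `"asd_adhd"`.
#' @param sample_rate_hz Nominal gaze sampling rate in Hz (> 0).
#' @param gaze Data frame with columns `t` (ms), `x`, `y` (normalized, in
#'   `[0, 1]`); `t` must be non-decreasing.
#' @param stimuli Data frame with columns `trial_id`, `onset`, `offset` (ms),
#'   `location` (0-8, one of the nine fixed screen positions), `cx`, `cy`
#'   (normalized stimulus center) and `kind` (`"go"` or `"nogo"`); onsets must
#'   be strictly increasing. Appearance intervals are half-open
#'   `[onset, offset)`.
#' @param responses Data frame with column `t` (keypress times, ms); may have
#'   zero rows.
#'
#' @return An object of class `session_log`.
#' @seealso [read_session_log()], [write_session_log()],
#'   [validate_session_log()]
#' @export
#' @examples
#' s <- session_log(
#'   "s1", "typical", 144,
#'   gaze = data.frame(t = c(0, 7, 14), x = 0.5, y = 0.5),
#'   stimuli = data.frame(trial_id = 1L, onset = 0, offset = 700,
#'                        location = 4L, cx = 0.5, cy = 0.5, kind = "go"),
#'   responses = data.frame(t = 350)
#' )
#' s
session_log <- function(subject_id, group, sample_rate_hz, gaze, stimuli,
                        responses = data.frame(t = numeric())) {
  s <- structure(
    list(
      subject_id = as.character(subject_id),
      group = match.arg(group, c("typical", "asd_no_adhd", "asd_adhd")),
      sample_rate_hz = as.numeric(sample_rate_hz),
      gaze = tibble::as_tibble(gaze[, c("t", "x", "y")]),
      stimuli = tibble::as_tibble(
        stimuli[, c("trial_id", "onset", "offset", "location",
                    "cx", "cy", "kind")]
      ),
      responses = tibble::as_tibble(responses[, "t", drop = FALSE])
    ),
    class = "session_log"
  )
  s$stimuli$trial_id <- as.integer(s$stimuli$trial_id)
  s$stimuli$location <- as.integer(s$stimuli$location)
  validate_session_log(s, strict = TRUE)
}

#' Validate (and optionally repair) a session log
#'
#' Checks the session-log invariants: gaze timestamps non-decreasing,
#' coordinates inside the unit square, stimulus onsets strictly increasing,
#' `offset > onset`, a positive sampling rate, and a gaze track that spans the
#' stimulus events. In strict mode any violation is an error; otherwise
#' out-of-range coordinates (a common artifact of gaze estimates just past
#' the window border) are clipped into `[0, 1]` with a message.
#'
#' @param session A `session_log`.
#' @param strict If `TRUE`, fail on any violation; if `FALSE`, clip repairable
#'   coordinate violations and only fail on structural ones.
#' @return The (possibly repaired) `session_log`, invisibly classed as before.
#' @export
validate_session_log <- function(session, strict = TRUE) {
  g <- session$gaze
  st <- session$stimuli
  if (!is.numeric(session$sample_rate_hz) || session$sample_rate_hz <= 0) {
    abort("`sample_rate_hz` must be > 0.")
  }
  if (nrow(g) == 0) abort("session has an empty gaze track")
  if (is.unsorted(g$t)) {
    abort("gaze timestamps must be non-decreasing")
  }
  bad <- which(g$x < 0 | g$x > 1 | g$y < 0 | g$y > 1)
  if (length(bad) > 0) {
    if (strict) {
      abort(sprintf(
        "gaze coordinates outside [0, 1] at %d row(s) (first offending row: %d)",
        length(bad), bad[1]
      ))
    }
    inform(sprintf("clipping %d out-of-range gaze coordinate row(s)",
                   length(bad)))
    session$gaze$x <- pmin(pmax(g$x, 0), 1)
    session$gaze$y <- pmin(pmax(g$y, 0), 1)
  }
  if (nrow(st) > 0) {
    if (any(diff(st$onset) <= 0)) abort("stimulus onsets must be strictly increasing")
    if (any(st$offset <= st$onset)) abort("stimulus offsets must exceed onsets")
    if (!all(st$kind %in% c("go", "nogo"))) {
      abort("stimulus `kind` must be \"go\" or \"nogo\"")
    }
    if (!all(st$location %in% 0:8)) {
      abort("stimulus `location` must index one of the nine positions (0-8)")
    }
    if (max(g$t) < max(st$onset)) {
      abort("gaze track ends before the last stimulus onset")
    }
  }
  session
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf(
    "<session_log> subject %s (%s)\n  %d gaze samples @ %g Hz over %.1f s, %d stimuli (%d go), %d presses\n",
    x$subject_id, x$group, nrow(x$gaze), x$sample_rate_hz,
    diff(range(x$gaze$t)) / 1000, nrow(x$stimuli),
    sum(x$stimuli$kind == "go"), nrow(x$responses)
  ))
  invisible(x)
}

#' Read a session log from disk
#'
#' The on-disk dialect is a directory holding one JSON header
#' (`header.json`: subject, group, sampling rate) and three RFC-4180 CSV
#' tables: `gaze.csv` (`t,x,y`), `events.csv`
#' (`trial_id,onset,offset,location,cx,cy,kind`) and `presses.csv` (`t`). The
#' format is deliberately human-inspectable and diff-friendly.
#'
#' @param path Directory written by [write_session_log()].
#' @param strict Passed to [validate_session_log()]: strict parsing errors on
#'   any invariant violation; non-strict clips out-of-range coordinates.
#' @return A validated [session_log()].
#' @export
read_session_log <- function(path, strict = FALSE) {
  if (!dir.exists(path)) abort(sprintf("no session directory at '%s'", path))
  hdr_path <- file.path(path, "header.json")
  if (!file.exists(hdr_path)) abort("missing header.json")
  hdr <- jsonlite::read_json(hdr_path, simplifyVector = TRUE)
  for (f in c("subject_id", "group", "sample_rate_hz")) {
    if (is.null(hdr[[f]])) abort(sprintf("header.json is missing field '%s'", f))
  }
  gaze <- read_log_csv(file.path(path, "gaze.csv"), c(t = "d", x = "d", y = "d"))
  events <- read_log_csv(
    file.path(path, "events.csv"),
    c(trial_id = "i", onset = "d", offset = "d", location = "i",
      cx = "d", cy = "d", kind = "c")
  )
  presses <- read_log_csv(file.path(path, "presses.csv"), c(t = "d"))
  s <- structure(
    list(
      subject_id = as.character(hdr$subject_id),
      group = as.character(hdr$group),
      sample_rate_hz = as.numeric(hdr$sample_rate_hz),
      gaze = gaze, stimuli = events, responses = presses
    ),
    class = "session_log"
  )
  validate_session_log(s, strict = strict)
}

read_log_csv <- function(path, col_spec) {
  if (!file.exists(path)) abort(sprintf("missing table '%s'", basename(path)))
  types <- paste(unname(col_spec), collapse = "")
  tbl <- readr::read_csv(path, col_types = types, progress = FALSE)
  missing_cols <- setdiff(names(col_spec), names(tbl))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s is missing required column(s): %s", basename(path),
                  paste(missing_cols, collapse = ", ")))
  }
  tbl[, names(col_spec)]
}

#' Write a session log to disk
#'
#' Writes the directory dialect documented in [read_session_log()]. Writing
#' the same session twice produces byte-identical files.
#'
#' @param session A valid [session_log()].
#' @param path Target directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_session_log <- function(session, path) {
  session <- validate_session_log(session, strict = TRUE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) abort(sprintf("cannot create directory '%s'", path))
  hdr <- list(
    subject_id = session$subject_id,
    group = session$group,
    sample_rate_hz = session$sample_rate_hz
  )
  jsonlite::write_json(hdr, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(session$gaze, file.path(path, "gaze.csv"), progress = FALSE)
  readr::write_csv(session$stimuli, file.path(path, "events.csv"),
                   progress = FALSE)
  readr::write_csv(session$responses, file.path(path, "presses.csv"),
                   progress = FALSE)
  invisible(path)
}

#' Test two session logs for equality
#'
#' Field-by-field comparison with a numeric tolerance covering CSV
#' round-trip formatting.
#'
#' @param a,b `session_log` objects.
#' @param tol Numeric tolerance.
#' @return Logical scalar.
#' @export
session_logs_equal <- function(a, b, tol = 1e-9) {
  num_eq <- function(u, v) {
    length(u) == length(v) && (length(u) == 0 || max(abs(u - v)) <= tol)
  }
  identical(a$subject_id, b$subject_id) &&
    identical(a$group, b$group) &&
    num_eq(a$sample_rate_hz, b$sample_rate_hz) &&
    num_eq(a$gaze$t, b$gaze$t) && num_eq(a$gaze$x, b$gaze$x) &&
    num_eq(a$gaze$y, b$gaze$y) &&
    identical(as.integer(a$stimuli$trial_id), as.integer(b$stimuli$trial_id)) &&
    num_eq(a$stimuli$onset, b$stimuli$onset) &&
    num_eq(a$stimuli$offset, b$stimuli$offset) &&
    identical(as.integer(a$stimuli$location), as.integer(b$stimuli$location)) &&
    num_eq(a$stimuli$cx, b$stimuli$cx) && num_eq(a$stimuli$cy, b$stimuli$cy) &&
    identical(a$stimuli$kind, b$stimuli$kind) &&
    num_eq(a$responses$t, b$responses$t)
}
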