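#' Trial metadata
#'
#' Identifies one force-plate trial: which subject, which experimental
#' group, which balance task and which of the repeated measurements.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param group One of `"control"`, `"beginner"`, `"biathlete"`.
#' @param task One of `"QS"` (quiet standing), `"SP"` (shooting position),
#'   `"AT"` (aiming at target).
#' @param repeat_index Integer in 1..3; each task is recorded three times.
#' @return An object of class `trial_meta`.
#' @export
trial_meta <- function(subject_id, group, task, repeat_index = 1L) {
  group <- match.arg(group, c("control", "beginner", "biathlete"))
  task <- match.arg(task, c("QS", "SP", "AT"))
  repeat_index <- as.integer(repeat_index)
  if (!repeat_index %in% 1:3) {
    stop("repeat_index must be 1, 2 or 3", call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id), group = group,
         task = task, repeat_index = repeat_index),
    class = "trial_meta"
  )
}

#' @export
print.trial_meta <- function(x, ...) {
  cat(sprintf("<trial %s | %s | %s | repeat %d>\n",
              x$subject_id, x$group, x$task, x$repeat_index))
  invisible(x)
}

.channel_names <- c("fx", "fy", "fz", "mx", "my", "mz")

#' Force-plate recording
#'
#' Bundles the six synchronized force-plate channels: ground reaction
#' forces Fx, Fy, Fz (N) and moments Mx, My, Mz (N m), with the sampling
#' rate and optional trial metadata.
#'
#' @param fx,fy,fz Force channels in newtons.
#' @param mx,my,mz Moment channels in newton-metres.
#' @param fs Sampling rate in Hz.
#' @param meta Optional [trial_meta()].
#' @param duration Optional declared duration in seconds; when given, the
#'   channel length must equal `round(fs * duration)`.
#' @return An object of class `force_plate_recording` with a `channels`
#'   data frame (columns fx, fy, fz, mx, my, mz), `fs`, and `meta`.
#' @export
force_plate_recording <- function(fx, fy, fz, mx, my, mz, fs,
                                  meta = NULL, duration = NULL) {
  ch <- list(fx = fx, fy = fy, fz = fz, mx = mx, my = my, mz = mz)
  lens <- vapply(ch, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("all six channels must have identical length", call. = FALSE)
  }
  n <- lens[[1]]
  if (n < 2L) stop("channels must have length >= 2", call. = FALSE)
  for (nm in names(ch)) {
    if (!is.numeric(ch[[nm]]) || anyNA(ch[[nm]])) {
      stop(sprintf("channel %s must be numeric with no missing values", nm),
           call. = FALSE)
    }
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a positive sampling rate in Hz", call. = FALSE)
  }
  if (!is.null(duration) && n != round(fs * duration)) {
    stop(sprintf("channel length %d does not match fs * duration = %d",
                 n, round(fs * duration)), call. = FALSE)
  }
  if (!is.null(meta) && !inherits(meta, "trial_meta")) {
    stop("meta must be a trial_meta object", call. = FALSE)
  }
  structure(
    list(channels = as.data.frame(lapply(ch, as.numeric)),
         fs = as.numeric(fs), meta = meta),
    class = "force_plate_recording"
  )
}

#' @export
print.force_plate_recording <- function(x, ...) {
  cat(sprintf("<force-plate recording: %d samples @ %g Hz (%.1f s)>\n",
              nrow(x$channels), x$fs, nrow(x$channels) / x$fs))
  if (!is.null(x$meta)) print(x$meta)
  invisible(x)
}

#' Read a force-plate recording from the plain-text dialect
#'
#' The on-disk dialect is a CSV whose first line is a comment of the form
#' `# fs=<Hz>` followed by a header naming the six channel columns
#' (`fx,fy,fz,mx,my,mz`, any order). Columns are normalized to the
#' canonical order on read.
#'
#' @param path Path to the file.
#' @param meta Optional [trial_meta()] to attach.
#' @return A [force_plate_recording()].
#' @export
read_recording <- function(path, meta = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^#\\s*fs\\s*=\\s*([0-9.]+)\\s*$", first))[[1]]
  if (length(m) < 2L) {
    stop("config error: first line must declare the sampling rate as '# fs=<Hz>'",
         call. = FALSE)
  }
  fs <- as.numeric(m[2])
  dat <- utils::read.csv(path, skip = 1L, colClasses = "character",
                         check.names = FALSE)
  names(dat) <- tolower(trimws(names(dat)))
  for (nm in .channel_names) {
    if (!nm %in% names(dat)) {
      stop(sprintf("format error: channel %s missing", nm), call. = FALSE)
    }
  }
  num <- lapply(.channel_names, function(nm) {
    v <- suppressWarnings(as.numeric(dat[[nm]]))
    bad <- which(is.na(v) & !is.na(dat[[nm]]) | is.na(dat[[nm]]))
    if (length(bad)) {
      stop(sprintf("parse error: non-numeric value in channel %s at data row %d",
                   nm, bad[1]), call. = FALSE)
    }
    v
  })
  names(num) <- .channel_names
  force_plate_recording(num$fx, num$fy, num$fz, num$mx, num$my, num$mz,
                        fs = fs, meta = meta)
}

#' Write a force-plate recording in the plain-text dialect
#'
#' @param rec A [force_plate_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "force_plate_recording"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", rec$fs), con)
  utils::write.csv(rec$channels, con, row.names = FALSE)
  invisible(path)
}

#' Compute the center of pressure from forces and moments
#'
#' Uses the standard flat-plate convention with the plate origin at the
#' surface: `cop_x = -my / fz`, `cop_y = mx / fz` (metres). The vertical
#' moment-arm correction is omitted. By default the plate y axis is taken
#' as anterior-posterior (AP) and the x axis as medio-lateral (ML);
#' `axis_rotation_deg` rotates the plate axes counter-clockwise before the
#' mapping, for trials in which the stance is rotated on the plate.
#'
#' @param rec A [force_plate_recording()].
#' @param fz_min Minimum admissible |Fz| in newtons; samples at or below
#'   this threshold indicate an unloaded plate and raise an error
#'   (division by a near-zero vertical force is meaningless).
#' @param axis_rotation_deg Rotation (degrees) applied to the plate x/y
#'   COP coordinates before the AP/ML mapping.
#' @return An object of class `cop_trajectory` with numeric vectors `ap`
#'   and `ml` (metres), `fs`, and the trial metadata.
#' @export
compute_cop <- function(rec, fz_min = 10, axis_rotation_deg = 0) {
  stopifnot(inherits(rec, "force_plate_recording"))
  ch <- rec$channels
  low <- which(abs(ch$fz) <= fz_min)
  if (length(low)) {
    stop(sprintf(
      "unloaded plate: |fz| <= %g N at sample %d (and %d more)",
      fz_min, low[1], length(low) - 1L), call. = FALSE)
  }
  cop_x <- -ch$my / ch$fz
  cop_y <- ch$mx / ch$fz
  if (axis_rotation_deg != 0) {
    th <- axis_rotation_deg * pi / 180
    rx <- cos(th) * cop_x - sin(th) * cop_y
    ry <- sin(th) * cop_x + cos(th) * cop_y
    cop_x <- rx
    cop_y <- ry
  }
  if (!all(is.finite(cop_x)) || !all(is.finite(cop_y))) {
    stop("COP contains non-finite values", call. = FALSE)
  }
  structure(
    list(ap = cop_y, ml = cop_x, fs = rec$fs, meta = rec$meta),
    class = "cop_trajectory"
  )
}

#' @export
print.cop_trajectory <- function(x, ...) {
  cat(sprintf(
    "<COP trajectory: %d samples @ %g Hz | AP range %.1f mm | ML range %.1f mm>\n",
    length(x$ap), x$fs, 1000 * diff(range(x$ap)), 1000 * diff(range(x$ml))))
  invisible(x)
}

#' Write a COP trajectory as two-column CSV
#'
#' Columns `ap` and `ml` in metres, preceded by a `# fs=<Hz>` header line.
#'
#' @param cop A `cop_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cop_trajectory <- function(cop, path) {
  stopifnot(inherits(cop, "cop_trajectory"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", cop$fs), con)
  utils::write.csv(data.frame(ap = cop$ap, ml = cop$ml), con,
                   row.names = FALSE)
  invisible(path)
}
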