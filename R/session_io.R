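#' Read skeleton-tracking sessions from disk
#'
#' Reads one session file or every session file in a directory, in either
#' of the package's two dialects:
#'
#' * **CSV** (long form): a comment header of `# key: value` lines
#'   (`participant_id`, `exercise`, `label`, `frame_rate`) followed by the
#'   columns `frame,timestamp,joint,x,y,z`, one row per joint per frame.
#' * **JSON**: an object with the same metadata plus `timestamps` and a
#'   `positions` map joint -> `L x 3` coordinate array.
#'
#' Coordinates are meters in the sensor frame; no axis convention is
#' imposed at ingest (the body-attached frame downstream makes the
#' features view-invariant). Every session is passed through
#' [validate_session()].
#'
#' @param path A session file or a directory of session files
#'   (`manifest.csv` is ignored).
#' @param format `"auto"` (by extension), `"csv"`, or `"json"`.
#' @param missing_joint_policy,max_gap Passed to [validate_session()].
#' @return A list of `"session"` objects.
#' @export
read_sessions <- function(path, format = c("auto", "csv", "json"),
                          missing_joint_policy = "interpolate", max_gap = 3L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path)
  files <- if (dir.exists(path)) {
    f <- list.files(path, pattern = "\\.(csv|json)$", full.names = TRUE)
    f[!basename(f) %in% c("manifest.csv", "run_info.json")]
  } else path
  if (!length(files)) stop("no session files found under ", path)
  lapply(files, function(f) {
    fmt <- if (format == "auto") {
      if (grepl("\\.json$", f)) "json" else "csv"
    } else format
    tryCatch({
      s <- if (fmt == "json") read_session_json(f) else read_session_csv(f)
      validate_session(s, missing_joint_policy = missing_joint_policy,
                       max_gap = max_gap)
    },
    error = function(e) stop("while reading '", f, "': ",
                             conditionMessage(e), call. = FALSE))
  })
}

read_session_csv <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines)
  if (length(hdr) && any(diff(hdr) != 1L))
    stop("header comment lines must be contiguous at the top")
  meta <- list()
  for (h in lines[hdr]) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- trimws(m[3])
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  df <- read.csv(text = paste(body, collapse = "\n"), stringsAsFactors = FALSE)
  need <- c("frame", "timestamp", "joint", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  joints <- unique(df$joint)
  frames <- sort(unique(df$frame))
  L <- length(frames)
  arr <- array(NA_real_, dim = c(L, 3, length(joints)),
               dimnames = list(NULL, c("x", "y", "z"), joints))
  fi <- match(df$frame, frames)
  ji <- match(df$joint, joints)
  arr[cbind(fi, 1L, ji)] <- df$x
  arr[cbind(fi, 2L, ji)] <- df$y
  arr[cbind(fi, 3L, ji)] <- df$z
  ts <- df$timestamp[match(frames, df$frame)]
  session(participant_id = meta$participant_id %||% "unknown",
          exercise = meta$exercise %||% stop("header lacks 'exercise'"),
          label = meta$label %||% "unlabeled",
          frame_rate = as.numeric(meta$frame_rate %||% 15),
          timestamps = ts, joints = arr, validate = FALSE)
}

read_session_json <- function(file) {
  x <- jsonlite::fromJSON(file, simplifyVector = TRUE)
  pos <- x$positions
  joints <- names(pos)
  L <- length(x$timestamps)
  arr <- array(NA_real_, dim = c(L, 3, length(joints)),
               dimnames = list(NULL, c("x", "y", "z"), joints))
  for (j in joints) {
    m <- matrix(unlist(pos[[j]]), ncol = 3, byrow = FALSE)
    if (!all(dim(m) == c(L, 3))) m <- matrix(unlist(pos[[j]]), ncol = 3, byrow = TRUE)
    arr[, , j] <- m
  }
  session(participant_id = x$participant_id, exercise = x$exercise,
          label = x$label %||% "unlabeled", frame_rate = x$frame_rate,
          timestamps = x$timestamps, joints = arr, validate = FALSE)
}

#' Write sessions to disk
#'
#' Writes one file per session plus a `manifest.csv`
#' (file, participant, exercise, label, frame count, duration).
#' Coordinates and timestamps are serialized with 17 significant digits,
#' so `read_sessions(write_sessions(s))` round-trips every double exactly.
#'
#' @param sessions List of `"session"` objects.
#' @param path Output directory (created if absent).
#' @param format `"csv"` or `"json"`.
#' @return The manifest as a data frame, invisibly written to
#'   `manifest.csv` as well.
#' @export
write_sessions <- function(sessions, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!dir.exists(path) &&
      !dir.create(path, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", path)
  rows <- vector("list", length(sessions))
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    stopifnot(inherits(s, "session"))
    fn <- sprintf("%s_%s_%s_%04d.%s", s$participant_id, s$exercise,
                  s$label, i, format)
    fp <- file.path(path, fn)
    if (format == "csv") write_session_csv(s, fp) else write_session_json(s, fp)
    rows[[i]] <- data.frame(
      file = fn, participant_id = s$participant_id, exercise = s$exercise,
      label = s$label, n_frames = length(s$timestamps),
      duration_s = diff(range(s$timestamps)), stringsAsFactors = FALSE)
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(file = character(), participant_id = character(),
               exercise = character(), label = character(),
               n_frames = integer(), duration_s = numeric())
  write.csv(manifest, file.path(path, "manifest.csv"), row.names = FALSE)
  manifest
}

fmt17 <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

write_session_csv <- function(s, file) {
  jn <- dimnames(s$joints)[[3]]
  L <- length(s$timestamps)
  hdr <- c("# armrehab-session: v1",
           paste0("# participant_id: ", s$participant_id),
           paste0("# exercise: ", s$exercise),
           paste0("# label: ", s$label),
           paste0("# frame_rate: ", fmt17(s$frame_rate)))
  fi <- rep(seq_len(L) - 1L, each = length(jn))
  ji <- rep(seq_along(jn), times = L)
  body <- paste(fi,
                fmt17(rep(s$timestamps, each = length(jn))),
                jn[ji],
                fmt17(s$joints[cbind(fi + 1L, 1L, ji)]),
                fmt17(s$joints[cbind(fi + 1L, 2L, ji)]),
                fmt17(s$joints[cbind(fi + 1L, 3L, ji)]),
                sep = ",")
  writeLines(c(hdr, "frame,timestamp,joint,x,y,z", body), file)
}

write_session_json <- function(s, file) {
  jn <- dimnames(s$joints)[[3]]
  pos <- setNames(lapply(jn, function(j) unname(s$joints[, , j, drop = TRUE])), jn)
  obj <- list(format = "armrehab-session", version = 1L,
              participant_id = s$participant_id, exercise = s$exercise,
              label = s$label, frame_rate = s$frame_rate,
              timestamps = s$timestamps, positions = pos)
  # I(17) = 17 *significant* digits: doubles survive the round trip exactly
  jsonlite::write_json(obj, file, digits = I(17), auto_unbox = TRUE, na = "null")
}
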