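#' Write a track set to CSV
#'
#' Fixed dialect: comma separators, '.' decimal, UTF-8, LF line endings.
#' Provenance (generating parameters, taxis, seed, package version) is
#' emitted as '#'-prefixed comment lines before the header, which is
#' exactly \code{track_id,t,x,y,z}. Values are written with 17
#' significant digits so a write/read round trip is bit-exact. Times are
#' minutes, coordinates micrometres (a documented contract, not encoded
#' per file).
#'
#' @param tracks a \code{\link{trackset}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  tracks <- as_trackset(tracks)
  pr <- attr(tracks, "provenance")
  meta <- c("# beauchemin cell track table (units: min, um)",
            paste0("# package_version: ",
                   as.character(utils::packageVersion("beauchemin"))))
  if (length(pr)) {
    if (!is.null(pr$params))
      meta <- c(meta, sprintf("# t_pause: %.17g", pr$params$t_pause),
                sprintf("# t_free: %.17g", pr$params$t_free),
                sprintf("# v_free: %.17g", pr$params$v_free))
    if (!is.null(pr$taxis)) {
      meta <- c(meta, paste0("# taxis_mode: ", pr$taxis$mode),
                sprintf("# taxis_p: %.17g", pr$taxis$p),
                paste0("# taxis_b: ",
                       paste(sprintf("%.17g", pr$taxis$b), collapse = ",")))
    }
    for (key in c("n", "duration", "sample_dt", "phase", "seed")) {
      if (!is.null(pr[[key]]))
        meta <- c(meta, paste0("# ", key, ": ",
                               if (is.numeric(pr[[key]]))
                                 sprintf("%.17g", pr[[key]]) else pr[[key]]))
    }
  }
  rows <- if (nrow(tracks))
    sprintf("%s,%.17g,%.17g,%.17g,%.17g", as.character(tracks$track_id),
            tracks$t, tracks$x, tracks$y, tracks$z)
  else character(0)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(meta, "track_id,t,x,y,z", rows), con, sep = "\n",
             useBytes = TRUE)
  invisible(path)
}

#' Read a track set from CSV
#'
#' Reads the format written by \code{\link{write_tracks}}: optional
#' '#'-prefixed metadata lines (parsed back into provenance when
#' present), the exact header \code{track_id,t,x,y,z}, then one row per
#' observation. Times must be strictly increasing within each track;
#' violations are reported with the offending track id.
#'
#' @param path input file path.
#' @return A \code{\link{trackset}}.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty track file: ", path)
  is_meta <- startsWith(lines, "#")
  body_start <- which(!is_meta)[1]
  if (is.na(body_start)) stop("no header line in track file: ", path)
  if (trimws(lines[body_start]) != "track_id,t,x,y,z")
    stop("malformed header (expected 'track_id,t,x,y,z'): ",
         lines[body_start])

  prov <- list()
  meta <- sub("^#\\s*", "", lines[seq_len(body_start - 1)][
    is_meta[seq_len(body_start - 1)]])
  kv <- regmatches(meta, regexec("^([A-Za-z_]+):\\s*(.*)$", meta))
  for (m in kv) {
    if (length(m) == 3) prov[[m[2]]] <- m[3]
  }
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  provenance <- list()
  if (!is.null(prov$t_pause) && !is.null(prov$t_free) && !is.null(prov$v_free))
    provenance$params <- list(t_pause = num(prov$t_pause),
                              t_free = num(prov$t_free),
                              v_free = num(prov$v_free))
  if (!is.null(prov$taxis_mode))
    provenance$taxis <- list(mode = prov$taxis_mode,
                             p = if (is.null(prov$taxis_p)) 0 else
                               num(prov$taxis_p),
                             b = if (is.null(prov$taxis_b)) c(1, 0, 0) else
                               as.numeric(strsplit(prov$taxis_b, ",")[[1]]))
  for (key in c("n", "duration", "sample_dt", "seed"))
    if (!is.null(prov[[key]])) provenance[[key]] <- num(prov[[key]])
  if (!is.null(prov$phase)) provenance$phase <- prov$phase

  body <- lines[body_start:length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 1L) {
    df <- data.frame(track_id = character(0), t = numeric(0), x = numeric(0),
                     y = numeric(0), z = numeric(0))
  } else {
    df <- utils::read.csv(text = body, colClasses = "character")
    for (cl in c("t", "x", "y", "z")) {
      v <- suppressWarnings(as.numeric(df[[cl]]))
      if (any(is.na(v)))
        stop("non-numeric or missing values in column '", cl, "'")
      df[[cl]] <- v
    }
    bad <- vapply(split(df$t, df$track_id), function(t) any(diff(t) <= 0),
                  logical(1))
    if (any(bad))
      stop("times not strictly increasing in track(s): ",
           paste(names(bad)[bad], collapse = ", "))
  }
  aligned <- if (nrow(df)) {
    first <- !duplicated(df$track_id)
    all(df$t[first] == 0) && all(df$x[first] == 0) &&
      all(df$y[first] == 0) && all(df$z[first] == 0)
  } else FALSE
  sample_dt <- if (!is.null(provenance$sample_dt)) provenance$sample_dt
               else NA_real_
  trackset(df, aligned = aligned, sample_dt = sample_dt,
           provenance = provenance)
}

#' Write a statistic curve to CSV
#'
#' Plain CSV with columns \code{t, estimate, se, n} and a '#' metadata
#' line recording the statistic tag and coordinate view.
#'
#' @param curve a \code{\link{stat_curve}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_stat_curve <- function(curve, path) {
  stopifnot(is.data.frame(curve))
  meta <- sprintf("# beauchemin stat curve: %s on (%s)",
                  attr(curve, "statistic") %||% "unknown",
                  paste(attr(curve, "dims") %||% "xyz", collapse = ","))
  rows <- sprintf("%.17g,%.17g,%.17g,%d", curve$t, curve$estimate, curve$se,
                  as.integer(curve$n))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(meta, "t,estimate,se,n", rows), con, sep = "\n",
             useBytes = TRUE)
  invisible(path)
}

#' Read a statistic curve from CSV
#' @param path input file path (as written by
#'   \code{\link{write_stat_curve}}).
#' @return A \code{\link{stat_curve}}.
#' @export
read_stat_curve <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  statistic <- "unknown"; dims <- c("x", "y", "z")
  m <- regexec("stat curve: (\\S+) on \\(([^)]*)\\)", lines[1])
  mm <- regmatches(lines[1], m)[[1]]
  if (length(mm) == 3) {
    statistic <- mm[2]
    dims <- strsplit(mm[3], ",")[[1]]
  }
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")],
                        colClasses = "numeric")
  if (!all(c("t", "estimate") %in% names(df)))
    stop("malformed stat curve file: ", path)
  if (is.null(df$se)) df$se <- 0
  if (is.null(df$n)) df$n <- 1L
  stat_curve(df$t, df$estimate, df$se, df$n, statistic, dims)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
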