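#' Read a TAC table from a TSV file
#'
#' The TAC dialect is UTF-8 tab-separated text with a header row
#' `frame_start<TAB>frame_duration<TAB><region>...` (times in minutes,
#' frame bins half-open), one row per frame and one value column per
#' region. Lines starting with `#` are comments. Frames must be contiguous
#' with positive durations.
#'
#' @param path file path.
#' @return A list of [tac()] objects, one per region column, sharing a
#'   [frame_schedule()]; the schedule itself is attached as attribute
#'   `"schedule"`.
#' @export
read_tac <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lineno <- seq_along(lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]; lineno <- lineno[keep]
  if (length(lines) < 2L) stop("TAC file has no data rows: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 3L || header[1L] != "frame_start" ||
      header[2L] != "frame_duration")
    stop(sprintf("line %d: header must start with 'frame_start\tframe_duration' and name at least one region",
                 lineno[1L]))
  regions <- header[-(1:2)]
  rows <- lapply(seq_along(lines)[-1L], function(i) {
    cells <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(cells) != length(header))
      stop(sprintf("line %d: expected %d columns, found %d",
                   lineno[i], length(header), length(cells)))
    v <- suppressWarnings(as.numeric(cells))
    if (anyNA(v) || any(!is.finite(v)))
      stop(sprintf("line %d: non-numeric or non-finite cell", lineno[i]))
    v
  })
  m <- do.call(rbind, rows)
  sched <- tryCatch(frame_schedule(m[, 1L], m[, 2L]), error = function(e)
    stop("invalid frame grid in ", path, ": ", conditionMessage(e)))
  out <- lapply(seq_along(regions), function(j)
    tac(sched, m[, j + 2L], regions[j]))
  names(out) <- regions
  attr(out, "schedule") <- sched
  out
}

#' Write TACs to a TSV file
#'
#' Inverse of [read_tac()]; values are written with 12 significant digits
#' so a write/read round-trip is value-exact at that precision.
#'
#' @param tacs a single [tac()] or a (possibly named) list of TACs on a
#'   common schedule.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tac <- function(tacs, path) {
  if (inherits(tacs, "tac")) tacs <- list(tacs)
  stopifnot(length(tacs) >= 1L, all(vapply(tacs, inherits, TRUE, "tac")))
  sched <- tacs[[1L]]$schedule
  for (x in tacs)
    if (max(abs(mid_times(x$schedule) - mid_times(sched))) > 1e-9)
      stop("all TACs must share one schedule")
  labels <- names(tacs)
  if (is.null(labels) || any(!nzchar(labels)))
    labels <- vapply(tacs, function(x)
      if (nzchar(x$label)) x$label else "region", "")
  labels <- make.unique(labels, sep = "_")
  num <- function(v) sprintf("%.12g", v)
  rows <- c(paste(c("frame_start", "frame_duration", labels),
                  collapse = "\t"),
            vapply(seq_along(sched$start), function(i)
              paste(c(num(sched$start[i]), num(sched$duration[i]),
                      vapply(tacs, function(x) num(x$values[i]), "")),
                    collapse = "\t"), ""))
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}

#' Read sampled plasma data
#'
#' TSV with header `time_min<TAB>concentration`; `#` comments allowed.
#'
#' @param path file path.
#' @return Data frame with columns `time_min`, `concentration`.
#' @export
read_plasma_samples <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lineno <- seq_along(lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]; lineno <- lineno[keep]
  if (length(lines) < 2L) stop("plasma sample file has no data rows")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header[1:2], c("time_min", "concentration")))
    stop(sprintf("line %d: header must be 'time_min\tconcentration'",
                 lineno[1L]))
  rows <- lapply(seq_along(lines)[-1L], function(i) {
    v <- suppressWarnings(as.numeric(
      strsplit(lines[i], "\t", fixed = TRUE)[[1L]][1:2]))
    if (anyNA(v)) stop(sprintf("line %d: non-numeric cell", lineno[i]))
    v
  })
  m <- do.call(rbind, rows)
  data.frame(time_min = m[, 1L], concentration = m[, 2L])
}
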