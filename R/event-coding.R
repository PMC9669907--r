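new_cat_series <- function(codes, level, alphabet, recoded = FALSE) {
  structure(list(codes = as.integer(codes), level = level,
                 alphabet = as.integer(alphabet), recoded = recoded),
            class = "cat_series")
}

#' @export
print.cat_series <- function(x, ...) {
  cat(sprintf("<cat_series> level=%s recoded=%s n=%d\n", x$level,
              x$recoded, length(x$codes)))
  invisible(x)
}

#' Categorical event coding of speaking series
#'
#' Builds the three integer-coded series recurrence analysis operates on:
#' * `code_operator()`: 1 while the operator speaks, otherwise 0 (the other
#'   channels are ignored).
#' * `code_ground()`: ground player k speaking alone is coded k (1--3 in
#'   fixed speaker order), no ground player 0, two or more ground players 4;
#'   the operator channel is ignored.
#' * `code_team()`: operator alone 1, ground player k alone k+1 (2--4), any
#'   two or more of the four speakers 5, silence 0.
#'
#' @param activity a [generate_activity()]-style `speaker_activity` object.
#' @return A `cat_series` with the frame-wise integer codes.
#' @export
code_operator <- function(activity) {
  stopifnot(inherits(activity, "speaker_activity"))
  new_cat_series(activity$frames[, "operator"], "operator", 1L)
}

#' @rdname code_operator
#' @export
code_ground <- function(activity) {
  stopifnot(inherits(activity, "speaker_activity"))
  gp <- activity$frames[, c("gp1", "gp2", "gp3"), drop = FALSE]
  n_active <- rowSums(gp)
  codes <- integer(nrow(gp))
  single <- n_active == 1
  codes[single] <- max.col(gp[single, , drop = FALSE], ties.method = "first")
  codes[n_active >= 2] <- 4L
  new_cat_series(codes, "ground", 1:4)
}

#' @rdname code_operator
#' @export
code_team <- function(activity) {
  stopifnot(inherits(activity, "speaker_activity"))
  fr <- activity$frames
  n_active <- rowSums(fr)
  codes <- integer(nrow(fr))
  single <- n_active == 1
  codes[single] <- max.col(fr[single, , drop = FALSE], ties.method = "first")
  codes[n_active >= 2] <- 5L
  new_cat_series(codes, "team", 1:5)
}

#' Replace silence frames by unique non-recurring codes
#'
#' Every silence (code 0) frame is rewritten with its own code, disjoint from
#' the speaking alphabet, so silence can never contribute recurrent points.
#' The codes are a strictly decreasing negative counter: non-repetition is
#' all the recurrence analysis needs, and a deterministic assignment keeps
#' trials exactly reproducible.
#'
#' @param series a `cat_series` that has not been recoded yet.
#' @return The recoded `cat_series` (`recoded = TRUE`); frames that were
#'   speaking are untouched.
#' @export
recode_silence <- function(series) {
  stopifnot(inherits(series, "cat_series"))
  if (series$recoded) stop("recode_silence: series is already recoded")
  codes <- series$codes
  silent <- codes == 0L
  codes[silent] <- -seq_len(sum(silent))
  out <- new_cat_series(codes, series$level, series$alphabet, recoded = TRUE)
  out
}

#' Read/write coded series as CSV
#'
#' The file holds (frame_idx, code) rows preceded by a comment line naming
#' the coding level and recoded flag.
#'
#' @param series a `cat_series`; @param path file path.
#' @return The path (writer, invisibly) or the parsed `cat_series`.
#' @export
write_cat_series_csv <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# level=%s recoded=%s", series$level,
                     tolower(as.character(series$recoded))), con)
  write.csv(data.frame(frame_idx = seq_along(series$codes) - 1L,
                       code = series$codes),
            con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cat_series_csv
#' @export
read_cat_series_csv <- function(path) {
  header <- readLines(path, n = 1)
  m <- regmatches(header,
                  regexec("level=(\\w+) recoded=(\\w+)", header))[[1]]
  if (length(m) != 3) stop("read_cat_series_csv: malformed header in ", path)
  df <- read.csv(path, comment.char = "#")
  alphabet <- switch(m[2], operator = 1L, ground = 1:4, team = 1:5,
                     stop("read_cat_series_csv: unknown level '", m[2], "'"))
  new_cat_series(df$code, m[2], alphabet, recoded = m[3] == "true")
}
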