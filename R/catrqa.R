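#' Categorical recurrence plot
#'
#' The auto-recurrence plot of an integer-coded series: cell (i, j) is
#' recurrent iff the codes at frames i and j are exactly equal (categorical
#' recurrence -- embedding dimension 1, delay 1, no radius). The trivially
#' recurrent line of identity (i = j) is excluded by default. The point set
#' is materialised explicitly, which is meant for inspection and for modest
#' series lengths; [catrqa_trial()] computes the same statistics in O(n)
#' memory for long series.
#'
#' A series that still contains raw silence codes (0) is rejected: silence
#' must be recoded first ([recode_silence()]) or every silent stretch would
#' count as massively recurrent.
#'
#' @param series a `cat_series`.
#' @param loi_excluded drop the main diagonal (default `TRUE`).
#' @return An object of class `recurrence_plot`: `n`, integer matrix
#'   `points` with one (i, j) row per recurrent cell (both triangles), and
#'   `loi_excluded`.
#' @export
recurrence_plot <- function(series, loi_excluded = TRUE) {
  stopifnot(inherits(series, "cat_series"))
  codes <- series$codes
  n <- length(codes)
  if (n < 2) stop("recurrence_plot: need a series of length >= 2")
  if (!series$recoded && any(codes == 0L))
    stop("recurrence_plot: series contains silence codes (0); apply ",
         "recode_silence() first")
  eq <- outer(codes, codes, "==")
  if (loi_excluded) diag(eq) <- FALSE
  idx <- which(eq, arr.ind = TRUE)
  structure(list(n = n,
                 points = matrix(as.integer(idx), ncol = 2,
                                 dimnames = list(NULL, c("i", "j"))),
                 loi_excluded = loi_excluded),
            class = "recurrence_plot")
}

#' @export
print.recurrence_plot <- function(x, ...) {
  cat(sprintf("<recurrence_plot> n=%d, %d recurrent points (LOI %s)\n", x$n,
              nrow(x$points), if (x$loi_excluded) "excluded" else "included"))
  invisible(x)
}

#' Percent recurrence of a recurrence plot
#'
#' Share of off-diagonal plot cells that are recurrent:
#' `100 * n_recurrent / (n^2 - n)`.
#'
#' @param rp a [recurrence_plot()].
#' @return Percentage in `[0, 100]`.
#' @export
percent_recurrence <- function(rp) {
  stopifnot(inherits(rp, "recurrence_plot"))
  if (rp$n < 2) stop("percent_recurrence: need n >= 2")
  100 * nrow(rp$points) / (rp$n^2 - rp$n)
}

#' Percent determinism of a recurrence plot
#'
#' Share of recurrent points lying on diagonal line segments of at least
#' `min_line` points (excluding the line of identity): repeated sequences of
#' states rather than isolated repeats. Defined as 0 when the plot has no
#' recurrent points, so condition-level averages never drop trials.
#'
#' @param rp a [recurrence_plot()].
#' @param min_line minimum diagonal line length (>= 2).
#' @return Percentage in `[0, 100]`.
#' @export
percent_determinism <- function(rp, min_line = 2) {
  stopifnot(inherits(rp, "recurrence_plot"))
  if (min_line < 2) stop("percent_determinism: 'min_line' must be >= 2")
  pts <- rp$points
  if (nrow(pts) == 0) return(0)
  upper <- pts[pts[, 2] > pts[, 1], , drop = FALSE]
  det_pts <- 0L
  for (d in unique(upper[, 2] - upper[, 1])) {
    ii <- sort(upper[upper[, 2] - upper[, 1] == d, 1])
    # maximal consecutive runs of i along this diagonal
    lens <- integer(0)
    cur <- 1L
    if (length(ii) > 1) {
      for (k in 2:length(ii)) {
        if (ii[k] == ii[k - 1] + 1L) cur <- cur + 1L
        else { lens <- c(lens, cur); cur <- 1L }
      }
    }
    lens <- c(lens, cur)
    det_pts <- det_pts + sum(lens[lens >= min_line])
  }
  100 * (2 * det_pts) / nrow(pts)
}

#' Full categorical RQA statistics of a coded series
#'
#' Computes recurrent-point count, %REC, %DET and the diagonal line-length
#' histogram with an O(n^2)-time, O(n)-memory diagonal scan (the plot is
#' never materialised), suitable for full-trial series.
#'
#' @param series a recoded `cat_series` (or any integer vector free of
#'   silence zeros).
#' @param min_line minimum diagonal line length (>= 2).
#' @return An object of class `rqa_result`: `n`, `n_recurrent`, `pct_rec`,
#'   `pct_det`, `min_line`, and the histogram of maximal diagonal run
#'   lengths (`line_lengths`, `line_counts`; upper triangle).
#' @export
rqa_stats <- function(series, min_line = 2) {
  if (min_line < 2) stop("rqa_stats: 'min_line' must be >= 2")
  codes <- if (inherits(series, "cat_series")) {
    if (!series$recoded && any(series$codes == 0L))
      stop("rqa_stats: series contains silence codes (0); apply ",
           "recode_silence() first")
    series$codes
  } else as.integer(series)
  if (length(codes) < 2) stop("rqa_stats: need a series of length >= 2")
  res <- cpp_rqa(codes, as.integer(min_line))
  structure(c(res, list(min_line = as.integer(min_line))),
            class = "rqa_result")
}

#' @export
print.rqa_result <- function(x, ...) {
  cat(sprintf("<rqa_result> n=%d: %%REC=%.3f %%DET=%.3f (%.0f points)\n",
              x$n, x$pct_rec, x$pct_det, x$n_recurrent))
  invisible(x)
}

#' Categorical RQA of one trial's speaking series at a given level
#'
#' Composes the full per-trial path: event coding at the requested level,
#' silence recoding, and the recurrence statistics.
#'
#' @param activity a `speaker_activity`.
#' @param level `"operator"`, `"ground"` or `"team"`.
#' @param min_line minimum diagonal line length.
#' @return An `rqa_result` (see [rqa_stats()]) with a `level` field.
#' @export
catrqa_trial <- function(activity, level = c("team", "operator", "ground"),
                         min_line = 2) {
  level <- match.arg(level)
  coder <- switch(level, operator = code_operator, ground = code_ground,
                  team = code_team)
  res <- rqa_stats(recode_silence(coder(activity)), min_line = min_line)
  res$level <- level
  res
}

#' Tidy one-row summary of an RQA result
#'
#' @param result an `rqa_result`.
#' @param team_id,trial_id identifiers for the output row.
#' @return One-row data.frame (team_id, trial_id, level, pct_rec, pct_det,
#'   n, n_recurrent, min_line).
#' @export
rqa_row <- function(result, team_id = NA, trial_id = NA) {
  data.frame(team_id = team_id, trial_id = trial_id,
             level = if (is.null(result$level)) NA_character_ else
               result$level,
             pct_rec = result$pct_rec, pct_det = result$pct_det,
             n = result$n, n_recurrent = result$n_recurrent,
             min_line = result$min_line)
}
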