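# Independent oracles used across the suite. All deliberately brute-force /
# closed-form, never sharing code with the implementation they check.

# Double-loop recurrence oracle: materialise the full n x n plot, count
# recurrent cells, and read diagonal line lengths straight off the matrix.
oracle_rqa <- function(codes, min_line = 2) {
  n <- length(codes)
  rp <- outer(codes, codes, "==")
  diag(rp) <- FALSE
  n_rec <- sum(rp)
  det_pts <- 0L
  hist <- integer(0)
  for (d in seq_len(n - 1)) {
    vals <- rp[cbind(seq_len(n - d), seq_len(n - d) + d)]
    r <- rle(vals)
    lens <- r$lengths[r$values]
    hist <- c(hist, lens)
    det_pts <- det_pts + sum(lens[lens >= min_line])
  }
  list(n_recurrent = n_rec,
       pct_rec = 100 * n_rec / (n^2 - n),
       pct_det = if (n_rec == 0) 0 else 100 * 2 * det_pts / n_rec,
       line_lengths = sort(hist))
}

# Wrap a plain integer matrix as a speaker_activity for coding tests.
make_activity <- function(op, g1, g2, g3, frame_rate = 30) {
  speaker_activity(cbind(op, g1, g2, g3), frame_rate = frame_rate)
}

# Cell-mean / sums-of-squares RM-ANOVA oracle via stats::aov error strata.
oracle_rm_anova_aov <- function(tab) {
  d <- data.frame(A = factor(tab$target_number), B = factor(tab$visibility),
                  C = factor(tab$perturbation), S = factor(tab$team_id),
                  value = tab$value)
  fit <- stats::aov(value ~ A * B * C + Error(S / (A * B * C)), data = d)
  out <- c()
  for (st in summary(fit)) {
    df <- st[[1]]
    rn <- trimws(rownames(df))
    for (i in seq_len(nrow(df)))
      if ("F value" %in% colnames(df) && !is.na(df[i, "F value"]))
        out[rn[i]] <- df[i, "F value"]
  }
  out
}

aov_effect_name <- function(effect) {
  map <- c(target_number = "A", visibility = "B", perturbation = "C")
  paste(map[strsplit(effect, ":")[[1]]], collapse = ":")
}

# Random balanced 2x2x2 within-team table.
random_design_table <- function(n_teams, sd_team = 1, sd_noise = 1,
                                shift = NULL) {
  cells <- expand.grid(target_number = c(9L, 18L),
                       visibility = c("clear", "fog"),
                       perturbation = c("none", "late_spawn"),
                       stringsAsFactors = FALSE)
  tab <- do.call(rbind, lapply(seq_len(n_teams), function(t)
    cbind(team_id = t, cells)))
  tab$value <- rnorm(n_teams, sd = sd_team)[tab$team_id] +
    rnorm(nrow(tab), sd = sd_noise)
  if (!is.null(shift))
    tab$value <- tab$value + shift * (tab$visibility == "fog")
  tab
}

# Random convex polygon around a centre (angles sorted => simple, convex).
random_convex_polygon <- function(center, radius, n = 8) {
  th <- sort(runif(n, 0, 2 * pi))
  r <- radius * runif(n, 0.6, 1)
  list(x = center[1] + r * cos(th), y = center[2] + r * sin(th))
}

# Grid-rasterisation overlap oracle at cell size h (cell-centre sampling).
oracle_overlap_grid <- function(paths, h = 0.01) {
  xs <- range(unlist(lapply(paths, `[[`, "x")))
  ys <- range(unlist(lapply(paths, `[[`, "y")))
  gx <- seq(xs[1] + h / 2, xs[2], by = h)
  gy <- seq(ys[1] + h / 2, ys[2], by = h)
  gr <- expand.grid(x = gx, y = gy)
  ncov <- rowSums(vapply(paths, function(p)
    sp::point.in.polygon(gr$x, gr$y, p$x, p$y) > 0,
    logical(nrow(gr))))
  list(proportion = sum(ncov >= 2) / sum(ncov >= 1),
       overlap_area = sum(ncov >= 2) * h^2,
       total_area = sum(ncov >= 1) * h^2)
}
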