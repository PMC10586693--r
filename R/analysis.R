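#' Between-limb symmetry index
#'
#' `1 - (a_involved - a_uninvolved) / a_uninvolved`: equal peaks give 1, and
#' the index exceeds 1 when the involved (e.g., unweighted left) side's peak
#' is lower than the uninvolved side's. The clinically relevant threshold
#' associated with functional deficits is shipped as [SYMMETRY_THRESHOLD]
#' (1.15).
#'
#' @param a_involved Peak value on the involved side (activation, N·m, ...).
#' @param a_uninvolved Peak value on the uninvolved side (same units, != 0).
#' @return The unitless symmetry index (vectorized).
#' @export
symmetry_index <- function(a_involved, a_uninvolved) {
  if (any(a_uninvolved == 0)) stop("uninvolved peak must be non-zero")
  1 - (a_involved - a_uninvolved) / a_uninvolved
}

#' Detect stance intervals from vertical ground reaction force
#'
#' Intervals where the vertical GRF exceeds `threshold` (default 5% of
#' bodyweight) with hysteresis (release at 60% of the threshold) and a
#' 50-ms minimum duration.
#'
#' @param grf_vertical Vertical force series (N or %BW).
#' @param times Time stamps (s), uniform.
#' @param bodyweight Bodyweight in the units of `grf_vertical` (use 100 for
#'   %BW input).
#' @param threshold Onset threshold as a fraction of bodyweight.
#' @param min_duration Minimum stance duration (s).
#' @return Tibble with columns `start`, `end` (s); zero rows when no stance.
#' @export
detect_stance <- function(grf_vertical, times, bodyweight,
                          threshold = 0.05, min_duration = 0.05) {
  on_lvl <- threshold * bodyweight
  off_lvl <- 0.6 * on_lvl
  state <- FALSE
  flags <- logical(length(grf_vertical))
  for (i in seq_along(grf_vertical)) {
    state <- if (state) grf_vertical[i] > off_lvl else grf_vertical[i] > on_lvl
    flags[i] <- state
  }
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (times[ends] - times[starts]) >= min_duration
  tibble::tibble(start = times[starts[keep]], end = times[ends[keep]])
}

#' Peak of a signal within a portion of an interval
#'
#' @param signal Numeric series.
#' @param times Time stamps (s).
#' @param interval Length-2 numeric `(start, end)` within the signal span.
#' @param portion `"full"`, `"first_half"`, or `"second_half"`.
#' @return List with `value` and `time`; ties resolve to the earliest time.
#' @export
peak_in_window <- function(signal, times, interval,
                           portion = c("full", "first_half", "second_half")) {
  portion <- match.arg(portion)
  if (interval[1] < times[1] - 1e-9 ||
      interval[2] > times[length(times)] + 1e-9) {
    stop("interval lies outside the signal span")
  }
  mid <- mean(interval)
  rng <- switch(portion,
                full = interval,
                first_half = c(interval[1], mid),
                second_half = c(mid, interval[2]))
  ix <- which(times >= rng[1] - 1e-9 & times <= rng[2] + 1e-9)
  k <- ix[which.max(signal[ix])]
  list(value = signal[k], time = times[k])
}

#' Normalize forces and moments to bodyweight (and height)
#'
#' Forces are expressed in percent bodyweight (%BW) and moments in percent
#' bodyweight times height (%BW·ht), with g = 9.81 m/s^2.
#'
#' @param x Force (N) or moment (N·m), vectorized.
#' @param mass Subject mass (kg).
#' @param height Subject height (m); needed for moments.
#' @return Normalized values.
#' @export
normalize_force <- function(x, mass) 100 * x / (mass * GRAVITY)

#' @rdname normalize_force
#' @export
normalize_moment <- function(x, mass, height) {
  100 * x / (mass * GRAVITY * height)
}

#' EMG linear envelope
#'
#' Band-pass (30-500 Hz, 4th-order zero-lag Butterworth), rectify, low-pass
#' (6 Hz, 4th-order zero-lag), then divide by a supplied per-channel maximum
#' (e.g., from maximum voluntary activation trials).
#'
#' @param raw Raw EMG series (V).
#' @param fs Sampling rate (Hz); must exceed 1000 Hz for the 500-Hz band
#'   edge.
#' @param max_activation Normalization constant (same units as the rectified
#'   filtered signal); `NULL` skips normalization.
#' @return Envelope series (in \[0, 1\] when normalized and not exceeding
#'   the calibration maximum).
#' @export
emg_envelope <- function(raw, fs, max_activation = NULL) {
  if (fs <= 1000) stop("EMG sampling rate must exceed 1000 Hz")
  bp <- signal::butter(4, c(30, 500) / (fs / 2), type = "pass")
  x <- filtfilt_reflect(bp, raw)
  x <- abs(x)
  x <- apply_filtfilt(x, 6, fs, 4)
  if (!is.null(max_activation)) x <- x / max_activation
  x
}

filtfilt_reflect <- function(filt, x) {
  n <- length(x)
  npad <- min(n - 1, 3 * max(length(filt$a), length(filt$b)) * 10)
  pre <- 2 * x[1] - x[seq(npad + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - npad)]
  ext <- c(pre, x, post)
  fwd <- signal::filter(filt, ext)
  bwd <- rev(signal::filter(filt, rev(fwd)))
  bwd[seq(npad + 1, npad + n)]
}

#' Align two series and quantify waveform error
#'
#' Finds the integer-frame delay minimizing the mean (Euclidean) difference
#' between the series, subtracts the residual constant offset, then reports
#' MAE, RMSE, and MAE as percent of the reference range over the overlap.
#'
#' @param series_a Reference series: numeric vector or `frames x d` matrix.
#' @param series_b Series to align (same width).
#' @param max_delay Maximum delay searched (frames).
#' @return List: `delay` (frames; positive = `b` lags `a`), `offset`
#'   (per-column), `mae`, `rmse`, `mae_pct_range`.
#' @export
align_and_compare <- function(series_a, series_b, max_delay = 60) {
  A <- as.matrix(series_a); B <- as.matrix(series_b)
  stopifnot(ncol(A) == ncol(B))
  best <- NULL
  for (d in -max_delay:max_delay) {
    if (d >= 0) {
      ia <- seq_len(min(nrow(A) - d, nrow(B)))
      if (length(ia) < 2) next
      Aa <- A[ia + d, , drop = FALSE]; Bb <- B[ia, , drop = FALSE]
    } else {
      ib <- seq_len(min(nrow(B) + d, nrow(A)))
      if (length(ib) < 2) next
      Aa <- A[ib, , drop = FALSE]; Bb <- B[ib - d, , drop = FALSE]
    }
    md <- mean(sqrt(rowSums((Aa - Bb)^2)))
    if (is.null(best) || md < best$md) best <- list(d = d, md = md)
  }
  d <- best$d
  if (d >= 0) {
    ia <- seq_len(min(nrow(A) - d, nrow(B)))
    Aa <- A[ia + d, , drop = FALSE]; Bb <- B[ia, , drop = FALSE]
  } else {
    ib <- seq_len(min(nrow(B) + d, nrow(A)))
    Aa <- A[ib, , drop = FALSE]; Bb <- B[ib - d, , drop = FALSE]
  }
  offset <- colMeans(Bb - Aa)
  Bc <- sweep(Bb, 2, offset)
  err <- Bc - Aa
  mae <- mean(abs(err))
  rng <- mean(apply(Aa, 2, function(col) diff(range(col))))
  list(delay = d, offset = offset, mae = mae,
       rmse = sqrt(mean(err^2)),
       mae_pct_range = 100 * mae / rng)
}

#' ROC analysis with the Youden-optimal threshold
#'
#' AUC by the rank (pair-counting) statistic with tie correction; the
#' reported threshold maximizes the true positive rate minus the false
#' positive rate over the observed scores, and accuracy is evaluated there.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Logical or 0/1 class labels; both classes must be present.
#' @return A `classification_report`: `auc`, `threshold`, `accuracy`, `n`.
#' @export
roc_analysis <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("both classes must be present")
  pos <- scores[labels]; neg <- scores[!labels]
  rk <- rank(c(pos, neg))
  auc <- (sum(rk[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  cand <- sort(unique(scores))
  thr_c <- c(cand[1] - 1e-9, (cand[-1] + cand[-length(cand)]) / 2,
             cand[length(cand)] + 1e-9)
  stats <- vapply(thr_c, function(t) {
    tpr <- mean(pos > t); fpr <- mean(neg > t)
    c(j = tpr - fpr,
      acc = (sum(pos > t) + sum(neg <= t)) / length(scores))
  }, numeric(2))
  k <- which.max(stats["j", ])
  structure(list(auc = auc, threshold = thr_c[k],
                 accuracy = unname(stats["acc", k]), n = length(scores)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> AUC %.3f, accuracy %.1f%% at threshold %.3f (n = %d)\n",
              x$auc, 100 * x$accuracy, x$threshold, x$n))
  invisible(x)
}

#' @export
glance.classification_report <- function(x, ...) {
  tibble::tibble(auc = x$auc, threshold = x$threshold,
                 accuracy = x$accuracy, n = x$n)
}

#' Paired comparison with a normality gate
#'
#' Shapiro-Wilk on the paired differences decides the test: a two-sided
#' paired t test when p > .05, otherwise a two-sided Wilcoxon signed-rank
#' test. Effect size is Cohen's d_z (t branch) or the rank-biserial
#' correlation (Wilcoxon branch); post-hoc power is evaluated at the
#' observed effect size. All-zero differences are flagged degenerate and
#' return p = 1 by convention.
#'
#' @param x,y Paired samples (equal length, n >= 3).
#' @param alpha Significance level for the power computation.
#' @return A one-row tibble: test used, raw p, effect size, normality p,
#'   post-hoc power, n, and a `degenerate` flag.
#' @export
paired_comparison <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  d <- x - y
  n <- length(d)
  if (all(d == 0)) {
    return(tibble::tibble(test = "degenerate", p = 1, effect = 0,
                          normality_p = NA_real_, power = NA_real_,
                          n = n, degenerate = TRUE))
  }
  if (stats::sd(d) == 0) {
    # exactly constant non-zero differences: a sure effect
    return(tibble::tibble(test = "paired_t", p = 0, effect = Inf,
                          normality_p = NA_real_, power = 1,
                          n = n, degenerate = FALSE))
  }
  sw <- stats::shapiro.test(d)
  if (sw$p.value > 0.05) {
    tt <- stats::t.test(x, y, paired = TRUE)
    dz <- mean(d) / stats::sd(d)
    pw <- posthoc_power(dz, n, alpha, test = "t")
    tibble::tibble(test = "paired_t", p = tt$p.value, effect = dz,
                   normality_p = sw$p.value, power = pw, n = n,
                   degenerate = FALSE)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                              exact = FALSE))
    nz <- d[d != 0]
    rk <- rank(abs(nz))
    rpos <- sum(rk[nz > 0]); rtot <- sum(rk)
    rb <- 2 * rpos / rtot - 1           # rank-biserial correlation
    dz <- mean(d) / stats::sd(d)
    pw <- posthoc_power(dz, n, alpha, test = "wilcoxon")
    tibble::tibble(test = "wilcoxon", p = wt$p.value, effect = rb,
                   normality_p = sw$p.value, power = pw, n = n,
                   degenerate = FALSE)
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control with monotonicity enforcement,
#' capped at 1 (delegates to [stats::p.adjust()]).
#'
#' @param p Raw p-values.
#' @return Adjusted p-values (same order).
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")

#' Post-hoc power of a paired test
#'
#' Paired-t power via the noncentral t distribution; Wilcoxon signed-rank
#' power via the normal approximation with asymptotic relative efficiency
#' 3/pi (documented as approximate).
#'
#' @param effect_size Cohen's d_z (mean difference / SD of differences).
#' @param n Number of pairs.
#' @param alpha Two-sided significance level.
#' @param test `"t"` or `"wilcoxon"`.
#' @return Power in \[0, 1\].
#' @export
posthoc_power <- function(effect_size, n, alpha = 0.05,
                          test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  n_eff <- if (test == "wilcoxon") n * 3 / pi else n
  ncp <- abs(effect_size) * sqrt(n_eff)
  df <- n - 1
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tc, df, ncp = ncp) + 1 - stats::pt(tc, df, ncp = ncp)
}

#' Run a family of paired comparisons with FDR control
#'
#' @param data Data frame with one row per subject-measure pair.
#' @param measure,condition_a,condition_b Column names: the value column and
#'   the two paired condition columns.
#' @param by Optional grouping column naming each comparison.
#' @param alpha Significance level.
#' @return A `stat_report` tibble: one row per comparison with raw and
#'   BH-adjusted p-values, effect sizes, and post-hoc power.
#' @export
comparison_battery <- function(data, condition_a, condition_b, by = NULL,
                               alpha = 0.05) {
  groups <- if (is.null(by)) list(all = data) else split(data, data[[by]])
  rows <- purrr::imap(groups, function(g, nm) {
    out <- paired_comparison(g[[condition_a]], g[[condition_b]], alpha)
    out$comparison <- nm
    out
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- adjust_bh(out$p)
  out <- dplyr::relocate(out, "comparison")
  class(out) <- c("stat_report", class(out))
  out
}

#' @export
autoplot.stat_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$comparison,
                                   y = .data$p_adjusted)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.05, linetype = 2) +
    ggplot2::labs(y = "BH-adjusted p", x = NULL)
}
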