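#' Optical fluorescence trace container
#'
#' @param samples fluorescence values (a.u.).
#' @param fs sampling rate (samples/s), >= 100.
#' @param stim_rate field-stimulation rate (Hz).
#' @param cell_id,region,animal metadata.
#' @param polarity `"inverted"` if the dye deflects *downward* on
#'   depolarization (di-8-ANEPPS convention; flipped on analysis) or
#'   `"upright"`.
#' @param truth optional generator ground truth.
#' @return object of class `optical_trace`.
#' @export
optical_trace <- function(samples, fs, stim_rate, cell_id = NA,
                          region = NA, animal = NA,
                          polarity = c("inverted", "upright"),
                          truth = NULL) {
  polarity <- match.arg(polarity)
  if (fs < 100) stop("optical sampling rate must be >= 100 samples/s")
  duration <- length(samples) / fs
  if (duration * stim_rate < 10)
    stop("record too short: need >= 10 beats for averaging")
  structure(list(samples = as.numeric(samples), fs = fs,
                 stim_rate = stim_rate, duration = duration,
                 cell_id = cell_id, region = region, animal = animal,
                 polarity = polarity, truth = truth),
            class = "optical_trace")
}

# Analysis-side signal: "up" = depolarized regardless of dye polarity.
trace_signal <- function(trace) {
  if (trace$polarity == "inverted") -trace$samples else trace$samples
}

#' Segment an optical trace into beats
#'
#' Splits the record into fixed-length windows of one stimulation cycle,
#' each re-anchored on the detected upstroke (maximum dF/dt within the
#' expected stimulus epoch).  A trace whose upstrokes are not detectable
#' (flat record) is rejected.
#'
#' @param trace an [optical_trace()].
#' @param min_beats minimum number of usable beats (default 10).
#' @param pre_ms baseline window kept ahead of each upstroke (ms).
#' @return list of class `beat_list`: `beats` (list of numeric vectors,
#'   one cycle each, starting `pre_ms` before the upstroke), `upstroke_idx`
#'   (sample index of each detected upstroke in the full record), `fs`.
#'   On failure, `NULL` with a warning naming the reason.
#' @export
segment_beats <- function(trace, min_beats = 10L, pre_ms = 50) {
  v <- trace_signal(trace)
  fs <- trace$fs
  cyc <- round(fs / trace$stim_rate)
  n_epochs <- floor(trace$duration * trace$stim_rate)
  dv <- diff(v)
  if (mad(dv) <= .Machine$double.eps && max(abs(dv)) < 1e-12) {
    warning("trace rejected: flat signal, no upstrokes detectable")
    return(NULL)
  }
  pre <- round(pre_ms * fs / 1000)
  ups <- integer(0)
  for (k in seq_len(n_epochs)) {
    lo <- (k - 1L) * cyc + 1L
    hi <- min(k * cyc, length(dv))
    if (hi - lo < 3) next
    seg <- dv[lo:hi]
    # require a genuine upstroke: slope prominent over the epoch's noise
    if ((max(seg) - median(seg)) < 6 * (mad(seg) + 1e-12)) next
    ups <- c(ups, lo + which.max(seg))   # sample after the steepest rise
  }
  if (length(ups) < min_beats) {
    warning(sprintf(
      "trace rejected: %d upstrokes detected, need >= %d",
      length(ups), min_beats))
    return(NULL)
  }
  beats <- lapply(ups, function(u) {
    lo <- u - pre
    hi <- u + cyc - pre - 1L
    if (lo < 1 || hi > length(v)) return(NULL)
    v[lo:hi]
  })
  keep <- !vapply(beats, is.null, TRUE)
  structure(list(beats = beats[keep], upstroke_idx = ups[keep], fs = fs,
                 pre = pre),
            class = "beat_list")
}

#' Average the final beats of a segmented trace
#'
#' Pointwise mean of the last `n` aligned beats (the steady-state end of
#' the record), the population-imaging averaging rule.
#'
#' @param beats a `beat_list` from [segment_beats()], or a plain list of
#'   equal-length numeric vectors.
#' @param n number of final beats to average (default 10).
#' @return numeric mean beat.
#' @export
average_last_beats <- function(beats, n = 10L) {
  bl <- if (inherits(beats, "beat_list")) beats$beats else beats
  if (length(bl) < n) stop("fewer than n beats available")
  sel <- bl[(length(bl) - n + 1L):length(bl)]
  stopifnot(length(unique(lengths(sel))) == 1)
  Reduce(`+`, sel) / n
}

#' Action-potential duration at a repolarization fraction
#'
#' Normalizes a beat to \[0, 1\] using the pre-upstroke baseline (median of
#' the 50 ms before the upstroke) and the peak, then measures the time from
#' the upstroke (maximum dF/dt) to the first downward crossing of level
#' `1 - fraction`, with linear sub-sample interpolation.  APD90 therefore
#' is the time to reach 10% of the amplitude above baseline.
#'
#' @param beat numeric beat (one cycle, upstroke within).
#' @param fraction repolarization fraction: 0.25, 0.50 or 0.90.
#' @param fs sampling rate (samples/s).
#' @param max_chatter maximum tolerated number of crossings of the level
#'   (more indicates noise chatter; the beat is flagged unmeasurable).
#' @return list: `apd` (ms; `NA` if unmeasurable), `upstroke_time` (ms from
#'   beat start), `amplitude` (a.u.), `quality` (`"ok"` or a reason).
#' @examples
#' fs <- 1000
#' beat <- c(rep(0, 100), exp(-(0:600) / 100))  # tau = 100 ms
#' compute_apd(beat, 0.90, fs)$apd              # ~ 100 * log(10)
#' @export
compute_apd <- function(beat, fraction, fs, max_chatter = 3L) {
  stopifnot(fraction > 0, fraction < 1)
  dv <- diff(beat)
  up <- which.max(dv) + 1L                  # first sample after max rise
  pre <- max(1L, up - 1L - round(0.05 * fs)):(max(up - 1L, 1L))
  baseline <- median(beat[pre])
  peak_idx <- up - 1L + which.max(beat[up:length(beat)])
  amplitude <- beat[peak_idx] - baseline
  out <- list(apd = NA_real_, upstroke_time = (up - 1) * 1000 / fs,
              amplitude = amplitude, quality = "ok")
  if (amplitude <= 0) { out$quality <- "no upstroke"; return(out) }
  if (length(beat) - peak_idx < round(0.05 * fs)) {
    out$quality <- "too little post-peak signal"; return(out)
  }
  x <- (beat - baseline) / amplitude
  level <- 1 - fraction
  post <- x[peak_idx:length(x)]
  below <- post < level
  cross <- which(diff(below) == 1L)         # downward crossings
  if (length(cross) == 0) { out$quality <- "no crossing"; return(out) }
  if (length(cross) > max_chatter) {
    out$quality <- "crossing chatter"; return(out)
  }
  i <- cross[1]                              # bracket: post[i] >= level > post[i+1]
  fracstep <- (post[i] - level) / (post[i] - post[i + 1])
  t_cross <- (peak_idx - 1 + i - 1 + fracstep) * 1000 / fs
  out$apd <- t_cross - out$upstroke_time
  out
}

#' Measure APD25/50/90 for every cell of an optical population
#'
#' Full per-cell pipeline: polarity-corrected load, beat segmentation,
#' averaging of the last `n_avg` beats, APD at the three canonical
#' repolarization fractions.  Cells failing segmentation, with amplitude
#' SNR below `min_snr`, or with chatter at the APD90 level are excluded
#' and counted.
#'
#' @param pop an `optical_population` (from [gen_optical_population()]) or
#'   plain list of [optical_trace()] objects.
#' @param n_avg beats averaged (default 10).
#' @param min_snr minimum amplitude / residual-noise ratio.
#' @return object of class `apd_table`: data.frame with `cell`, `region`,
#'   `animal`, `apd25`, `apd50`, `apd90` (ms), `amplitude`, `accepted`;
#'   attribute `n_rejected` with per-reason counts.
#' @export
measure_apd <- function(pop, n_avg = 10L, min_snr = 3) {
  traces <- if (inherits(pop, "optical_population")) pop$traces else pop
  reasons <- character(0)
  rows <- lapply(traces, function(tr) {
    row <- data.frame(cell = tr$cell_id, region = tr$region,
                      animal = tr$animal, apd25 = NA_real_,
                      apd50 = NA_real_, apd90 = NA_real_,
                      amplitude = NA_real_, accepted = FALSE)
    seg <- withCallingHandlers(segment_beats(tr, min_beats = n_avg),
                               warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(seg)) { reasons <<- c(reasons, "segmentation"); return(row) }
    mb <- average_last_beats(seg, n = n_avg)
    a90 <- compute_apd(mb, 0.90, tr$fs)
    if (a90$quality != "ok") { reasons <<- c(reasons, a90$quality); return(row) }
    noise <- sd(diff(mb[seq_len(max(3, seg$pre - 2))])) / sqrt(2)
    if (is.finite(noise) && noise > 0 && a90$amplitude / noise < min_snr) {
      reasons <<- c(reasons, "low SNR"); return(row)
    }
    row$apd90 <- a90$apd
    row$apd50 <- compute_apd(mb, 0.50, tr$fs)$apd
    row$apd25 <- compute_apd(mb, 0.25, tr$fs)$apd
    row$amplitude <- a90$amplitude
    row$accepted <- !anyNA(row[c("apd25", "apd50", "apd90")])
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "n_rejected") <- table(reasons)
  class(out) <- c("apd_table", "data.frame")
  out
}

#' Population APD dispersion by animal and region
#'
#' Per (animal, region) mean, SD and n of a per-cell APD measurement plus
#' within-animal BZ-minus-remote differences — the intraregional
#' heterogeneity statistic of the cellular stage.
#'
#' @param measurements an `apd_table` (or any data.frame with `region`,
#'   `animal` and the `channel` column), accepted rows only are used when
#'   an `accepted` column is present.
#' @param channel column to summarize (default `"apd90"`).
#' @inheritParams regional_summary
#' @return a [regional_summary()].
#' @export
population_dispersion <- function(measurements, channel = "apd90",
                                  ref_region = "remote") {
  df <- as.data.frame(measurements)
  if ("accepted" %in% names(df)) df <- df[df$accepted, ]
  regional_summary(df[[channel]], df$region, df$animal,
                   ref_region = ref_region)
}

#' Cell-morphology dispersion by animal and region
#'
#' Same contract as [population_dispersion()] applied to cell width and
#' length separately.  Width/length pairs with `length < width` are
#' flagged (kept, with a warning) rather than rejected.
#'
#' @param cells data.frame with `width`, `length` (um), `region`, `animal`.
#' @inheritParams regional_summary
#' @return list with `width` and `length` [regional_summary()] objects.
#' @export
morphology_dispersion <- function(cells, ref_region = "remote") {
  stopifnot(all(c("width", "length", "region", "animal") %in% names(cells)))
  if (any(cells$width <= 0) || any(cells$length <= 0))
    stop("cell dimensions must be positive")
  n_flag <- sum(cells$length < cells$width)
  if (n_flag > 0)
    warning(sprintf("%d cells have length < width (kept, flagged)", n_flag))
  list(width = regional_summary(cells$width, cells$region, cells$animal,
                                ref_region = ref_region),
       length = regional_summary(cells$length, cells$region, cells$animal,
                                 ref_region = ref_region),
       n_flagged = n_flag)
}

#' Cross-scale per-animal correlation
#'
#' OLS of one per-animal scalar on another (e.g. cellular APD SD on in vivo
#' ARI local SD); shared implementation with
#' [inducibility_regression()].
#'
#' @param x,y per-animal scalars, matched by position; >= 3 values.
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
cross_scale_correlation <- function(x, y) ols_fit(x, y)
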