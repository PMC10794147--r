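#' Normalize a fluorescence trace
#'
#' Divides a trace by the maximum raw fluorescence of that fluorophore in
#' that sample, so the series lies in (0, 1] with maximum exactly 1. The
#' whole downstream pipeline is invariant to per-trace multiplicative
#' constants.
#'
#' @param trace numeric signal vector, or a data.frame with a \code{signal}
#'   column (a \code{norm} column is added).
#' @return normalized vector, or the data.frame with \code{norm} added.
#' @export
normalizeTrace <- function(trace) {
  if (is.data.frame(trace)) {
    trace$norm <- normalizeTrace(trace$signal)
    return(trace)
  }
  if (!length(trace) || all(trace == 0)) stop("all-zero or empty signal")
  trace / max(trace)
}

#' Time of 10 percent fluorescence quenching
#'
#' Finds the first time the normalized signal has decreased by
#' \code{threshold} (default 10 percent), used as a measure of the extent of
#' nucleation. The reference is the running maximum by default (robust to
#' upward drift before the drop; identical to the global maximum whenever
#' the maximum precedes the drop); \code{reference = "global"} uses the
#' global maximum. The crossing is linearly interpolated between samples.
#'
#' @param time numeric times (hours), strictly increasing.
#' @param signal raw or normalized signal values.
#' @param threshold fractional decrease defining quenching.
#' @param reference "running" or "global" maximum.
#' @param smooth odd width of an edge-preserving running-median filter
#'   applied before thresholding (1 = none); a no-op on monotone traces, it
#'   suppresses isolated noise spikes in both the signal and the reference.
#' @param confirm number of consecutive samples that must sit below the
#'   threshold for a crossing to count (guards against single-sample dips).
#' @return the quench time in hours, or \code{NA} if the signal never
#'   drops by \code{threshold}.
#' @examples
#' quenchTime(0:10, c(rep(1, 5), .97, .94, .91, .88, .85, .8))  # between 7 and 8
#' @export
quenchTime <- function(time, signal, threshold = 0.10,
                       reference = c("running", "global"),
                       smooth = 7, confirm = 2) {
  reference <- match.arg(reference)
  stopifnot(length(time) == length(signal), all(diff(time) > 0))
  s <- if (smooth > 1 && length(signal) > smooth)
    stats::runmed(signal, smooth, endrule = "keep") else signal
  ref <- if (reference == "running") cummax(s) else rep(max(s), length(s))
  level <- (1 - threshold) * ref
  below <- s <= level + 1e-12
  ## sustained crossing: `confirm` consecutive samples below the level
  ok <- below
  if (confirm > 1 && length(below) >= confirm) {
    for (j in seq_len(confirm - 1L))
      ok <- ok & c(below[-seq_len(j)], rep(TRUE, j))
  }
  i <- which(ok)[1L]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(time[1L])
  ## plateau refinement: the max of a noisy flat stretch overestimates the
  ## true level, biasing the crossing early. If the samples just before the
  ## provisional crossing still sit within half a threshold of the running
  ## max (a genuine plateau, not a slow decline or a rising drift), the
  ## plateau median is an unbiased level estimate; recompute against it.
  win <- s[max(1L, i - 11L):max(1L, i - 2L)]
  if (length(win) >= 5 && stats::median(win) > (1 - threshold / 2) * ref[i]) {
    lvl <- (1 - threshold) * stats::median(win)
    below2 <- s <= lvl + 1e-12
    ok2 <- below2
    if (confirm > 1 && length(below2) >= confirm) {
      for (j in seq_len(confirm - 1L))
        ok2 <- ok2 & c(below2[-seq_len(j)], rep(TRUE, j))
    }
    i2 <- which(ok2)[1L]
    if (!is.na(i2)) {
      i <- i2
      level <- rep(lvl, length(s))
    }
  }
  if (i == 1L) return(time[1L])
  ## interpolate the crossing of the signal with the threshold level at i
  s0 <- s[i - 1L]; s1 <- s[i]; l <- level[i]
  if (s0 <= l + 1e-12) return(time[i - 1L])
  frac <- (s0 - l) / (s0 - s1)
  time[i - 1L] + frac * (time[i] - time[i - 1L])
}

#' Growth time of a fluorophore label
#'
#' The duration between the point of 10 percent quenching and the end of
#' the growth segment of the experiment; defined as 0 when quenching never
#' reaches the threshold (or occurs at/after the growth end).
#'
#' @param quench quench time in hours (possibly \code{NA}), e.g. from
#'   \code{\link{quenchTime}}.
#' @param growthEnd end of the growth segment (hours).
#' @return growth time in hours (>= 0).
#' @examples
#' growthTime(30, 150)  # 120
#' growthTime(NA, 150)  # 0
#' @export
growthTime <- function(quench, growthEnd) {
  ifelse(is.na(quench), 0, pmax(0, growthEnd - quench))
}

#' Summarise quench traces into per-shape growth and selectivity
#'
#' Computes per-label quench and growth times, averages growth times over
#' each shape's labels (across samples, as in designs with four
#' shape-specific labels plus one label per shape in a combined sample),
#' and reports the on-target selectivity fraction and ternary coordinates
#' (per-shape fractions of total growth time).
#'
#' @param traces data.frame with columns \code{time_h, label, sample,
#'   signal} (long format).
#' @param design data.frame with columns \code{label, sample, shape}
#'   declaring which shape each label reports on.
#' @param growthEnd end of the growth segment (hours).
#' @param target on-target shape name (optional; selectivity is NA without
#'   it).
#' @param threshold quench threshold.
#' @param reference see \code{\link{quenchTime}}.
#' @return object of class \code{GrowthSummary}: list with \code{perLabel}
#'   (label, sample, shape, quench_h, growth_h), \code{perShape} (shape,
#'   meanGrowth_h), \code{fractions} (ternary coordinates, NA when total
#'   growth is zero), \code{selectivity}, \code{target}.
#' @export
summarizeTraces <- function(traces, design, growthEnd, target = NULL,
                            threshold = 0.10, reference = "running") {
  need <- c("time_h", "label", "sample", "signal")
  stopifnot(all(need %in% names(traces)),
            all(c("label", "sample", "shape") %in% names(design)))
  keys <- unique(traces[c("label", "sample")])
  per <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    tr <- traces[traces$label == keys$label[i] & traces$sample == keys$sample[i], ]
    tr <- tr[order(tr$time_h), ]
    di <- design[design$label == keys$label[i] & design$sample == keys$sample[i], ]
    if (!nrow(di))
      stop(sprintf("label '%s' sample '%s' has no declared shape",
                   keys$label[i], keys$sample[i]))
    qt <- quenchTime(tr$time_h, normalizeTrace(tr$signal),
                     threshold = threshold, reference = reference)
    data.frame(label = keys$label[i], sample = keys$sample[i],
               shape = di$shape[1L], quench_h = qt,
               growth_h = growthTime(qt, growthEnd),
               stringsAsFactors = FALSE)
  }))
  perShape <- stats::aggregate(growth_h ~ shape, data = per, FUN = mean)
  names(perShape)[2L] <- "meanGrowth_h"
  tot <- sum(perShape$meanGrowth_h)
  fractions <- if (tot > 0) stats::setNames(perShape$meanGrowth_h / tot,
                                            perShape$shape)
               else stats::setNames(rep(NA_real_, nrow(perShape)),
                                    perShape$shape)
  selectivity <- if (!is.null(target) && tot > 0) fractions[[target]]
                 else NA_real_
  structure(list(perLabel = per, perShape = perShape, fractions = fractions,
                 selectivity = selectivity, target = target),
            class = "GrowthSummary")
}

#' @export
print.GrowthSummary <- function(x, ...) {
  cat("GrowthSummary:\n")
  print(x$perShape)
  if (!is.null(x$target))
    cat(sprintf("  selectivity (%s): %s\n", x$target,
                if (is.na(x$selectivity)) "undefined"
                else sprintf("%.3f", x$selectivity)))
  invisible(x)
}

#' Generate synthetic quench traces
#'
#' Emulates qPCR fluorescence quench curves: each label follows a sigmoidal
#' quench (depth and width configurable) placed so that the 10 percent
#' quench time equals the scheduled ground truth, with optional linear
#' drift and multiplicative log-normal noise. Ground truth is stored in the
#' \code{schedule} attribute for recovery tests.
#'
#' @param design data.frame with columns \code{label, sample, shape}.
#' @param schedule numeric vector of true quench times (hours), one per
#'   design row; \code{NA} for labels that never quench.
#' @param duration_h trace length in hours.
#' @param interval_h sampling interval (12- and 30-minute readings are
#'   0.2 and 0.5).
#' @param depth total fractional quench depth of the sigmoid.
#' @param width_h sigmoid width parameter in hours.
#' @param drift linear drift per hour applied multiplicatively.
#' @param noise standard deviation of multiplicative log-normal noise.
#' @param amplitude raw fluorescence scale (arbitrary units).
#' @param seed optional integer seed.
#' @return data.frame with columns \code{time_h, label, sample, signal},
#'   with the ground-truth schedule attached as attribute
#'   \code{"schedule"}.
#' @export
synthTraces <- function(design, schedule, duration_h = 150,
                        interval_h = 0.5, depth = 0.6, width_h = 1,
                        drift = 0, noise = 0, amplitude = 2000,
                        seed = NULL) {
  stopifnot(nrow(design) == length(schedule), depth > 0.1, depth < 1)
  tt <- seq(0, duration_h, by = interval_h)
  withSeed(seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
      tq <- schedule[i]
      base <- rep(1, length(tt))
      if (!is.na(tq)) {
        ## place the sigmoid so the 10% crossing sits exactly at tq
        t0 <- tq - width_h * stats::qlogis(0.1 / depth)
        base <- 1 - depth * stats::plogis((tt - t0) / width_h)
      }
      s <- base * (1 + drift * tt)
      if (noise > 0) s <- s * exp(stats::rnorm(length(tt), 0, noise))
      data.frame(time_h = tt, label = design$label[i],
                 sample = design$sample[i], signal = amplitude * s,
                 stringsAsFactors = FALSE)
    }))
    attr(out, "schedule") <- stats::setNames(schedule,
                                             paste(design$label,
                                                   design$sample, sep = "|"))
    out
  })
}
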