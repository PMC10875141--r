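# Epoch-wise freezing statistics and their pairing with ripple counts.

setMethod("show", "FreezingSeries", function(object) {
  cat(sprintf("FreezingSeries: %d bins of %g s (%.1f s total)\n",
    length(object@binStart), object@binWidth,
    length(object@binStart) * object@binWidth))
  invisible(NULL)
})

#' Mean freezing per epoch window
#'
#' Per-window mean freezing in percent. Bins straddling a window boundary
#' contribute proportionally to their overlap, so epoch means are invariant
#' to bin-width refinement of the same underlying signal.
#'
#' @param series a [FreezingSeries-class].
#' @param windows epoch-window data.frame (e.g.
#'   \code{epochWindows(sched, "behavior")}); the series must cover every
#'   window.
#' @param animal animal identifier recorded in the output.
#' @return data.frame with columns \code{animal}, \code{trial_index},
#'   \code{epoch_label}, \code{freezing_percent}; the per-animal
#'   trial-average per label is attached as attribute \code{"trialAverage"}.
#' @export
epochFreezing <- function(series, windows, animal = "animal1") {
  binStart <- series@binStart
  binEnd <- binStart + series@binWidth
  coverStart <- binStart[1]
  coverEnd <- binEnd[length(binEnd)]
  pct <- vapply(seq_len(nrow(windows)), function(i) {
    ws <- windows$start[i]; we <- windows$end[i]
    if (ws < coverStart - 1e-9 || we > coverEnd + 1e-9) {
      stop(sprintf(
        "freezing series does not cover window %s [%g, %g): coverage is [%g, %g)",
        windows$label[i], ws, we, coverStart, coverEnd))
    }
    w <- pmax(0, pmin(binEnd, we) - pmax(binStart, ws))
    sum(w * series@freezing) / sum(w) * 100
  }, numeric(1))
  out <- data.frame(animal = animal, trial_index = windows$trial_index,
                    epoch_label = windows$label, freezing_percent = pct,
                    stringsAsFactors = FALSE)
  attr(out, "trialAverage") <- stats::aggregate(
    freezing_percent ~ epoch_label, data = out, FUN = mean)
  out
}

#' Pair per-ITI freezing with per-ITI ripple counts
#'
#' Builds one row per (animal, ITI) with the mean freezing percent and SWR
#' count over that ITI window, pooled across animals; the pooled table is
#' what enters the Pearson correlation (df = rows - 2).
#'
#' @param eventsBySession named list of ripple event tables, one per animal.
#' @param freezingBySession named list of [FreezingSeries-class], same names.
#' @param schedule the common [SessionSchedule-class].
#' @return data.frame with columns \code{animal}, \code{trial_index},
#'   \code{iti_freezing_percent}, \code{swr_count}.
#' @export
swrFreezingPairs <- function(eventsBySession, freezingBySession, schedule) {
  if (!setequal(names(eventsBySession), names(freezingBySession)) ||
      is.null(names(eventsBySession))) {
    stop("mismatched session identifiers between events and freezing inputs")
  }
  win <- epochWindows(schedule, "swr")
  itiWin <- win[win$label == "swr_iti", , drop = FALSE]
  rows <- lapply(names(eventsBySession), function(a) {
    inc <- rippleIncidence(eventsBySession[[a]], itiWin)
    fz <- epochFreezing(freezingBySession[[a]], itiWin, animal = a)
    data.frame(animal = a, trial_index = itiWin$trial_index,
               iti_freezing_percent = fz$freezing_percent,
               swr_count = inc$count, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read/write a freezing series as tidy CSV
#'
#' Columns \code{bin_start_s}, \code{freezing_fraction}.
#'
#' @param series a [FreezingSeries-class].
#' @param path CSV path.
#' @export
writeFreezingCsv <- function(series, path) {
  utils::write.csv(data.frame(bin_start_s = series@binStart,
                              freezing_fraction = series@freezing),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFreezingCsv
#' @export
readFreezingCsv <- function(path) {
  df <- utils::read.csv(path)
  bw <- stats::median(diff(df$bin_start_s))
  new("FreezingSeries", binStart = df$bin_start_s,
      freezing = df$freezing_fraction, binWidth = bw)
}
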