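#' Build a trace-fear-conditioning session schedule
#'
#' Constructs the absolute timeline of a TFC session: a baseline period
#' followed by \code{nTrials} trials of tone, trace interval, footshock and
#' ITI. Two profiles from the standard designs are available as shortcuts:
#' \code{"photometry"} (120 s baseline, 10 trials, 20 s tone, 20 s trace,
#' 2 s shock, 120 s ITI) and \code{"optogenetic"} (240 s baseline, 3 trials,
#' 240 s ITI, same tone/trace/shock).
#'
#' @param profile optional named profile supplying defaults; explicit
#'   arguments override profile values.
#' @param baselineDuration,toneDuration,traceDuration,shockDuration,itiDuration
#'   epoch durations in seconds, all strictly positive.
#' @param nTrials number of trials (>= 1).
#' @return a [SessionSchedule-class] object.
#' @examples
#' sched <- buildSchedule("photometry")
#' csOnsets(sched)[1:2]   # 120, 282
#' @export
buildSchedule <- function(profile = c("photometry", "optogenetic", "custom"),
                          baselineDuration = NULL, nTrials = NULL,
                          toneDuration = NULL, traceDuration = NULL,
                          shockDuration = NULL, itiDuration = NULL) {
  profile <- match.arg(profile)
  defaults <- switch(profile,
    photometry = list(baselineDuration = 120, nTrials = 10L, toneDuration = 20,
                      traceDuration = 20, shockDuration = 2, itiDuration = 120),
    optogenetic = list(baselineDuration = 240, nTrials = 3L, toneDuration = 20,
                       traceDuration = 20, shockDuration = 2, itiDuration = 240),
    custom = list(baselineDuration = 120, nTrials = 10L, toneDuration = 20,
                  traceDuration = 20, shockDuration = 2, itiDuration = 120)
  )
  pick <- function(x, d) if (is.null(x)) d else x
  baselineDuration <- pick(baselineDuration, defaults$baselineDuration)
  nTrials <- pick(nTrials, defaults$nTrials)
  toneDuration <- pick(toneDuration, defaults$toneDuration)
  traceDuration <- pick(traceDuration, defaults$traceDuration)
  shockDuration <- pick(shockDuration, defaults$shockDuration)
  itiDuration <- pick(itiDuration, defaults$itiDuration)

  durs <- c(baselineDuration, toneDuration, traceDuration, shockDuration,
            itiDuration)
  if (any(!is.finite(durs)) || any(durs <= 0)) {
    stop("invalid parameter: all durations must be finite and strictly positive")
  }
  if (!is.finite(nTrials) || nTrials < 1) {
    stop("invalid parameter: nTrials must be >= 1")
  }
  nTrials <- as.integer(nTrials)
  period <- toneDuration + traceDuration + shockDuration + itiDuration
  onsets <- baselineDuration + period * (seq_len(nTrials) - 1)
  new("SessionSchedule",
    baselineDuration = baselineDuration, nTrials = nTrials,
    toneDuration = toneDuration, traceDuration = traceDuration,
    shockDuration = shockDuration, itiDuration = itiDuration,
    csOnsets = onsets
  )
}

#' @rdname SessionSchedule-class
#' @export
setMethod("nTrials", "SessionSchedule", function(object) object@nTrials)

#' @rdname SessionSchedule-class
#' @export
setMethod("csOnsets", "SessionSchedule", function(object) object@csOnsets)

#' @rdname SessionSchedule-class
#' @export
setMethod("sessionDuration", "SessionSchedule", function(object) {
  last <- object@csOnsets[object@nTrials]
  last + object@toneDuration + object@traceDuration + object@shockDuration +
    object@itiDuration
})

#' Shock onset times of a schedule
#' @param schedule a [SessionSchedule-class].
#' @return numeric vector of absolute shock onset times (seconds).
#' @export
shockOnsets <- function(schedule) {
  schedule@csOnsets + schedule@toneDuration + schedule@traceDuration
}

setMethod("show", "SessionSchedule", function(object) {
  cat("SessionSchedule:", object@nTrials, "trial(s)\n")
  cat(sprintf("  baseline %.0f s | tone %.0f s | trace %.0f s | shock %.0f s | ITI %.0f s\n",
    object@baselineDuration, object@toneDuration, object@traceDuration,
    object@shockDuration, object@itiDuration))
  cat(sprintf("  CS onsets: %s s; session ends at %.0f s\n",
    paste(utils::head(object@csOnsets, 4), collapse = ", "),
    sessionDuration(object)))
  invisible(NULL)
})

epochRow <- function(label, start, end, trial) {
  data.frame(label = label, start = start, end = end, trial_index = trial,
             stringsAsFactors = FALSE)
}

#' @describeIn epochWindows windows for a \code{SessionSchedule}.
#'
#' The three families serve the three analysis streams:
#' \itemize{
#'   \item \code{behavior}: session \code{baseline} \code{[0, cs0)}, then per
#'     trial \code{tone}, \code{trace}, \code{shock} and \code{iti}
#'     (shock offset to next CS onset); these tile each inter-onset interval.
#'   \item \code{photometry}: \code{pre_shock} = the trace interval
#'     \code{[cs+tone, cs+tone+trace)} and \code{post_shock} = the equal-length
#'     window starting at shock offset. With the standard 20/20/2 s trial these
#'     are 20-40 s and 42-62 s after CS onset; the 2 s shock itself belongs to
#'     neither.
#'   \item \code{swr}: \code{swr_baseline} = the 120 s immediately before the
#'     first tone (truncated to \code{[0, cs0)} with a warning when the
#'     schedule's baseline is shorter) and per trial \code{swr_iti} = the first
#'     120 s after shock offset.
#' }
#' @export
setMethod("epochWindows", "SessionSchedule", function(schedule,
    family = c("behavior", "photometry", "swr"), ...) {
  family <- match.arg(family)
  cs <- schedule@csOnsets
  tone <- schedule@toneDuration
  trace <- schedule@traceDuration
  shock <- schedule@shockDuration
  iti <- schedule@itiDuration
  trials <- seq_len(schedule@nTrials) - 1L
  shockEnd <- cs + tone + trace + shock

  out <- switch(family,
    behavior = rbind(
      epochRow("baseline", 0, cs[1], NA_integer_),
      epochRow(rep("tone", length(cs)), cs, cs + tone, trials),
      epochRow(rep("trace", length(cs)), cs + tone, cs + tone + trace, trials),
      epochRow(rep("shock", length(cs)), cs + tone + trace, shockEnd, trials),
      epochRow(rep("iti", length(cs)), shockEnd, shockEnd + iti, trials)
    ),
    photometry = rbind(
      epochRow(rep("pre_shock", length(cs)), cs + tone, cs + tone + trace, trials),
      epochRow(rep("post_shock", length(cs)), shockEnd, shockEnd + trace, trials)
    ),
    swr = {
      blStart <- cs[1] - 120
      if (blStart < 0) {
        warning("baseline shorter than 120 s; swr_baseline truncated to [0, ",
                cs[1], ")")
        blStart <- 0
      }
      rbind(
        epochRow("swr_baseline", blStart, cs[1], NA_integer_),
        epochRow(rep("swr_iti", length(cs)), shockEnd, shockEnd + 120, trials)
      )
    }
  )
  rownames(out) <- NULL
  out
})

#' Clip epoch windows to a recording length
#'
#' @param windows an epoch-window data.frame from [epochWindows()].
#' @param duration recording duration in seconds.
#' @return the windows with \code{end} clipped to \code{duration}; windows
#'   that fall entirely outside the recording are dropped.
#' @export
clipWindows <- function(windows, duration) {
  windows$end <- pmin(windows$end, duration)
  windows[windows$start < windows$end, , drop = FALSE]
}

#' Read or write a schedule as a YAML/JSON config
#'
#' The file holds the scalar schedule fields (\code{baseline_duration},
#' \code{n_trials}, \code{tone_duration}, \code{trace_duration},
#' \code{shock_duration}, \code{iti_duration}); CS onsets are derived.
#'
#' @param path file path; format chosen by extension (\code{.json} for JSON,
#'   anything else parsed as YAML).
#' @return for the reader, a [SessionSchedule-class]; the writer returns
#'   \code{path} invisibly.
#' @export
readSchedule <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  buildSchedule("custom",
    baselineDuration = cfg$baseline_duration, nTrials = cfg$n_trials,
    toneDuration = cfg$tone_duration, traceDuration = cfg$trace_duration,
    shockDuration = cfg$shock_duration, itiDuration = cfg$iti_duration
  )
}

#' @rdname readSchedule
#' @param schedule a [SessionSchedule-class] to serialise.
#' @export
writeSchedule <- function(schedule, path) {
  cfg <- list(
    baseline_duration = schedule@baselineDuration,
    n_trials = schedule@nTrials,
    tone_duration = schedule@toneDuration,
    trace_duration = schedule@traceDuration,
    shock_duration = schedule@shockDuration,
    iti_duration = schedule@itiDuration
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' Export epoch windows as a BED-like interval table
#'
#' Writes a tab-separated file with columns \code{label}, \code{start_s},
#' \code{end_s}, \code{trial_index}.
#'
#' @param windows epoch-window data.frame.
#' @param path output path.
#' @export
writeWindowsTsv <- function(windows, path) {
  out <- data.frame(label = windows$label, start_s = windows$start,
                    end_s = windows$end, trial_index = windows$trial_index)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
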