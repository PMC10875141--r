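# The study's statistical tests, implemented from their defining closed
# forms (with explicit degenerate-input contracts) on top of R's t/F
# distribution functions. Results are one-row tidy data.frames:
# method, statistic, df (and df2 for F), p_value, estimate.

statRow <- function(method, statistic, df, p, estimate, df2 = NA_real_) {
  data.frame(method = method, statistic = statistic, df = df, df2 = df2,
             p_value = p, estimate = estimate, stringsAsFactors = FALSE)
}

#' Paired t test from the closed-form definition
#'
#' \code{t = mean(d) / (sd(d)/sqrt(n))} on the paired differences
#' \code{d = post - pre}, with the sample SD (n - 1), df = n - 1 and a
#' two-sided p-value.
#'
#' @param pre,post equal-length per-animal scalars.
#' @return one-row results data.frame; \code{estimate} is \code{mean(post - pre)}.
#' @export
pairedT <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre and post must have equal length")
  n <- length(pre)
  if (n < 2) stop("need at least 2 pairs")
  d <- post - pre
  sdd <- stats::sd(d)
  if (!is.finite(sdd) || sdd <= 0) {
    stop("degenerate test: paired differences have zero variance")
  }
  tstat <- mean(d) / (sdd / sqrt(n))
  statRow("paired t", tstat, n - 1, 2 * stats::pt(-abs(tstat), n - 1), mean(d))
}

#' Welch's unpaired t test from the closed forms
#'
#' Welch statistic \code{t = (mA - mB) / sqrt(sA^2/nA + sB^2/nB)} with the
#' Welch-Satterthwaite df and a two-sided p-value.
#'
#' @param groupA,groupB scalars, each of length >= 2.
#' @return one-row results data.frame; \code{estimate} is \code{mean(A) - mean(B)}.
#' @export
welchT <- function(groupA, groupB) {
  nA <- length(groupA); nB <- length(groupB)
  if (nA < 2 || nB < 2) stop("each group needs at least 2 values")
  vA <- stats::var(groupA); vB <- stats::var(groupB)
  if ((!is.finite(vA) || vA <= 0) && (!is.finite(vB) || vB <= 0)) {
    stop("degenerate test: zero variance in both groups")
  }
  se2 <- vA / nA + vB / nB
  tstat <- (mean(groupA) - mean(groupB)) / sqrt(se2)
  df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  statRow("Welch t", tstat, df, 2 * stats::pt(-abs(tstat), df),
          mean(groupA) - mean(groupB))
}

#' Pearson correlation test from the closed forms
#'
#' Product-moment r, then \code{t = r * sqrt((n - 2)/(1 - r^2))} with
#' df = n - 2 and a two-sided p-value. Exactly collinear input
#' (\code{|r| = 1}) is reported with p = 0 rather than dividing by zero.
#'
#' @param x,y equal-length scalars, n >= 3, both with positive variance.
#' @return one-row results data.frame; \code{estimate} is r.
#' @export
pearsonTest <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 pairs")
  if (stats::var(x) <= 0 || stats::var(y) <= 0) {
    stop("degenerate test: zero variance in x or y")
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (abs(r) >= 1 - 1e-12) {
    out <- statRow("Pearson r", sign(r) * Inf, n - 2, 0, r)
    attr(out, "note") <- "degenerate variance: exactly collinear input"
    return(out)
  }
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  statRow("Pearson r", tstat, n - 2, 2 * stats::pt(-abs(tstat), n - 2), r)
}

#' Mixed-design (split-plot) two-way ANOVA
#'
#' One between-subjects factor (group) and one within-subjects factor
#' (phase), one value per (animal, phase). Sums of squares are decomposed
#' into group (tested against animals-within-group) and phase and
#' group x phase (tested against phase x animals-within-group). No
#' sphericity correction is applied.
#'
#' @param table data.frame with columns \code{animal}, \code{group},
#'   \code{phase}, \code{value}; every animal must have every phase.
#' @return three-row results data.frame (effects \code{group}, \code{phase},
#'   \code{group:phase}) with F statistics, df pairs and p-values.
#' @export
mixedAnova <- function(table) {
  req <- c("animal", "group", "phase", "value")
  if (!all(req %in% names(table))) {
    stop("table must have columns animal, group, phase, value")
  }
  table$animal <- as.character(table$animal)
  table$group <- as.character(table$group)
  table$phase <- as.character(table$phase)
  animals <- unique(table$animal)
  phases <- unique(table$phase)
  groups <- unique(table$group)
  k <- length(phases)
  if (length(groups) < 2) stop("need at least 2 groups")
  # completeness: every animal has exactly one value per phase
  tab <- table(table$animal, table$phase)
  if (any(tab != 1L)) {
    bad <- rownames(tab)[apply(tab != 1L, 1, any)]
    stop("animal(s) missing a phase (no imputation): ",
         paste(bad, collapse = ", "))
  }
  y <- table$value
  grand <- mean(y)
  ssTotal <- sum((y - grand)^2)
  subjMean <- tapply(y, table$animal, mean)
  subjGroup <- tapply(table$group, table$animal, function(g) g[1])
  nPerGroup <- table(subjGroup)
  groupMean <- tapply(y, table$group, mean)
  phaseMean <- tapply(y, table$phase, mean)
  cellMean <- tapply(y, list(table$group, table$phase), mean)

  ssSubjects <- k * sum((subjMean - grand)^2)
  ssGroup <- k * sum(nPerGroup[names(groupMean)] * (groupMean - grand)^2)
  ssSubjErr <- ssSubjects - ssGroup
  N <- length(animals)
  ssPhase <- N * sum((phaseMean - grand)^2)
  ssCells <- sum(outer(nPerGroup[rownames(cellMean)], rep(1, k)) *
                   (cellMean - grand)^2)
  ssInter <- ssCells - ssGroup - ssPhase
  ssWithinErr <- ssTotal - ssSubjects - ssPhase - ssInter

  a <- length(groups)
  dfGroup <- a - 1
  dfSubjErr <- N - a
  dfPhase <- k - 1
  dfInter <- (a - 1) * (k - 1)
  dfWithinErr <- (N - a) * (k - 1)
  if (dfSubjErr < 1 || dfWithinErr < 1) {
    stop("not enough animals for the error terms")
  }
  msSubjErr <- ssSubjErr / dfSubjErr
  msWithinErr <- ssWithinErr / dfWithinErr
  fGroup <- (ssGroup / dfGroup) / msSubjErr
  fPhase <- (ssPhase / dfPhase) / msWithinErr
  fInter <- (ssInter / dfInter) / msWithinErr
  out <- rbind(
    statRow("mixed ANOVA: group", fGroup, dfGroup,
            stats::pf(fGroup, dfGroup, dfSubjErr, lower.tail = FALSE),
            ssGroup, df2 = dfSubjErr),
    statRow("mixed ANOVA: phase", fPhase, dfPhase,
            stats::pf(fPhase, dfPhase, dfWithinErr, lower.tail = FALSE),
            ssPhase, df2 = dfWithinErr),
    statRow("mixed ANOVA: group:phase", fInter, dfInter,
            stats::pf(fInter, dfInter, dfWithinErr, lower.tail = FALSE),
            ssInter, df2 = dfWithinErr)
  )
  out$effect <- c("group", "phase", "group:phase")
  out
}

#' Sidak adjustment for a family of comparisons
#'
#' \code{p_adj = 1 - (1 - p)^m}, capped at 1.
#'
#' @param p raw p-values in [0, 1].
#' @param m family size (defaults to \code{length(p)}).
#' @return adjusted p-values.
#' @export
sidakAdjust <- function(p, m = length(p)) {
  if (m < 1) stop("m must be >= 1")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  pmin(1, 1 - (1 - p)^m)
}

#' Per-phase group contrasts with Sidak adjustment
#'
#' For each phase, compares the two groups with either Welch's t (default)
#' or a pooled-variance t, then Sidak-adjusts the family of per-phase
#' p-values.
#'
#' @param table as in [mixedAnova()] (exactly two groups).
#' @param pool use pooled-variance t instead of Welch.
#' @return data.frame with one row per phase: statistic, df, raw and
#'   adjusted p-values, mean difference.
#' @export
sidakPosthoc <- function(table, pool = FALSE) {
  groups <- unique(table$group)
  if (length(groups) != 2) stop("post hoc contrasts require exactly 2 groups")
  phases <- unique(table$phase)
  rows <- lapply(phases, function(ph) {
    sub <- table[table$phase == ph, ]
    a <- sub$value[sub$group == groups[1]]
    b <- sub$value[sub$group == groups[2]]
    res <- if (pool) pooledT(a, b) else welchT(a, b)
    data.frame(phase = ph, statistic = res$statistic, df = res$df,
               p_value = res$p_value, estimate = res$estimate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- sidakAdjust(out$p_value, nrow(out))
  rownames(out) <- NULL
  out
}

# pooled-variance two-sample t (used by the post hoc 'pool' option and the
# k = 2 interaction identity)
pooledT <- function(a, b) {
  nA <- length(a); nB <- length(b)
  if (nA < 2 || nB < 2) stop("each group needs at least 2 values")
  sp2 <- ((nA - 1) * stats::var(a) + (nB - 1) * stats::var(b)) / (nA + nB - 2)
  if (!is.finite(sp2) || sp2 <= 0) stop("degenerate test: zero pooled variance")
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / nA + 1 / nB))
  statRow("pooled t", tstat, nA + nB - 2,
          2 * stats::pt(-abs(tstat), nA + nB - 2), mean(a) - mean(b))
}

#' Write a tidy results table as CSV
#' @param results a results data.frame from any test in this package.
#' @param path output CSV path.
#' @export
writeResultsCsv <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}
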