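#' Tumor volume by the modified ellipsoid formula
#'
#' `volume = length x width^2 / 2`, with lengths in mm and volume in mm^3.
#' By caliper convention the width is the smaller diameter; inputs with
#' width greater than length are swapped with a warning.
#'
#' @param length,width caliper diameters in mm (non-negative; vectorized).
#' @return Numeric vector of volumes in mm^3.
#' @export
#' @examples
#' tumorVolume(10, 5)  # 125
tumorVolume <- function(length, width) {
  if (anyNA(length) || anyNA(width) || any(length < 0) || any(width < 0))
    stop("caliper measures must be non-negative numbers")
  swap <- width > length
  if (any(swap)) {
    warning(sprintf("swapped length/width for %d measurement(s)", sum(swap)))
    tmp <- length[swap]
    length[swap] <- width[swap]
    width[swap] <- tmp
  }
  length * width^2 / 2
}

#' Percent tumor-volume inhibition of a treated arm
#'
#' Default definition: `100 * (1 - mean(treated) / mean(control))` on
#' final volumes. The alternative growth-delta definition
#' (`100 * (1 - mean(treated - treatedBaseline) /
#' mean(control - controlBaseline))`) is available via `method = "delta"`.
#'
#' @param treated,control numeric vectors of final tumor volumes (mm^3).
#' @param treatedBaseline,controlBaseline baseline volumes, required for
#'   `method = "delta"`.
#' @param method `"final_mean"` (default) or `"delta"`.
#' @param digits rounding of the reported percent (default nearest
#'   integer, half away from zero).
#' @return Percent inhibition.
#' @export
#' @examples
#' percentInhibition(c(90, 90), c(1000, 1000))  # 91
percentInhibition <- function(treated, control, treatedBaseline = NULL,
                              controlBaseline = NULL,
                              method = c("final_mean", "delta"),
                              digits = 0) {
  method <- match.arg(method)
  if (!length(treated) || !length(control))
    stop("both arms must be non-empty")
  if (method == "delta") {
    if (is.null(treatedBaseline) || is.null(controlBaseline))
      stop("baselines are required for the delta definition")
    treated <- treated - treatedBaseline
    control <- control - controlBaseline
  }
  if (mean(control) == 0) stop("control arm mean volume is zero")
  roundHalfUp(100 * (1 - mean(treated) / mean(control)), digits)
}

#' Percent shrinkage from baseline
#'
#' `100 * (V0 - Vend) / V0`; negative when the tumor grew.
#'
#' @param v0 baseline volume (mm^3, > 0).
#' @param vend final volume (mm^3).
#' @param digits rounding (default nearest integer, half away from zero).
#' @return Percent shrinkage.
#' @export
#' @examples
#' percentShrinkage(250, 0.47 * 250)  # 53
percentShrinkage <- function(v0, vend, digits = 0) {
  if (any(v0 <= 0)) stop("baseline volume must be positive")
  roundHalfUp(100 * (v0 - vend) / v0, digits)
}

#' Read a caliper growth log
#'
#' CSV with columns `mouse_id`, `arm`, `day`, `length_mm`, `width_mm`.
#' Volumes are derived with [tumorVolume()].
#'
#' @param path file path.
#' @return data.frame with an added `volume` column, ordered by mouse and
#'   day.
#' @export
readGrowthLog <- function(path) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mouse_id", "arm", "day", "length_mm", "width_mm")
  if (!all(need %in% names(g)))
    stop(sprintf("growth log needs columns %s", paste(need, collapse = ", ")))
  g$volume <- tumorVolume(g$length_mm, g$width_mm)
  g[order(g$mouse_id, g$day), , drop = FALSE]
}

#' Classify one tumor growth curve as CR, DR, SR or NR
#'
#' Classes, assessed at end of follow-up relative to the volume at
#' treatment start (baseline):
#' \itemize{
#'   \item CR (complete response): final volume at or below `crThreshold`
#'     (default 0, i.e. no palpable tumor);
#'   \item DR (durable response): final volume below baseline;
#'   \item SR (short response): the tumor responded (nadir below
#'     `responseFraction` x baseline) but progressed back to at least
#'     baseline;
#'   \item NR (no response): none of the above.
#' }
#'
#' @param day integer vector of measurement days (strictly increasing).
#' @param volume numeric vector of volumes (mm^3), same length as `day`.
#' @param treatmentStart day treatment began (baseline = first measurement
#'   at or after this day); default 0.
#' @param crThreshold absolute CR volume cutoff (mm^3).
#' @param responseFraction nadir fraction of baseline that counts as a
#'   response (default 0.8).
#' @return list with `class` (factor level among CR/DR/SR/NR), `baseline`,
#'   `nadir`, `final`.
#' @export
#' @examples
#' classifyResponse(c(0, 7, 14, 21), c(250, 150, 100, 110))$class  # DR
classifyResponse <- function(day, volume, treatmentStart = 0,
                             crThreshold = 0, responseFraction = 0.8) {
  if (length(day) < 2L) stop("at least 2 time points are required")
  if (is.unsorted(day, strictly = TRUE)) stop("days must strictly increase")
  onTx <- which(day >= treatmentStart)
  if (!length(onTx)) stop("no measurement at or after treatment start")
  baseline <- volume[onTx[1]]
  if (baseline <= 0) stop("baseline volume must be positive")
  final <- volume[length(volume)]
  nadir <- min(volume[onTx])
  cls <- if (final <= crThreshold) "CR"
  else if (final < baseline) "DR"
  else if (nadir < responseFraction * baseline) "SR"
  else "NR"
  list(class = factor(cls, levels = c("CR", "DR", "SR", "NR")),
       baseline = baseline, nadir = nadir, final = final)
}

#' Classify every mouse in a growth log
#'
#' @param growth data.frame as returned by [readGrowthLog()] (columns
#'   `mouse_id`, `arm`, `day`, `volume`).
#' @inheritParams classifyResponse
#' @return data.frame with one row per mouse: `mouse_id`, `arm`, `class`,
#'   `baseline`, `nadir`, `final`.
#' @export
classifyResponses <- function(growth, treatmentStart = 0, crThreshold = 0,
                              responseFraction = 0.8) {
  out <- lapply(split(growth, growth$mouse_id), function(g) {
    g <- g[order(g$day), , drop = FALSE]
    r <- classifyResponse(g$day, g$volume, treatmentStart, crThreshold,
                          responseFraction)
    data.frame(mouse_id = g$mouse_id[1], arm = g$arm[1],
               class = as.character(r$class), baseline = r$baseline,
               nadir = r$nadir, final = r$final, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize response calls into per-class counts and percentages
#'
#' Percentages are rendered both to the nearest integer and to one decimal
#' (half away from zero), the two precisions used in arm summaries such as
#' "48\% (10 of 21)" and "14.3\% (1 of 7)".
#'
#' @param class character or factor vector of per-mouse classes
#'   (CR/DR/SR/NR).
#' @return data.frame with one row per class: `class`, `count`, `total`,
#'   `pct`, `pct_1dp`.
#' @export
#' @examples
#' summarizeResponses(rep(c("CR", "DR", "SR"), c(10, 6, 5)))
summarizeResponses <- function(class) {
  if (!length(class)) stop("no response calls to summarize")
  class <- factor(as.character(class), levels = c("CR", "DR", "SR", "NR"))
  if (anyNA(class)) stop("classes must be among CR, DR, SR, NR")
  n <- length(class)
  counts <- table(class)
  data.frame(class = names(counts), count = as.integer(counts), total = n,
             pct = roundHalfUp(100 * as.integer(counts) / n),
             pct_1dp = roundHalfUp(100 * as.integer(counts) / n, 1),
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time positive event/censoring times (days).
#' @param event 1 = endpoint reached, 0 = censored.
#' @return data.frame step function: `time` (starting at 0), `surv`
#'   (starting at 1), `n_risk`, `n_event`.
#' @export
kmEstimator <- function(time, event) {
  if (!length(time)) stop("no survival records")
  if (any(time <= 0)) stop("times must be positive")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = c(0, fit$time), surv = c(1, fit$surv),
             n_risk = c(length(time), fit$n.risk),
             n_event = c(0, fit$n.event))
}

#' Log-rank (Mantel-Cox) test between two arms
#'
#' One-degree-of-freedom log-rank chi-square over pooled event times; if
#' neither arm has an event the statistic is 0 and p is 1 by convention.
#'
#' @param timeA,eventA times and event indicators of arm A.
#' @param timeB,eventB times and event indicators of arm B.
#' @return Named list with `chisq` and `p`.
#' @export
logrankTest <- function(timeA, eventA, timeB, eventB) {
  if (!length(timeA) || !length(timeB)) stop("both arms must be non-empty")
  if (sum(eventA) + sum(eventB) == 0) return(list(chisq = 0, p = 1))
  time <- c(timeA, timeB)
  event <- c(eventA, eventB)
  group <- rep(c("A", "B"), c(length(timeA), length(timeB)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chisq <- unname(sd$chisq)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Relative qPCR quantification (delta-delta-Ct)
#'
#' Normalizes target Ct against a housekeeping gene (Tbp in this
#' pipeline), subtracts the reference sample's normalized Ct and returns
#' `-ddCt`, i.e. the log2 fold change.
#'
#' @param ctTarget,ctHousekeeping sample Ct values.
#' @param refCtTarget,refCtHousekeeping reference-sample Ct values.
#' @return log2 fold change.
#' @export
#' @examples
#' ddctLog2fc(20, 15, 24, 16)  # 3
ddctLog2fc <- function(ctTarget, ctHousekeeping, refCtTarget,
                       refCtHousekeeping) {
  ct <- c(ctTarget, ctHousekeeping, refCtTarget, refCtHousekeeping)
  if (anyNA(ct) || any(!is.finite(ct)) || any(ct <= 0))
    stop("all four Ct values must be finite and positive")
  dctSample <- ctTarget - ctHousekeeping
  dctRef <- refCtTarget - refCtHousekeeping
  -(dctSample - dctRef)
}

#' Run the preclinical response pipeline
#'
#' Classifies every mouse in a growth log, summarizes classes per arm,
#' and, when survival records are supplied, computes per-arm Kaplan-Meier
#' curves and a log-rank test of each arm against the control arm.
#'
#' @param growth data.frame as from [readGrowthLog()], or a CSV path.
#' @param survival optional data.frame (columns `mouse_id`, `arm`,
#'   `time_days`, `event`) or CSV path.
#' @param treatmentStart,crThreshold,responseFraction see
#'   [classifyResponse()].
#' @param controlArm arm label used as log-rank reference (default
#'   `"control"`).
#' @param outDir optional directory for TSV reports plus a manifest.
#' @return list with `calls`, `summary` (per arm), and (if survival data
#'   given) `km` (per arm) and `logrank` (per non-control arm).
#' @export
runPreclinical <- function(growth, survival = NULL, treatmentStart = 0,
                           crThreshold = 0, responseFraction = 0.8,
                           controlArm = "control", outDir = NULL) {
  if (is.character(growth)) growth <- readGrowthLog(growth)
  calls <- classifyResponses(growth, treatmentStart, crThreshold,
                             responseFraction)
  summ <- do.call(rbind, lapply(split(calls, calls$arm), function(a) {
    data.frame(arm = a$arm[1], summarizeResponses(a$class))
  }))
  rownames(summ) <- NULL
  out <- list(calls = calls, summary = summ)
  if (!is.null(survival)) {
    if (is.character(survival))
      survival <- utils::read.csv(survival, stringsAsFactors = FALSE)
    out$km <- lapply(split(survival, survival$arm), function(a)
      kmEstimator(a$time_days, a$event))
    ctrl <- survival[survival$arm == controlArm, , drop = FALSE]
    if (nrow(ctrl)) {
      arms <- setdiff(unique(survival$arm), controlArm)
      out$logrank <- do.call(rbind, lapply(arms, function(aa) {
        a <- survival[survival$arm == aa, , drop = FALSE]
        lr <- logrankTest(a$time_days, a$event, ctrl$time_days, ctrl$event)
        data.frame(arm = aa, chisq = lr$chisq, p = lr$p)
      }))
    }
  }
  if (!is.null(outDir)) {
    .ensureDir(outDir)
    utils::write.table(calls, file.path(outDir, "response_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summ, file.path(outDir, "response_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(out$logrank))
      utils::write.table(out$logrank, file.path(outDir, "logrank.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    .writeManifest(outDir, list(treatmentStart = treatmentStart,
                                crThreshold = crThreshold,
                                responseFraction = responseFraction,
                                controlArm = controlArm))
  }
  out
}
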