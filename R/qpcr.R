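#' Single-pass outlier filtering of technical replicates
#'
#' Computes the mean over all replicates once and discards values that
#' differ from it by more than `max_dev` cycles. The mean is not
#' recomputed after discards (a single discard step; iterative re-meaning
#' can cascade on quadruplicates). A group keeping fewer than two
#' replicates is flagged unusable.
#'
#' @param replicate_cqs numeric vector of Cq values (>= 2)
#' @param max_dev maximum allowed deviation from the group mean, cycles
#'   (default 1.0)
#' @return list with `kept`, `dropped`, `usable`
#' @examples
#' filterReplicates(c(20.1, 20.2, 19.9, 22.0))  # drops 22.0
#' @export
filterReplicates <- function(replicate_cqs, max_dev = 1.0) {
  stopifnot(is.numeric(replicate_cqs))
  if (length(replicate_cqs) < 2L)
    stop("at least 2 replicates are required")
  m <- mean(replicate_cqs)
  keep <- abs(replicate_cqs - m) <= max_dev
  list(kept = replicate_cqs[keep], dropped = replicate_cqs[!keep],
       usable = sum(keep) >= 2L)
}

#' Summarize a replicate group
#'
#' @param kept_cqs numeric vector of retained Cq values (>= 2)
#' @return list with `mean_cq`, `sem` (sample SD over sqrt(n)), `n`
#' @examples
#' summarizeGroup(c(19, 21))  # mean 20, sem 1
#' @export
summarizeGroup <- function(kept_cqs) {
  stopifnot(is.numeric(kept_cqs))
  n <- length(kept_cqs)
  if (n < 2L) stop("at least 2 kept replicates are required")
  list(mean_cq = mean(kept_cqs), sem = sd(kept_cqs) / sqrt(n), n = n)
}

#' Per-sample delta-Cq between the autosomal and sex-linked targets
#'
#' `delta_cq = mean Cq(autosome) - mean Cq(sex locus)`. Because the two
#' targets share the same template input, any per-sample concentration
#' shift cancels in the difference — no input normalization is needed.
#' The reported uncertainty is the arithmetic sum of the two groups' SEMs
#' (quadrature available as an option).
#'
#' @param auto,sex summaries from [summarizeGroup()]
#' @param quadrature if TRUE, combine SEMs as sqrt(sem_a^2 + sem_s^2)
#'   instead of the default arithmetic sum
#' @return list with `delta_cq`, `sem_total`
#' @export
deltaCq <- function(auto, sex, quadrature = FALSE) {
  stopifnot(is.list(auto), is.list(sex),
            !is.null(auto$mean_cq), !is.null(sex$mean_cq))
  sem <- if (quadrature) sqrt(auto$sem^2 + sex$sem^2) else auto$sem + sex$sem
  list(delta_cq = auto$mean_cq - sex$mean_cq, sem_total = sem)
}

#' Split samples into the two dosage clusters
#'
#' Sorts samples by delta-Cq and splits at the contiguous boundary that
#' minimizes the total within-cluster sum of squares (the exact 1-D
#' two-class natural-breaks partition; in clean data this coincides with
#' the largest adjacent gap, but unlike the raw largest gap it is not
#' derailed by a single extreme sample at a batch edge). A batch is
#' reported as single-cluster (e.g. all-male) — requiring a male-standard
#' reference instead — when the boundary gap is below `min_gap` AND the
#' candidate split's cluster medians lie closer than `min_separation`.
#' The second condition keeps large, noisy mixed batches splittable:
#' technical scatter narrows the local gap between the nearest samples of
#' opposite sex well below `min_gap` long before it erodes the ~1-cycle
#' distance between the cluster medians that the Z-dosage difference
#' produces. The high cluster (greater delta-Cq) holds the putative ZZ
#' males.
#'
#' @param delta_cqs named numeric vector of per-sample delta-Cq values
#' @param min_gap smallest gap accepted outright as a cluster boundary,
#'   cycles (default 0.3)
#' @param min_separation smallest between-median distance accepted as
#'   evidence of two clusters when the gap test fails, cycles (default
#'   0.5, half the one-cycle dosage signature)
#' @return list with `high` and `low` (named numeric vectors) and
#'   `single_cluster` (logical; when TRUE, `high`/`low` are empty and
#'   `all` carries the input)
#' @export
splitClusters <- function(delta_cqs, min_gap = 0.3, min_separation = 0.5) {
  stopifnot(is.numeric(delta_cqs))
  if (length(delta_cqs) < 2L)
    stop("at least 2 samples are required for unsupervised clustering; ",
         "use a male standard for single samples")
  ord <- order(delta_cqs)
  sorted <- delta_cqs[ord]
  gaps <- diff(sorted)
  k <- .bestSplit(sorted)
  high <- sorted[(k + 1L):length(sorted)]
  low <- sorted[1:k]
  if (gaps[k] < min_gap &&
      median(high) - median(low) < min_separation) {
    return(list(high = numeric(0), low = numeric(0), single_cluster = TRUE,
                all = delta_cqs, max_gap = unname(gaps[k])))
  }
  list(high = high, low = low, single_cluster = FALSE,
       max_gap = unname(gaps[k]))
}

# Exact optimal contiguous 2-partition of a sorted vector: the split
# index k (low = 1..k) minimizing the total within-cluster sum of
# squares, via prefix sums. Ties go to the smaller k.
.bestSplit <- function(sorted) {
  n <- length(sorted)
  cs <- cumsum(sorted)
  cs2 <- cumsum(sorted^2)
  k <- seq_len(n - 1L)
  wssLow <- cs2[k] - cs[k]^2 / k
  wssHigh <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  which.min(wssLow + wssHigh)
}

#' Normalize delta-Cq to delta-delta-Cq
#'
#' Subtracts the male reference — the median of the high (male) cluster,
#' or a supplied male-standard delta-Cq — so that males center at 0 and
#' Z0 females at -1.
#'
#' @param delta_cqs numeric vector of delta-Cq values
#' @param clusters result of [splitClusters()], or NULL when
#'   `male_standard` is given
#' @param male_standard delta-Cq of a known male standard (used when the
#'   batch forms a single cluster)
#' @return list with `ddcq` (numeric vector) and `reference` (the value
#'   subtracted)
#' @export
normalizeDdcq <- function(delta_cqs, clusters = NULL, male_standard = NULL) {
  ref <- if (!is.null(male_standard)) {
    male_standard
  } else if (!is.null(clusters) && !clusters$single_cluster) {
    median(clusters$high)
  } else {
    stop("reference required: batch forms a single cluster and no male ",
         "standard was supplied")
  }
  list(ddcq = delta_cqs - ref, reference = ref)
}

#' Call sex from a normalized delta-delta-Cq
#'
#' The nearest of the two expected values wins: 0 (ZZ male, two Z copies)
#' or -1 (Z0 female, one Z copy). Values within `ambiguity_margin` of the
#' -0.5 midpoint are called `ambiguous`.
#'
#' @param ddcq numeric vector of delta-delta-Cq values
#' @param ambiguity_margin half-width of the ambiguous zone around -0.5,
#'   cycles (default 0.25)
#' @return character vector: "male", "female" or "ambiguous"
#' @examples
#' callSex(c(0.02, -0.98, -0.5))
#' @export
callSex <- function(ddcq, ambiguity_margin = 0.25) {
  stopifnot(is.numeric(ddcq))
  out <- ifelse(abs(ddcq - 0) < abs(ddcq - (-1)), "male", "female")
  out[abs(ddcq + 0.5) < ambiguity_margin] <- "ambiguous"
  out
}

#' Cluster separation statistics
#'
#' `median_distance` is the distance between the two cluster medians;
#' `min_gap` is the smallest distance between points from opposite
#' clusters, `min(high) - max(low)` — negative when the clusters overlap
#' (reported as-is, with a QC flag raised by [runBatch()]).
#'
#' @param high,low numeric vectors of per-sample values (delta-Cq or
#'   delta-delta-Cq; both give identical statistics)
#' @return list with `median_distance`, `min_gap`
#' @export
separationMetrics <- function(high, low) {
  if (!length(high) || !length(low))
    stop("both clusters must be non-empty")
  list(median_distance = abs(median(high) - median(low)),
       min_gap = min(high) - max(low))
}

#' One-sided exact binomial tail probability
#'
#' Probability of observing at least `n_correct` successes in `n_total`
#' trials under success probability `p0`; used to test whether the rate
#' of correct sex predictions beats chance (50%). Computed as the exact
#' upper binomial tail; 2^-81 is comfortably representable.
#'
#' @param n_correct number of successes
#' @param n_total number of trials
#' @param p0 null success probability (default 0.5)
#' @return the one-sided p-value
#' @examples
#' exactBinomialP(8, 8)    # 0.00390625
#' exactBinomialP(81, 81)  # 2^-81
#' @export
exactBinomialP <- function(n_correct, n_total, p0 = 0.5) {
  stopifnot(n_correct >= 0, n_correct <= n_total, p0 >= 0, p0 <= 1)
  pbinom(n_correct - 1, n_total, p0, lower.tail = FALSE)
}

#' Run the full sex-calling workflow on a Cq table
#'
#' Composes the pipeline: per-(sample, target) outlier filtering, group
#' summaries, delta-Cq, largest-gap clustering, male-median (or
#' male-standard) normalization, nearest-target sex calls, separation
#' statistics, and — when true sexes are supplied — exact binomial
#' validation of the accuracy. Every usable sample is called male or
#' female by proximity to the expected delta-delta-Cq of 0 (ZZ) or -1
#' (Z0); values inside the ambiguity zone around the -0.5 midpoint keep
#' their call but receive an `ambiguous-zone` QC flag. Samples failing
#' replicate QC are excluded from clustering but kept in the output with
#' flags, never silently dropped. The workflow is fully deterministic.
#'
#' @param cq data.frame with columns `sample_id`, `target`
#'   (autosome/sex), `cq` — one row per technical replicate (see
#'   [readCqTable()])
#' @param truth optional data.frame with columns `sample_id`, `sex`
#'   ("male"/"female") for validation
#' @param max_dev replicate outlier threshold, cycles (default 1.0)
#' @param min_gap minimum cluster-splitting gap, cycles (default 0.3)
#' @param ambiguity_margin ambiguous-call half-width, cycles (default 0.25)
#' @param male_standard optional delta-Cq of a male standard, required for
#'   single-cluster (e.g. all-male) batches
#' @param quadrature combine the two SEMs in quadrature instead of the
#'   default arithmetic sum
#' @return a [SexCallBatch-class]
#' @examples
#' sim <- simulateCqBatch(n_male = 4, n_female = 4, seed = 1)
#' res <- runBatch(sim$measurements, truth = sim$truth)
#' res
#' @export
runBatch <- function(cq, truth = NULL, max_dev = 1.0, min_gap = 0.3,
                     ambiguity_margin = 0.25, male_standard = NULL,
                     quadrature = FALSE) {
  groups <- groupMeasurements(cq, minReplicates = 2L)
  samples <- unique(groups$sample_id)
  perSample <- lapply(samples, function(sid) {
    flags <- character(0)
    sub <- groups[groups$sample_id == sid, , drop = FALSE]
    sums <- list()
    for (tg in CQ_TARGETS) {
      row <- which(sub$target == tg)
      if (!length(row)) {
        flags <- c(flags, paste0("missing-", tg))
        next
      }
      filt <- filterReplicates(sub$replicate_cqs[[row]], max_dev = max_dev)
      if (length(filt$dropped))
        flags <- c(flags, paste0("outliers-dropped-", tg, ":",
                                 length(filt$dropped)))
      if (!filt$usable) {
        flags <- c(flags, paste0("unusable-", tg))
        next
      }
      sums[[tg]] <- summarizeGroup(filt$kept)
    }
    if (length(sums) == 2L) {
      d <- deltaCq(sums$autosome, sums$sex, quadrature = quadrature)
      list(sample_id = sid, delta_cq = d$delta_cq, sem = d$sem_total,
           mean_cq_auto = sums$autosome$mean_cq,
           mean_cq_sex = sums$sex$mean_cq, flags = flags, usable = TRUE)
    } else {
      list(sample_id = sid, delta_cq = NA_real_, sem = NA_real_,
           mean_cq_auto = NA_real_, mean_cq_sex = NA_real_,
           flags = flags, usable = FALSE)
    }
  })
  usable <- vapply(perSample, `[[`, logical(1), "usable")
  dvec <- setNames(vapply(perSample, `[[`, numeric(1), "delta_cq"),
                   vapply(perSample, `[[`, character(1), "sample_id"))
  dUse <- dvec[usable]
  batchFlags <- character(0)

  if (!is.null(male_standard)) {
    clusters <- NULL
    norm <- normalizeDdcq(dUse, male_standard = male_standard)
  } else {
    clusters <- splitClusters(dUse, min_gap = min_gap)
    norm <- normalizeDdcq(dUse, clusters = clusters)
  }
  ddcq <- setNames(rep(NA_real_, length(dvec)), names(dvec))
  ddcq[names(norm$ddcq)] <- norm$ddcq
  # Sex is always assigned by the nearest of the expected targets (0 for
  # ZZ males, -1 for Z0 females); samples inside the ambiguity zone keep
  # their call but are flagged, so the headline accuracy reflects the
  # proximity rule while borderline values remain visible for QC.
  sex <- setNames(rep("unusable", length(dvec)), names(dvec))
  sex[usable] <- ifelse(abs(ddcq[usable]) < abs(ddcq[usable] + 1),
                        "male",
                        ifelse(abs(ddcq[usable]) > abs(ddcq[usable] + 1),
                               "female", "ambiguous"))
  inZone <- usable & abs(ddcq + 0.5) < ambiguity_margin
  for (i in which(inZone))
    perSample[[i]]$flags <- c(perSample[[i]]$flags, "ambiguous-zone")

  cluster <- setNames(rep(NA_character_, length(dvec)), names(dvec))
  if (!is.null(clusters) && !clusters$single_cluster) {
    cluster[names(clusters$high)] <- "high"
    cluster[names(clusters$low)] <- "low"
    sepIn <- ddcq
    sep <- separationMetrics(sepIn[names(clusters$high)],
                             sepIn[names(clusters$low)])
    # medians on the delta-Cq scale minus the reference: the male median
    # is then 0 by construction (bitwise), since the reference IS the
    # male-cluster median
    maleMed <- median(dUse[names(clusters$high)]) - norm$reference
    femaleMed <- median(dUse[names(clusters$low)]) - norm$reference
    if (sep$min_gap <= 0) batchFlags <- c(batchFlags, "clusters-overlap")
  } else {
    # reference-standard mode: cluster membership follows the call
    cluster[usable] <- ifelse(sex[usable] == "male", "high", "low")
    maleMed <- if (any(sex[usable] == "male"))
      median(ddcq[usable][sex[usable] == "male"]) else NA_real_
    femaleMed <- if (any(sex[usable] == "female"))
      median(ddcq[usable][sex[usable] == "female"]) else NA_real_
    sep <- list(
      median_distance = if (!is.na(maleMed) && !is.na(femaleMed))
        maleMed - femaleMed else NA_real_,
      min_gap = NA_real_)
  }

  calls <- data.frame(
    sample_id = names(dvec),
    mean_cq_auto = vapply(perSample, `[[`, numeric(1), "mean_cq_auto"),
    mean_cq_sex = vapply(perSample, `[[`, numeric(1), "mean_cq_sex"),
    delta_cq = unname(dvec),
    ddcq = unname(ddcq),
    sem = vapply(perSample, `[[`, numeric(1), "sem"),
    cluster = unname(cluster),
    predicted_sex = unname(sex),
    qc_flags = vapply(perSample, function(x)
      paste(x$flags, collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
  if (any(inZone))
    batchFlags <- c(batchFlags, "ambiguous-zone")

  validation <- list()
  if (!is.null(truth)) {
    stopifnot(all(c("sample_id", "sex") %in% names(truth)))
    m <- merge(calls, truth, by = "sample_id")
    scored <- m[m$predicted_sex %in% c("male", "female", "ambiguous"), ,
                drop = FALSE]
    nCorrect <- sum(scored$predicted_sex == scored$sex)
    nTotal <- nrow(scored)
    validation <- list(n_correct = nCorrect, n_total = nTotal,
                       p_value = exactBinomialP(nCorrect, nTotal))
  }

  methods::new("SexCallBatch",
    calls = calls,
    male_median = maleMed,
    female_median = femaleMed,
    median_distance = sep$median_distance,
    min_gap = sep$min_gap,
    n_male = sum(calls$predicted_sex == "male"),
    n_female = sum(calls$predicted_sex == "female"),
    validation = validation,
    params = list(max_dev = max_dev, min_gap = min_gap,
                  ambiguity_margin = ambiguity_margin,
                  male_standard = male_standard, quadrature = quadrature,
                  batch_flags = batchFlags)
  )
}

#' @describeIn runBatch per-sample call table
#' @param x a SexCallBatch
#' @export
sexCalls <- function(x) {
  stopifnot(methods::is(x, "SexCallBatch"))
  x@calls
}

#' @describeIn runBatch validation summary (empty list when no truth
#'   table was supplied)
#' @export
validation <- function(x) {
  stopifnot(methods::is(x, "SexCallBatch"))
  x@validation
}

#' @describeIn runBatch cluster separation: median distance and minimum
#'   between-cluster gap, in cycles
#' @export
separation <- function(x) {
  stopifnot(methods::is(x, "SexCallBatch"))
  c(median_distance = x@median_distance, min_gap = x@min_gap)
}

setMethod("show", "SexCallBatch", function(object) {
  cat("SexCallBatch:", nrow(object@calls), "sample(s) —",
      object@n_male, "male,", object@n_female, "female\n")
  if (!is.na(object@median_distance))
    cat(sprintf("  cluster medians (ddCq): male %.3f, female %.3f; distance %.3f",
                object@male_median, object@female_median,
                object@median_distance),
        if (!is.na(object@min_gap))
          sprintf("; min gap %.3f", object@min_gap) else "", "\n", sep = "")
  if (length(object@validation))
    cat(sprintf("  validation: %d/%d correct, one-sided exact binomial p = %.3g\n",
                object@validation$n_correct, object@validation$n_total,
                object@validation$p_value))
})

#' Write per-sample calls as CSV
#'
#' @param batch a [SexCallBatch-class]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
writeCalls <- function(batch, path) {
  stopifnot(methods::is(batch, "SexCallBatch"))
  utils::write.csv(batch@calls, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a machine-readable batch report as JSON
#'
#' Includes the per-sample calls, cluster medians and separation
#' statistics, and the validation block when present.
#'
#' @param batch a [SexCallBatch-class]
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
writeReport <- function(batch, path) {
  stopifnot(methods::is(batch, "SexCallBatch"))
  rep <- list(
    n_samples = nrow(batch@calls),
    n_male = batch@n_male,
    n_female = batch@n_female,
    male_median_ddcq = batch@male_median,
    female_median_ddcq = batch@female_median,
    median_distance = batch@median_distance,
    min_gap = batch@min_gap,
    batch_flags = batch@params$batch_flags,
    calls = batch@calls
  )
  if (length(batch@validation)) rep$validation <- batch@validation
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
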