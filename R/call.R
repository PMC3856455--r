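#' CNV calling configuration
#'
#' Freezes the stringent filter cascade: a segment is a deletion
#' candidate if its mean log2 ratio is <= `loss_threshold` (-2) and an
#' amplification candidate if >= `gain_threshold` (+1), both inclusive;
#' every member probe must individually meet the directional cut-off
#' (`require_all_probes`, the "100% of probes" rule that kills single
#' outlier probes); a call needs at least `min_probes` probes and
#' `min_length_bp` (1 kb, the definitional CNV minimum).
#'
#' @param loss_threshold mean log2 at or below which a segment is a loss
#'   candidate (< 0).
#' @param gain_threshold mean log2 at or above which a segment is a gain
#'   candidate (> 0).
#' @param min_probes minimum probes per call (>= 1).
#' @param require_all_probes demand every probe pass the cut-off.
#' @param min_length_bp minimum call length in bp.
#' @return list of class `calling_config`.
#' @export
calling_config <- function(loss_threshold = -2, gain_threshold = 1,
                           min_probes = 5, require_all_probes = TRUE,
                           min_length_bp = 1000) {
  if (!(loss_threshold < 0)) stop("loss_threshold must be < 0")
  if (!(gain_threshold > 0)) stop("gain_threshold must be > 0")
  if (min_probes < 1) stop("min_probes must be >= 1")
  structure(list(loss_threshold = loss_threshold,
                 gain_threshold = gain_threshold,
                 min_probes = as.integer(min_probes),
                 require_all_probes = isTRUE(require_all_probes),
                 min_length_bp = min_length_bp),
            class = "calling_config")
}

#' Drop copy-number-neutral segments
#'
#' Retains only aberrant-mean segments: mean log2 <= loss threshold
#' (inclusive) or >= gain threshold (inclusive). Everything in the
#' neutral band is removed.
#'
#' @param segments a [segment_scan()] result.
#' @param config a [calling_config()].
#' @return the retained subset, with a `candidate_type` column
#'   (`"loss"`/`"gain"`).
#' @export
filter_segments <- function(segments, config = calling_config()) {
  .need_cols(segments, "mean_log2", "segments")
  is_loss <- segments$mean_log2 <= config$loss_threshold
  is_gain <- segments$mean_log2 >= config$gain_threshold
  out <- segments[is_loss | is_gain, , drop = FALSE]
  out$candidate_type <- ifelse(
    out$mean_log2 <= config$loss_threshold, "loss", "gain")
  rownames(out) <- NULL
  out
}

#' Probe-level (100% of probes) filter for one candidate segment
#'
#' Accepts a candidate segment only if every member probe individually
#' satisfies the directional cut-off (<= loss threshold for loss
#' candidates, >= gain threshold for gain candidates). Single-probe
#' segments are rejected outright when `min_probes > 1`: a lone extreme
#' probe is presumed an outlier, not a CNV.
#'
#' @param segment one-row segment data.frame with a `candidate_type`.
#' @param probe_ratios log2 ratios of the segment's member probes.
#' @param config a [calling_config()].
#' @return list with `accepted` (logical) and `reason` (character, `""`
#'   when accepted).
#' @export
apply_probe_level_filter <- function(segment, probe_ratios,
                                     config = calling_config()) {
  type <- segment$candidate_type
  if (length(probe_ratios) == 1 && config$min_probes > 1)
    return(list(accepted = FALSE, reason = "single outlier probe"))
  if (config$require_all_probes) {
    if (type == "loss") {
      bad <- probe_ratios > config$loss_threshold
      if (any(bad))
        return(list(accepted = FALSE,
                    reason = sprintf("probe %.6g above cut-off",
                                     probe_ratios[which(bad)[1]])))
    } else {
      bad <- probe_ratios < config$gain_threshold
      if (any(bad))
        return(list(accepted = FALSE,
                    reason = sprintf("probe %.6g below cut-off",
                                     probe_ratios[which(bad)[1]])))
    }
  }
  list(accepted = TRUE, reason = "")
}

#' Call CNVs from segments via the stringent filter cascade
#'
#' Composition of [filter_segments()], [apply_probe_level_filter()], and
#' the probe-count and length minima. Every rejection is logged with its
#' reason in the `"filter_log"` attribute of the result.
#'
#' @param segments segments for one or more samples ([segment_scan()]
#'   output, possibly row-bound).
#' @param scans a single `array_scan` or a named list of scans keyed by
#'   sample id; source of the member probe ratios.
#' @param config a [calling_config()].
#' @return `data.frame` of class `cnv_calls`, sorted by (sample, chrom,
#'   start): `sample`, `chrom`, `start`, `end`, `type`, `mean_log2`,
#'   `n_probes`, `length`, `first_probe`, `last_probe`.
#' @export
call_cnvs <- function(segments, scans, config = calling_config()) {
  if (config$loss_threshold >= 0)
    stop("inconsistent config: loss_threshold must be negative")
  .need_cols(segments,
             c("sample", "chrom", "start", "end", "first_probe",
               "last_probe", "n_probes", "mean_log2"), "segments")
  if (inherits(scans, "data.frame")) {
    nm <- attr(scans, "sample")
    scans <- stats::setNames(list(scans),
                             if (is.null(nm)) unique(segments$sample) else nm)
  }
  cand <- filter_segments(segments, config)
  keep <- logical(nrow(cand))
  reasons <- character(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    s <- cand$sample[i]
    if (!s %in% names(scans))
      stop("no scan supplied for sample ", s)
    ratios <- scans[[s]]$log2ratio[cand$first_probe[i]:cand$last_probe[i]]
    if (cand$n_probes[i] < config$min_probes) {
      reasons[i] <- if (cand$n_probes[i] == 1 && config$min_probes > 1)
        "single outlier probe" else
          sprintf("fewer than %d probes", config$min_probes)
      next
    }
    pf <- apply_probe_level_filter(cand[i, ], ratios, config)
    if (!pf$accepted) { reasons[i] <- pf$reason; next }
    if (cand$end[i] - cand$start[i] + 1 < config$min_length_bp) {
      reasons[i] <- sprintf("shorter than %d bp", config$min_length_bp)
      next
    }
    keep[i] <- TRUE
  }
  calls <- cand[keep, , drop = FALSE]
  out <- data.frame(
    sample = calls$sample, chrom = calls$chrom,
    start = calls$start, end = calls$end,
    type = calls$candidate_type, mean_log2 = calls$mean_log2,
    n_probes = calls$n_probes,
    length = calls$end - calls$start + 1,
    first_probe = calls$first_probe, last_probe = calls$last_probe,
    stringsAsFactors = FALSE)
  out <- out[order(out$sample, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_log") <- data.frame(
    sample = cand$sample, chrom = cand$chrom, start = cand$start,
    end = cand$end, accepted = keep, reason = reasons,
    stringsAsFactors = FALSE)
  structure(out, class = c("cnv_calls", "data.frame"))
}
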