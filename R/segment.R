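#' Robust noise-scale estimate and default segmentation penalty
#'
#' The penalty charged per segment is `2 * sigma^2 * log(n)` (a BIC-like
#' rule), with `sigma` estimated from the median absolute successive
#' difference of the ratios: `median(|diff(x)|) / (sqrt(2) * 0.6745)`,
#' which is immune to the (sparse) true copy-number jumps. A small floor
#' keeps the penalty positive on noiseless input, where tie-breaking
#' toward fewest segments does the rest.
#'
#' @param x numeric vector of ordered log2 ratios.
#' @return penalty (single non-negative number).
#' @export
auto_penalty <- function(x) {
  n <- length(x)
  if (n < 2) return(1e-6)
  sigma <- stats::median(abs(diff(x))) / (sqrt(2) * 0.6745)
  max(2 * sigma^2 * log(n), 1e-6)
}

#' Least-squares change-point segmentation of one chromosome
#'
#' Exact dynamic program minimizing
#' `sum of within-segment squared deviations + penalty * (#segments)`
#' over all partitions of the ordered ratio vector into contiguous
#' segments -- the documented equivalent of NimbleScan's proprietary
#' segMNT least-squares segmenter. The optimum is global. Ties (costs
#' equal to relative tolerance 1e-9) are broken toward fewer segments,
#' then toward leftmost boundaries.
#'
#' @param ratios ordered per-probe log2 ratios of a single chromosome;
#'   must be finite.
#' @param penalty per-segment penalty (>= 0), or `"auto"` for
#'   [auto_penalty()].
#' @param max_segments optional cap on the number of segments.
#' @return `data.frame` with one row per segment: `first_probe_index`,
#'   `last_probe_index` (1-based, inclusive, in input order), `n_probes`,
#'   `mean_log2`, `sse`.
#' @export
segment_chromosome <- function(ratios, penalty = "auto",
                               max_segments = NULL) {
  x <- as.numeric(ratios)
  n <- length(x)
  if (n < 1) stop("need at least one probe")
  bad <- which(!is.finite(x))
  if (length(bad))
    stop("non-finite ratio at probe index ", bad[1])
  if (identical(penalty, "auto")) penalty <- auto_penalty(x)
  if (!is.numeric(penalty) || penalty < 0)
    stop("penalty must be a non-negative number or \"auto\"")

  cs <- c(0, cumsum(x))
  css <- c(0, cumsum(x^2))
  seg_sse <- function(i, j) {           # SSE of x[(i+1)..j], i vectorized
    len <- j - i
    s <- css[j + 1] - css[i + 1] - (cs[j + 1] - cs[i + 1])^2 / len
    pmax(s, 0)
  }

  if (is.null(max_segments)) {
    F <- numeric(n + 1)                 # F[j+1]: best cost of x[1..j]
    K <- integer(n + 1)                 # segments used
    P <- integer(n + 1)                 # predecessor end index
    for (j in seq_len(n)) {
      i <- 0:(j - 1)
      cost <- F[i + 1] + seg_sse(i, j) + penalty
      m <- min(cost)
      tol <- 1e-9 * (1 + abs(m))
      cand <- which(cost <= m + tol)
      ks <- K[cand]
      cand <- cand[ks == min(ks)]
      pick <- cand[1]                   # smallest i: leftmost boundary
      F[j + 1] <- cost[pick]
      K[j + 1] <- K[pick] + 1L
      P[j + 1] <- pick - 1L
    }
    ends <- integer(0)
    j <- n
    while (j > 0) { ends <- c(j, ends); j <- P[j + 1] }
  } else {
    kmax <- min(max_segments, n)
    # Fk[k, j+1]: best cost of x[1..j] in exactly k segments
    Fk <- matrix(Inf, kmax, n + 1)
    Pk <- matrix(0L, kmax, n + 1)
    Fk[1, 2:(n + 1)] <- seg_sse(rep(0L, n), seq_len(n)) + penalty
    if (kmax > 1) for (k in 2:kmax) for (j in k:n) {
      i <- (k - 1):(j - 1)
      cost <- Fk[k - 1, i + 1] + seg_sse(i, j) + penalty
      m <- min(cost)
      pick <- which(cost <= m + 1e-9 * (1 + abs(m)))[1]
      Fk[k, j + 1] <- cost[pick]
      Pk[k, j + 1] <- i[pick]
    }
    best <- Fk[, n + 1]
    kstar <- which(best <= min(best) + 1e-9 * (1 + abs(min(best))))[1]
    ends <- integer(0)
    j <- n
    for (k in kstar:1) { ends <- c(j, ends); j <- Pk[k, j + 1] }
  }

  firsts <- c(1L, utils::head(ends, -1) + 1L)
  data.frame(
    first_probe_index = firsts,
    last_probe_index = ends,
    n_probes = ends - firsts + 1L,
    mean_log2 = (cs[ends + 1] - cs[firsts]) / (ends - firsts + 1),
    sse = seg_sse(firsts - 1L, ends)
  )
}

#' Segment a whole scan chromosome by chromosome
#'
#' Runs [segment_chromosome()] independently on each chromosome's ordered
#' ratios (segments never span chromosomes) and attaches genomic
#' coordinates from the layout.
#'
#' @param scan normalized `array_scan`.
#' @param layout matching probe layout.
#' @param penalty per-segment penalty or `"auto"` (per chromosome).
#' @return `data.frame` of class `segments`: `sample`, `chrom`, `start`,
#'   `end` (bp, 1-based inclusive, probe extents), `first_probe`,
#'   `last_probe` (global row indices into the layout),
#'   `n_probes`, `mean_log2`, `sse`.
#' @export
segment_scan <- function(scan, layout, penalty = "auto") {
  .check_scan_layout(scan, layout)
  sample_id <- attr(scan, "sample")
  if (is.null(sample_id)) sample_id <- "sample"
  chroms <- unique(layout$chrom)
  res <- lapply(chroms, function(cc) {
    rows <- which(layout$chrom == cc)
    seg <- segment_chromosome(scan$log2ratio[rows], penalty = penalty)
    data.frame(
      sample = sample_id, chrom = cc,
      start = layout$start[rows[seg$first_probe_index]],
      end = layout$end[rows[seg$last_probe_index]],
      first_probe = rows[seg$first_probe_index],
      last_probe = rows[seg$last_probe_index],
      n_probes = seg$n_probes, mean_log2 = seg$mean_log2, sse = seg$sse,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("segments", "data.frame"))
}
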