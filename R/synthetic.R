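#' Generate a tiling probe layout
#'
#' Places oligonucleotide probes along each chromosome with jittered
#' spacing (successive start-to-start gaps drawn uniformly on
#' `[0.5, 1.5] *` `median_spacing_bp`, so the median realized gap matches
#' the request) and probe lengths uniform on 50--75 bp, emulating an
#' isothermal 50--75-mer tiling design with ~500 bp median spacing.
#' Probes are assigned array grid coordinates on a near-square grid in
#' genome order and the assignment is then shuffled, so genomic and
#' spatial neighborhoods are decoupled (a spatial artifact on the array
#' does not masquerade as a genomic segment).
#'
#' @param genome a [genome_model()].
#' @param median_spacing_bp target median start-to-start distance (>= 100).
#' @param seed integer seed; identical seeds give byte-identical layouts.
#' @return `data.frame` of class `probe_layout` with columns `probe_id`,
#'   `chrom`, `start`, `end` (1-based inclusive), `length`, `grid_x`,
#'   `grid_y`, sorted by (chrom, start).
#' @export
make_probe_layout <- function(genome, median_spacing_bp = 500, seed = 1) {
  stopifnot(inherits(genome, "data.frame"))
  if (median_spacing_bp < 100) stop("median_spacing_bp must be >= 100")
  short <- genome$chrom[genome$length < median_spacing_bp]
  if (length(short))
    stop("chromosome(s) shorter than one spacing unit: ",
         paste(short, collapse = ", "))
  set.seed(as.integer(seed))
  per <- lapply(seq_len(nrow(genome)), function(i) {
    L <- genome$length[i]
    n_draw <- ceiling(L / (0.5 * median_spacing_bp)) + 10L
    gaps <- stats::runif(n_draw, 0.5, 1.5) * median_spacing_bp
    starts <- floor(cumsum(c(stats::runif(1, 1, median_spacing_bp), gaps)))
    lens <- sample(50:75, length(starts), replace = TRUE)
    keep <- (starts + lens - 1) <= L
    data.frame(chrom = genome$chrom[i],
               start = starts[keep], end = (starts + lens - 1)[keep],
               length = lens[keep], stringsAsFactors = FALSE)
  })
  lay <- do.call(rbind, per)
  n <- nrow(lay)
  side <- ceiling(sqrt(n))
  idx <- sample.int(n)                       # shuffled grid assignment
  lay$grid_x <- ((idx - 1L) %% side) + 1L
  lay$grid_y <- ((idx - 1L) %/% side) + 1L
  lay$probe_id <- sprintf("P%07d", seq_len(n))
  lay <- lay[, c("probe_id", "chrom", "start", "end", "length",
                 "grid_x", "grid_y")]
  rownames(lay) <- NULL
  structure(lay, class = c("probe_layout", "data.frame"))
}

#' Plant a truth set of copy-number events
#'
#' Draws non-overlapping loss/gain events for each sample, uniform over
#' the genome (chromosome chosen proportional to length) with lengths
#' uniform on `length_range`. Every event is required to cover at least
#' one probe midpoint; events shorter than 1 kb are not CNVs by
#' definition and are refused. Losses dominate real panels (roughly 9:1
#' against gains), hence the default `loss_fraction`. Default planted
#' log2 shifts are -2.5 (homozygous loss) and +1.2 (duplication), which
#' clear the -2/+1 calling thresholds with margin.
#'
#' @param layout a [make_probe_layout()] result.
#' @param samples character vector of sample ids.
#' @param n_events_per_sample events planted per sample (0 allowed).
#' @param length_range `c(min, max)` event length in bp; min >= 1000.
#' @param loss_fraction probability an event is a loss, in `[0, 1]`.
#' @param copy_ratio_loss,copy_ratio_gain planted log2-ratio shifts.
#' @param seed integer seed.
#' @return `data.frame` of class `truth_set`: `sample`, `chrom`, `start`,
#'   `end`, `type` (`"loss"`/`"gain"`), `copy_ratio`.
#' @export
plant_cnvs <- function(layout, samples, n_events_per_sample = 10,
                       length_range = c(1000, 10000), loss_fraction = 0.9,
                       copy_ratio_loss = -2.5, copy_ratio_gain = 1.2,
                       seed = 1) {
  .need_cols(layout, c("chrom", "start", "end"), "layout")
  if (length_range[1] < 1000)
    stop("minimum event length is 1000 bp (CNV definition)")
  if (loss_fraction < 0 || loss_fraction > 1)
    stop("loss_fraction must be in [0, 1]")
  set.seed(as.integer(seed))
  empty <- data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      type = character(), copy_ratio = numeric(),
                      stringsAsFactors = FALSE)
  if (n_events_per_sample == 0 || length(samples) == 0)
    return(structure(empty, class = c("truth_set", "data.frame")))

  chroms <- unique(layout$chrom)
  clen <- vapply(chroms, function(cc) max(layout$end[layout$chrom == cc]),
                 numeric(1))
  mid <- (layout$start + layout$end) / 2
  out <- vector("list", length(samples))
  for (s in seq_along(samples)) {
    placed <- empty[0, ]
    tries <- 0L
    while (nrow(placed) < n_events_per_sample) {
      tries <- tries + 1L
      if (tries > 500L * n_events_per_sample)
        stop("genome too small to place ", n_events_per_sample,
             " disjoint events for sample ", samples[s])
      cc <- sample(chroms, 1, prob = clen)
      len <- floor(stats::runif(1, length_range[1], length_range[2] + 1))
      if (len >= clen[[cc]]) next
      st <- floor(stats::runif(1, 1, clen[[cc]] - len + 1))
      en <- st + len - 1
      # disjoint within sample, and covering >= 1 probe midpoint
      same <- placed$chrom == cc
      if (any(same & placed$start <= en & placed$end >= st)) next
      if (!any(layout$chrom == cc & mid >= st & mid <= en)) next
      is_loss <- stats::runif(1) < loss_fraction
      placed <- rbind(placed, data.frame(
        sample = samples[s], chrom = cc, start = st, end = en,
        type = if (is_loss) "loss" else "gain",
        copy_ratio = if (is_loss) copy_ratio_loss else copy_ratio_gain,
        stringsAsFactors = FALSE))
    }
    out[[s]] <- placed
  }
  res <- do.call(rbind, out)
  res <- res[order(res$sample, res$chrom, res$start), ]
  rownames(res) <- NULL
  structure(res, class = c("truth_set", "data.frame"))
}

# internal: smooth low-order polynomial surface over normalized grid
# coordinates, used as the spatial artifact. Mean ~ 0 over a uniform grid.
.spatial_surface <- function(gx, gy, amp) {
  u <- 2 * (gx - min(gx)) / max(1, diff(range(gx))) - 1
  v <- 2 * (gy - min(gy)) / max(1, diff(range(gy))) - 1
  amp * (0.6 * u + 0.8 * v + 0.5 * u * v + 0.4 * (u^2 - 1 / 3))
}

#' Simulate one two-channel array scan
#'
#' Builds per-probe test/reference intensities for one sample. The
#' reference channel is log-normal (log2 intensities Gaussian around
#' `baseline_log2`); the test channel equals the reference shifted by the
#' planted copy ratio inside truth events. Three artifacts are layered
#' on, in order: a smooth polynomial surface in array grid coordinates
#' added to the test channel (scaled by `spatial_amp`; what LOESS spatial
#' correction must remove), a monotone intensity-dependent distortion of
#' the reference channel (scaled by `dye_bias_strength`; what q-spline
#' normalization must undo), and independent Gaussian noise of sd
#' `noise_sd/sqrt(2)` per channel, so the log2 ratio has noise sd
#' `noise_sd`. With all three set to 0 the ratios are exactly the planted
#' shifts.
#'
#' A sample absent from `truth` yields a valid event-free scan, which is
#' how self--self hybridizations are modelled.
#'
#' @param layout probe layout.
#' @param truth a [plant_cnvs()] truth set, or `NULL` for no events.
#' @param sample sample id for this scan.
#' @param noise_sd log2-ratio noise standard deviation (>= 0).
#' @param spatial_amp amplitude of the spatial surface (log2 units).
#' @param dye_bias_strength strength of the monotone dye distortion.
#' @param baseline_log2,baseline_sd location/spread of reference log2
#'   intensities.
#' @param seed integer seed.
#' @return `data.frame` of class `array_scan` with columns `probe_id`,
#'   `test`, `ref`, `log2ratio`; attributes `sample` and `stage`
#'   (`"raw"`).
#' @export
simulate_scan <- function(layout, truth = NULL, sample = "S1",
                          noise_sd = 0.15, spatial_amp = 0.1,
                          dye_bias_strength = 0.2,
                          baseline_log2 = 10, baseline_sd = 1, seed = 1) {
  .need_cols(layout, c("probe_id", "chrom", "start", "end",
                       "grid_x", "grid_y"), "layout")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(as.integer(seed))
  n <- nrow(layout)
  shift <- numeric(n)
  if (!is.null(truth) && nrow(truth)) {
    ev <- truth[truth$sample == sample, , drop = FALSE]
    if (nrow(ev)) {
      mid <- (layout$start + layout$end) / 2
      for (r in seq_len(nrow(ev))) {
        hit <- layout$chrom == ev$chrom[r] &
          mid >= ev$start[r] & mid <= ev$end[r]
        shift[hit] <- ev$copy_ratio[r]
      }
    }
  }
  ref_l2 <- stats::rnorm(n, baseline_log2, baseline_sd)
  test_l2 <- ref_l2 + shift
  if (spatial_amp != 0)
    test_l2 <- test_l2 +
      .spatial_surface(layout$grid_x, layout$grid_y, spatial_amp)
  if (dye_bias_strength != 0)
    ref_l2 <- ref_l2 + dye_bias_strength * tanh(ref_l2 - baseline_log2)
  if (noise_sd > 0) {
    test_l2 <- test_l2 + stats::rnorm(n, 0, noise_sd / sqrt(2))
    ref_l2 <- ref_l2 + stats::rnorm(n, 0, noise_sd / sqrt(2))
  }
  scan <- data.frame(probe_id = layout$probe_id,
                     test = 2^test_l2, ref = 2^ref_l2,
                     log2ratio = test_l2 - ref_l2,
                     stringsAsFactors = FALSE)
  attr(scan, "sample") <- sample
  attr(scan, "stage") <- "raw"
  class(scan) <- c("array_scan", "data.frame")
  scan
}

#' Simulate a self--self hybridization
#'
#' Both channels from the same DNA: an event-free scan in which every
#' downstream CNV call is by construction a false positive. Used as the
#' pipeline's null experiment.
#'
#' @inheritParams simulate_scan
#' @return an `array_scan` with no planted events.
#' @export
simulate_self_self <- function(layout, noise_sd = 0.15, spatial_amp = 0.1,
                               dye_bias_strength = 0.2, seed = 1) {
  sc <- simulate_scan(layout, truth = NULL, sample = "self_self",
                      noise_sd = noise_sd, spatial_amp = spatial_amp,
                      dye_bias_strength = dye_bias_strength, seed = seed)
  sc
}
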