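#' Percentage with half-up rounding
#'
#' `100 * numerator / denominator`, rounded half-up at the requested
#' number of decimals. Half-up (not banker's) rounding matches how
#' published tables print percentages.
#'
#' @param numerator,denominator counts; denominator must be > 0.
#' @param decimals decimal places (default 1).
#' @return percentage as a number (e.g. `34.4`).
#' @export
percentage <- function(numerator, denominator, decimals = 1) {
  if (any(denominator <= 0)) stop("denominator must be > 0")
  round_half_up(100 * numerator / denominator, decimals)
}

#' Panel summary of CNV calls by subspecies
#'
#' Per subspecies: number of cultivars, total calls, mean calls per
#' cultivar (1 decimal, half-up), the min-max range of per-cultivar
#' counts, and the gain/loss split.
#'
#' @param calls a `cnv_calls` data.frame.
#' @param metadata panel `data.frame(sample, subspecies, group)`.
#' @return `data.frame`: `subspecies`, `n_samples`, `total_cnvs`,
#'   `mean_per_cultivar`, `min`, `max`, `gains`, `losses`.
#' @export
summarize_panel <- function(calls, metadata) {
  .need_cols(metadata, c("sample", "subspecies"), "metadata")
  if (nrow(metadata) == 0) stop("empty panel")
  missing_s <- setdiff(unique(calls$sample), metadata$sample)
  if (length(missing_s))
    stop("call sample(s) not in metadata: ",
         paste(missing_s, collapse = ", "))
  rows <- lapply(unique(metadata$subspecies), function(s) {
    ss <- metadata$sample[metadata$subspecies == s]
    cc <- calls[calls$sample %in% ss, , drop = FALSE]
    per <- vapply(ss, function(x) sum(cc$sample == x), numeric(1))
    data.frame(subspecies = s, n_samples = length(ss),
               total_cnvs = nrow(cc),
               mean_per_cultivar = round_half_up(nrow(cc) / length(ss), 1),
               min = min(per), max = max(per),
               gains = sum(cc$type == "gain"),
               losses = sum(cc$type == "loss"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-chromosome CNVR coverage and enrichment folds
#'
#' For each chromosome: the union of CNVR intervals (no double counting
#' of overlapping regions), the percentage of the chromosome covered
#' (2 decimals, half-up), and the fold enrichment of that percentage
#' over the genome-wide percentage (2 decimals).
#'
#' @param cnvrs `data.frame` with `chrom`, `start`, `end`.
#' @param genome a [genome_model()].
#' @return `data.frame`: `chrom`, `n_cnvrs`, `cnvr_bp`, `chrom_bp`,
#'   `pct_covered`, `fold`; attribute `"genome_pct"` holds the
#'   genome-wide percentage.
#' @export
coverage_stats <- function(cnvrs, genome) {
  .need_cols(cnvrs, c("chrom", "start", "end"), "cnvrs")
  union_bp <- vapply(genome$chrom, function(cc) {
    d <- cnvrs[cnvrs$chrom == cc, , drop = FALSE]
    if (!nrow(d)) return(0)
    sum(IRanges::width(IRanges::reduce(IRanges::IRanges(d$start, d$end))))
  }, numeric(1))
  n_cnvrs <- vapply(genome$chrom,
                    function(cc) sum(cnvrs$chrom == cc), numeric(1))
  genome_pct <- percentage(sum(union_bp), sum(genome$length), 2)
  out <- data.frame(
    chrom = genome$chrom, n_cnvrs = as.integer(n_cnvrs),
    cnvr_bp = union_bp, chrom_bp = genome$length,
    pct_covered = percentage(union_bp, genome$length, 2),
    stringsAsFactors = FALSE)
  out$fold <- if (genome_pct > 0)
    round_half_up(out$pct_covered / genome_pct, 2) else NA_real_
  rownames(out) <- NULL
  attr(out, "genome_pct") <- genome_pct
  out
}

#' Compare calls with a planted truth set
#'
#' Recall is measured over "callable" truth events: those covering at
#' least `min_probes` probe midpoints and whose planted copy ratio
#' clears the directional calling threshold by at least `margin` (events
#' at the edge of detectability are excluded from the denominator, as in
#' the calling contract). A truth event is recovered if a call of the
#' same sample and type overlaps it by >= 1 bp. Precision is measured
#' over all calls: a call is a true positive if it overlaps a truth
#' event of its sample and type.
#'
#' @param calls a `cnv_calls` data.frame.
#' @param truth a [plant_cnvs()] truth set.
#' @param layout probe layout (to count probes per event).
#' @param config the [calling_config()] in force.
#' @param min_probes,margin callability bounds (defaults 5 and 0.3).
#' @return list `recall`, `precision`, `n_callable`, `n_recovered`,
#'   `n_calls`, `n_true_calls`.
#' @export
evaluate_calls <- function(calls, truth, layout,
                           config = calling_config(),
                           min_probes = 5, margin = 0.3) {
  mid <- (layout$start + layout$end) / 2
  probes_in <- vapply(seq_len(nrow(truth)), function(i)
    sum(layout$chrom == truth$chrom[i] &
          mid >= truth$start[i] & mid <= truth$end[i]), numeric(1))
  clears <- ifelse(truth$type == "loss",
                   truth$copy_ratio <= config$loss_threshold - margin,
                   truth$copy_ratio >= config$gain_threshold + margin)
  callable <- probes_in >= min_probes & clears
  hit_truth <- vapply(which(callable), function(i) {
    any(calls$sample == truth$sample[i] &
          calls$type == truth$type[i] &
          calls$chrom == truth$chrom[i] &
          calls$start <= truth$end[i] & calls$end >= truth$start[i])
  }, logical(1))
  true_call <- vapply(seq_len(nrow(calls)), function(j) {
    any(truth$sample == calls$sample[j] &
          truth$type == calls$type[j] &
          truth$chrom == calls$chrom[j] &
          truth$start <= calls$end[j] & truth$end >= calls$start[j])
  }, logical(1))
  list(recall = if (sum(callable)) mean(hit_truth) else NA_real_,
       precision = if (nrow(calls)) mean(true_call) else NA_real_,
       n_callable = sum(callable), n_recovered = sum(hit_truth),
       n_calls = nrow(calls), n_true_calls = sum(true_call))
}

#' Default pipeline configuration
#'
#' Collects every tunable of the end-to-end run in one list. Values are
#' the package defaults: 12 x 1 Mb genome, ~500 bp probe spacing, the
#' 20-cultivar panel, 10 planted events per sample at loss -2.5 / gain
#' +1.2 with 90% losses, noise sd 0.15, spatial amplitude 0.1, dye bias
#' 0.2, LOESS span 0.3, 100 quantile knots, automatic segmentation
#' penalty, and the stringent calling thresholds of
#' [calling_config()].
#'
#' @param seed base seed; per-sample seeds are derived from it.
#' @param out_dir output directory for [run_pipeline()].
#' @param ... overrides for any config entry.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("ricecnv_"), ...) {
  cfg <- list(
    seed = as.integer(seed), out_dir = out_dir,
    chrom_lengths = rep(1e6, 12), median_spacing_bp = 500,
    panel = default_panel(),
    n_events_per_sample = 10, length_range = c(1000, 10000),
    loss_fraction = 0.9, copy_ratio_loss = -2.5, copy_ratio_gain = 1.2,
    noise_sd = 0.15, spatial_amp = 0.1, dye_bias_strength = 0.2,
    span = 0.3, n_quantile_knots = 100, penalty = "auto",
    calling = calling_config(), n_self_self = 2)
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the full pipeline on synthetic data
#'
#' simulate -> spatial correction -> q-spline normalization ->
#' segmentation -> calling -> CNVR merging and validation -> genotype
#' matrix -> population statistics -> summaries. Self--self nulls are
#' run through the identical path and their call count reported. Every
#' stage writes a TSV/BED artifact into `out_dir` plus a JSON manifest
#' (parameters, seed, package version, file checksums); rerunning with
#' the same config reproduces the outputs byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with the in-memory objects: `layout`,
#'   `truth`, `calls`, `cnvrs`, `gm`, `diversity`, `panel_summary`,
#'   `coverage`, `evaluation`, `self_self_calls`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- genome_model(cfg$chrom_lengths)
  layout <- make_probe_layout(genome, cfg$median_spacing_bp,
                              seed = cfg$seed)
  truth <- plant_cnvs(layout, cfg$panel$sample,
                      n_events_per_sample = cfg$n_events_per_sample,
                      length_range = cfg$length_range,
                      loss_fraction = cfg$loss_fraction,
                      copy_ratio_loss = cfg$copy_ratio_loss,
                      copy_ratio_gain = cfg$copy_ratio_gain,
                      seed = cfg$seed + 1L)

  process_one <- function(sample_id, sc_seed, with_truth = TRUE) {
    sc <- simulate_scan(layout, truth = if (with_truth) truth else NULL,
                        sample = sample_id, noise_sd = cfg$noise_sd,
                        spatial_amp = cfg$spatial_amp,
                        dye_bias_strength = cfg$dye_bias_strength,
                        seed = sc_seed)
    sc <- spatial_correct(sc, layout, span = cfg$span)
    sc <- qspline_normalize(sc, cfg$n_quantile_knots)
    sc
  }
  scans <- list()
  segs <- list()
  for (i in seq_len(nrow(cfg$panel))) {
    sid <- cfg$panel$sample[i]
    scans[[sid]] <- process_one(sid, cfg$seed + 100L + i)
    segs[[sid]] <- segment_scan(scans[[sid]], layout,
                                penalty = cfg$penalty)
  }
  segments <- do.call(rbind, segs)
  calls <- call_cnvs(segments, scans, cfg$calling)

  # self--self nulls through the identical path
  ss_calls <- 0L
  for (j in seq_len(cfg$n_self_self)) {
    ss <- process_one(paste0("self_self_", j), cfg$seed + 900L + j,
                      with_truth = FALSE)
    attr(ss, "sample") <- paste0("self_self_", j)
    sseg <- segment_scan(ss, layout, penalty = cfg$penalty)
    sc_list <- stats::setNames(list(ss), paste0("self_self_", j))
    ss_calls <- ss_calls + nrow(call_cnvs(sseg, sc_list, cfg$calling))
  }

  cnvrs <- merge_calls(calls, panel_size = nrow(cfg$panel))
  cnvrs <- validate_cnvrs(cnvrs, layout,
                          min_probes = cfg$calling$min_probes)
  gm <- genotype_matrix(cnvrs, calls, cfg$panel)
  diversity <- cnvr_diversity(gm)
  panel_summary <- summarize_panel(calls, cfg$panel)
  coverage <- coverage_stats(cnvrs, genome)
  evaluation <- evaluate_calls(calls, truth, layout, cfg$calling)

  # artifacts
  p <- function(f) file.path(cfg$out_dir, f)
  write_probe_layout(layout, p("layout.bed"))
  write_tsv(truth, p("truth.tsv"))
  write_tsv(segments, p("segments.tsv"))
  write_tsv(calls, p("calls.tsv"))
  write_calls_bed(calls, p("calls.bed"))
  write_tsv(cnvrs, p("cnvrs.tsv"))
  write_genotype_tsv(gm, p("genotypes.tsv"))
  write_tsv(diversity, p("diversity.tsv"))
  write_tsv(panel_summary, p("panel_summary.tsv"))
  write_tsv(coverage, p("coverage.tsv"))
  ev_mat <- (gm != "N") * 1
  if (nrow(ev_mat) >= 2 && ncol(ev_mat) >= 2 &&
      all(rowSums(ev_mat^2) > 0)) {   # uncentered metric needs nonzero rows
    hc <- hierarchical_cluster(ev_mat)
    ape::write.tree(ape::as.phylo(hc), p("cultivar_dendrogram.nwk"))
  }
  files <- list.files(cfg$out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package = "ricecnv",
    version = as.character(utils::packageVersion("ricecnv")),
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), c("panel", "calling", "out_dir"))],
    calling = unclass(cfg$calling),
    n_self_self_calls = ss_calls,
    evaluation = evaluation,
    files = stats::setNames(as.list(unname(tools::md5sum(files))),
                            basename(files)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(layout = layout, truth = truth, calls = calls,
                 cnvrs = cnvrs, gm = gm, diversity = diversity,
                 panel_summary = panel_summary, coverage = coverage,
                 evaluation = evaluation, self_self_calls = ss_calls,
                 manifest = p("manifest.json")))
}
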