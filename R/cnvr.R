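#' Merge per-sample CNV calls into CNVRs
#'
#' Copy-number-variable regions are the connected components of the
#' interval-overlap graph over all samples' calls on a chromosome:
#' calls sharing at least 1 bp are chained transitively and the CNVR
#' span is their union extent. A CNVR's type is `loss` or `gain` if all
#' member calls agree, and `both` if it contains at least one call of
#' each sign.
#'
#' @param calls a `cnv_calls` data.frame (any sample order).
#' @param panel_size optional panel size for the `frequency` column
#'   (carriers / panel size); `NA` otherwise.
#' @return `data.frame` of class `cnvr`: `cnvr_id`, `chrom`, `start`,
#'   `end`, `type`, `n_carriers`, `carriers` (comma-joined sample ids),
#'   `n_calls`, `frequency`. The `"call_map"` attribute maps each input
#'   call (after sorting) to its CNVR id.
#' @export
merge_calls <- function(calls, panel_size = NULL) {
  .need_cols(calls, c("sample", "chrom", "start", "end", "type"), "calls")
  calls <- calls[order(calls$chrom, calls$start, calls$end, calls$sample), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  empty <- data.frame(cnvr_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), type = character(),
                      n_carriers = integer(), carriers = character(),
                      n_calls = integer(), frequency = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(calls))
    return(structure(empty, class = c("cnvr", "data.frame")))

  gr <- GenomicRanges::GRanges(calls$chrom,
                               IRanges::IRanges(calls$start, calls$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)  # >=1 bp overlap only
  hit <- GenomicRanges::findOverlaps(gr, red)
  grp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]

  ord <- order(as.character(GenomicRanges::seqnames(red)),
               GenomicRanges::start(red))
  rank <- match(seq_along(red), ord)
  ids <- sprintf("CNVR_%05d", rank)

  agg <- lapply(seq_along(red), function(g) {
    m <- calls[grp == g, , drop = FALSE]
    ty <- unique(m$type)
    data.frame(
      cnvr_id = ids[g],
      chrom = as.character(GenomicRanges::seqnames(red))[g],
      start = GenomicRanges::start(red)[g],
      end = GenomicRanges::end(red)[g],
      type = if (length(ty) > 1) "both" else ty,
      n_carriers = length(unique(m$sample)),
      carriers = paste(sort(unique(m$sample)), collapse = ","),
      n_calls = nrow(m),
      frequency = if (is.null(panel_size)) NA_real_ else
        length(unique(m$sample)) / panel_size,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)[order(rank), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "call_map") <- data.frame(calls[, c("sample", "chrom",
                                                "start", "end", "type")],
                                      cnvr_id = ids[grp],
                                      stringsAsFactors = FALSE)
  structure(out, class = c("cnvr", "data.frame"))
}

#' Probe re-validation of CNVRs
#'
#' Applies the probe-accounting filters used after re-mapping array
#' probes to a newer assembly: probes without exactly one perfect match
#' are struck from each CNVR's probe count, CNVRs left with fewer than
#' `min_probes` probes are discarded, and CNVRs overlapping any declared
#' assembly gap are discarded. Drop reasons are kept in the `"dropped"`
#' attribute.
#'
#' @param cnvrs a [merge_calls()] result.
#' @param layout probe layout (probe positions).
#' @param validation optional `data.frame(probe_id, n_perfect_matches)`;
#'   probes absent from the table, or with a count other than 1, do not
#'   count. `NULL` means every probe is a unique match.
#' @param gaps optional `data.frame(chrom, start, end)` of assembly gap
#'   intervals (1-based inclusive).
#' @param min_probes minimum surviving probes per CNVR (default 5).
#' @return filtered `cnvr` data.frame with an added `n_probes` column.
#' @export
validate_cnvrs <- function(cnvrs, layout, validation = NULL, gaps = NULL,
                           min_probes = 5) {
  .need_cols(cnvrs, c("cnvr_id", "chrom", "start", "end"), "cnvrs")
  .need_cols(layout, c("probe_id", "chrom", "start", "end"), "layout")
  ok_probe <- rep(TRUE, nrow(layout))
  if (!is.null(validation)) {
    .need_cols(validation, c("probe_id", "n_perfect_matches"), "validation")
    m <- validation$n_perfect_matches[match(layout$probe_id,
                                            validation$probe_id)]
    ok_probe <- !is.na(m) & m == 1
  }
  lev <- unique(c(layout$chrom, cnvrs$chrom))
  pg <- .gr(layout, lev)
  rg <- .gr(cnvrs, lev)
  hits <- GenomicRanges::findOverlaps(rg, pg)
  valid_n <- tabulate(
    S4Vectors::queryHits(hits)[ok_probe[S4Vectors::subjectHits(hits)]],
    nbins = nrow(cnvrs))
  cnvrs$n_probes <- valid_n

  drop_reason <- rep("", nrow(cnvrs))
  drop_reason[valid_n < min_probes] <-
    sprintf("fewer than %d valid probes", min_probes)
  if (!is.null(gaps) && nrow(gaps)) {
    .need_cols(gaps, c("chrom", "start", "end"), "gaps")
    gg <- .gr(gaps, unique(c(lev, gaps$chrom)))
    in_gap <- IRanges::overlapsAny(rg, gg)
    drop_reason[in_gap & drop_reason == ""] <- "gap overlap"
  }
  keep <- drop_reason == ""
  out <- cnvrs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- data.frame(
    cnvr_id = cnvrs$cnvr_id[!keep], reason = drop_reason[!keep],
    stringsAsFactors = FALSE)
  attr(out, "call_map") <- attr(cnvrs, "call_map")
  structure(out, class = c("cnvr", "data.frame"))
}

#' Build the sample-by-CNVR genotype matrix
#'
#' Simplifies per-sample copy-number phenotypes into three categories --
#' normal (`"N"`), loss (`"L"`), gain (`"G"`) -- one entry per sample and
#' CNVR. Complex CNVRs (type `both`) stay in the matrix but are listed in
#' the `excluded_complex` attribute and skipped by the population
#' statistics.
#'
#' @param cnvrs validated `cnvr` data.frame.
#' @param calls the `cnv_calls` the CNVRs were merged from.
#' @param panel panel metadata `data.frame(sample, subspecies, group)`;
#'   every call's sample must appear here.
#' @return character matrix of class `genotype_matrix` (samples x CNVRs,
#'   values `"N"/"L"/"G"`) with attributes `panel`, `excluded_complex`,
#'   and `frequency` (per-CNVR carrier frequency).
#' @export
genotype_matrix <- function(cnvrs, calls, panel) {
  .need_cols(panel, c("sample", "subspecies", "group"), "panel")
  missing_s <- setdiff(unique(calls$sample), panel$sample)
  if (length(missing_s))
    stop("sample(s) in calls but absent from panel metadata: ",
         paste(missing_s, collapse = ", "))
  gm <- matrix("N", nrow = nrow(panel), ncol = nrow(cnvrs),
               dimnames = list(panel$sample, cnvrs$cnvr_id))
  if (nrow(cnvrs) && nrow(calls)) {
    lev <- unique(c(calls$chrom, cnvrs$chrom))
    cg <- .gr(calls, lev)
    rg <- .gr(cnvrs, lev)
    hits <- GenomicRanges::findOverlaps(cg, rg)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    for (h in seq_along(qi)) {
      s <- calls$sample[qi[h]]
      v <- if (calls$type[qi[h]] == "loss") "L" else "G"
      cur <- gm[s, si[h]]
      # a sample with both signs in one (complex) region: losses win the
      # matrix entry; the region is excluded from statistics anyway
      gm[s, si[h]] <- if (cur == "N" || cur == v) v else "L"
    }
  }
  freq <- colMeans(gm != "N")
  attr(gm, "panel") <- panel
  attr(gm, "excluded_complex") <- cnvrs$cnvr_id[cnvrs$type == "both"]
  attr(gm, "frequency") <- freq
  class(gm) <- c("genotype_matrix", class(gm))
  gm
}
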