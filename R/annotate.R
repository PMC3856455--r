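#' Gene overlap with CNVRs
#'
#' Classifies every gene as `wholly_contained` (its interval lies inside
#' some single CNVR, non-strictly), `partial` (>= 1 bp overlap but not
#' contained), or `none`. The three statuses are mutually exclusive and
#' exhaustive. Also returns, per CNVR, the list of overlapped genes.
#'
#' @param cnvrs `data.frame` with `cnvr_id`, `chrom`, `start`, `end`.
#' @param genes `data.frame` with `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive; see [read_gene_models()]).
#' @return `data.frame` `gene_id`, `status`; attribute `"cnvr_genes"` is
#'   a named list CNVR id -> character vector of gene ids.
#' @export
gene_overlap <- function(cnvrs, genes) {
  .need_cols(genes, c("gene_id", "chrom", "start", "end"), "genes")
  lev <- unique(c(genes$chrom, cnvrs$chrom))
  g <- .gr(genes, lev)
  r <- .gr(cnvrs, lev)
  contained <- IRanges::overlapsAny(g, r, type = "within")
  touched <- IRanges::overlapsAny(g, r)
  status <- ifelse(contained, "wholly_contained",
                   ifelse(touched, "partial", "none"))
  hits <- GenomicRanges::findOverlaps(r, g)
  per_cnvr <- split(genes$gene_id[S4Vectors::subjectHits(hits)],
                    cnvrs$cnvr_id[S4Vectors::queryHits(hits)])
  out <- data.frame(gene_id = genes$gene_id, status = status,
                    stringsAsFactors = FALSE)
  attr(out, "cnvr_genes") <- per_cnvr
  out
}

#' CNVR overlap with segmental duplications
#'
#' @param cnvrs `data.frame` with `chrom`, `start`, `end`.
#' @param sd_intervals segmental-duplication intervals (`chrom`,
#'   `start`, `end`, 1-based inclusive). Overlap means >= 1 bp shared.
#' @return list `n_overlap`, `n_total`, `fraction_pct` (percent, 2
#'   decimals, half-up).
#' @export
sd_overlap <- function(cnvrs, sd_intervals) {
  n_total <- nrow(cnvrs)
  if (is.null(sd_intervals) || nrow(sd_intervals) == 0)
    return(list(n_overlap = 0L, n_total = n_total, fraction_pct = 0))
  lev <- unique(c(cnvrs$chrom, sd_intervals$chrom))
  r <- .gr(cnvrs, lev)
  s <- .gr(sd_intervals, lev)
  n <- sum(IRanges::overlapsAny(r, s))
  list(n_overlap = n, n_total = n_total,
       fraction_pct = percentage(n, n_total, 2))
}

#' Repeat/TE content of deleted regions, per chromosome
#'
#' For each chromosome: the number of regions, their total bp, the bp
#' masked by repeats (overlapping repeat features are unioned first, so
#' no nucleotide is counted twice and the percentage cannot exceed 100),
#' and the masked percentage at 1 decimal. Per-class tallies are
#' attached: how many regions contain >= 1 feature of each repeat class
#' (region-level) and how many features of each class fall in regions
#' (feature-level).
#'
#' @param regions deleted regions, `data.frame(chrom, start, end)`.
#' @param repeats repeat features, `data.frame(chrom, start, end,
#'   class)` (see [read_repeatmasker()]).
#' @return `data.frame`: `chrom`, `n_regions`, `total_bp`, `repeat_bp`,
#'   `repeat_pct`; attributes `"class_regions"` and `"class_features"`.
#' @export
repeat_content <- function(regions, repeats) {
  .need_cols(regions, c("chrom", "start", "end"), "regions")
  .need_cols(repeats, c("chrom", "start", "end", "class"), "repeats")
  lev <- unique(c(regions$chrom, repeats$chrom))
  rg <- .gr(regions, lev)
  rp <- GenomicRanges::reduce(.gr(repeats, lev))
  chroms <- unique(regions$chrom)
  rows <- lapply(chroms, function(cc) {
    rr <- rg[as.character(GenomicRanges::seqnames(rg)) == cc]
    total <- sum(GenomicRanges::width(rr))
    masked <- sum(GenomicRanges::width(
      GenomicRanges::intersect(GenomicRanges::reduce(rr), rp)))
    data.frame(chrom = cc, n_regions = length(rr), total_bp = total,
               repeat_bp = masked,
               repeat_pct = percentage(masked, total, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL

  rpf <- .gr(repeats, lev)
  classes <- sort(unique(repeats$class))
  class_regions <- vapply(classes, function(cl)
    sum(IRanges::overlapsAny(rg, rpf[repeats$class == cl])),
    integer(1))
  class_features <- vapply(classes, function(cl)
    sum(IRanges::overlapsAny(rpf[repeats$class == cl], rg)),
    integer(1))
  attr(out, "class_regions") <- class_regions
  attr(out, "class_features") <- class_features
  out
}

# internal: RepeatMasker class/family string -> coarse class
.rm_class <- function(x) {
  base <- sub("/.*$", "", x)
  ifelse(base == "LINE", "LINE",
  ifelse(base == "SINE", "SINE",
  ifelse(base == "LTR", "LTR",
  ifelse(base == "DNA", "DNA",
  ifelse(base %in% c("Simple_repeat", "Low_complexity"), "simple",
         "other")))))
}

#' Read repeat annotations (RepeatMasker .out or BED)
#'
#' Parses the classic RepeatMasker `.out` dialect (3 header lines, then
#' whitespace-delimited records with query name/begin/end in fields 5-7
#' and the repeat class/family in field 11) or, for `.bed` files, a BED
#' whose name column carries the class string. Class strings are mapped
#' to the coarse classes `LINE`, `SINE`, `LTR`, `DNA`, `simple`
#' (Simple_repeat / Low_complexity), `other`.
#'
#' @param path file path.
#' @return `data.frame(chrom, start, end, class)`, coordinates 1-based
#'   inclusive.
#' @export
read_repeatmasker <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    b <- read_bed_intervals(path)
    b$class <- .rm_class(if ("name" %in% names(b)) b$name else "other")
    return(b[, c("chrom", "start", "end", "class")])
  }
  lines <- readLines(path)
  body <- lines[-seq_len(min(3L, length(lines)))]
  keep <- which(nzchar(trimws(body)))
  rows <- lapply(keep, function(i) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(f) < 11)
      stop("malformed RepeatMasker line ", i + 3L, " in ", path)
    st <- suppressWarnings(as.numeric(f[6]))
    en <- suppressWarnings(as.numeric(f[7]))
    if (is.na(st) || is.na(en))
      stop("malformed RepeatMasker line ", i + 3L, " in ", path)
    data.frame(chrom = f[5], start = st, end = en,
               class = .rm_class(f[11]), stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               class = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
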