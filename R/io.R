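# On-disk conventions: BED is 0-based half-open; everything in memory is
# 1-based inclusive. TSVs carry a header line; BEDs never do.

#' Write/read a probe layout as BED-like TSV
#'
#' Columns: chrom, start0 (0-based), end, probe_id, length, grid_x,
#' grid_y. No header.
#'
#' @param layout a [make_probe_layout()] result.
#' @param path file path.
#' @return `read_probe_layout` returns a `probe_layout` data.frame.
#' @export
write_probe_layout <- function(layout, path) {
  out <- data.frame(layout$chrom, layout$start - 1, layout$end,
                    layout$probe_id, layout$length,
                    layout$grid_x, layout$grid_y)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_layout
#' @export
read_probe_layout <- function(path) {
  d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                         col.names = c("chrom", "start0", "end",
                                       "probe_id", "length",
                                       "grid_x", "grid_y"))
  lay <- data.frame(probe_id = d$probe_id, chrom = d$chrom,
                    start = d$start0 + 1, end = d$end, length = d$length,
                    grid_x = d$grid_x, grid_y = d$grid_y,
                    stringsAsFactors = FALSE)
  structure(lay, class = c("probe_layout", "data.frame"))
}

#' Write/read an array scan as TSV
#'
#' A `# sample=<id> stage=<stage>` comment line precedes the header.
#'
#' @param scan an `array_scan`.
#' @param path file path.
#' @return `read_scan_tsv` returns an `array_scan`.
#' @export
write_scan_tsv <- function(scan, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample=%s stage=%s",
                     attr(scan, "sample"), attr(scan, "stage")), con)
  utils::write.table(scan, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_scan_tsv
#' @export
read_scan_tsv <- function(path) {
  hdr <- readLines(path, n = 1)
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         comment.char = "#", stringsAsFactors = FALSE)
  m <- regmatches(hdr, regexec("sample=(\\S+) stage=(\\S+)", hdr))[[1]]
  if (length(m) == 3) {
    attr(d, "sample") <- m[2]
    attr(d, "stage") <- m[3]
  }
  class(d) <- c("array_scan", "data.frame")
  d
}

#' Write CNV calls as BED
#'
#' chrom, start0, end, name (`sample:type`), score (mean log2). No
#' header.
#'
#' @param calls a `cnv_calls` data.frame.
#' @param path file path.
#' @export
write_calls_bed <- function(calls, path) {
  name <- if (nrow(calls)) paste0(calls$sample, ":", calls$type)
          else character(0)
  out <- data.frame(calls$chrom, calls$start - 1, calls$end,
                    name, calls$mean_log2)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read plain interval BED into 1-based inclusive coordinates
#'
#' @param path a BED file (>= 3 columns; a 4th becomes `name`).
#' @return `data.frame(chrom, start, end[, name])`.
#' @export
read_bed_intervals <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  nm <- gr$name
  if (!is.null(nm)) out$name <- nm
  out
}

#' Read gene models from GFF3 or BED
#'
#' GFF3: features of type `gene` (or all features when none is typed
#' `gene`), with `gene_id` taken from the `ID` or `Name` attribute.
#' BED: the name column is the gene id.
#'
#' @param path file path ending in `.gff`, `.gff3`, or `.bed`.
#' @return `data.frame(gene_id, chrom, start, end)`, 1-based inclusive.
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "GFF3")
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(gr$type == "gene")) gr <- gr[gr$type == "gene"]
    id <- gr$ID
    if (is.null(id) || all(is.na(id))) id <- gr$Name
    data.frame(gene_id = as.character(id),
               chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr),
               stringsAsFactors = FALSE)
  } else {
    b <- read_bed_intervals(path)
    data.frame(gene_id = b$name, chrom = b$chrom, start = b$start,
               end = b$end, stringsAsFactors = FALSE)
  }
}

#' Write a genotype matrix as TSV (samples x CNVRs, values N/L/G)
#'
#' @param gm a [genotype_matrix()].
#' @param path file path.
#' @export
write_genotype_tsv <- function(gm, path) {
  d <- data.frame(sample = rownames(gm),
                  as.data.frame(unclass(gm)[, , drop = FALSE]),
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# internal: generic TSV writer with header
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
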