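#' Define a genome model
#'
#' A genome model is the coordinate skeleton shared by all arrays: an
#' ordered set of chromosomes with lengths in base pairs. The default is a
#' desk-scale stand-in for a 12-chromosome rice genome (1 Mb per
#' chromosome) small enough that the whole pipeline runs in seconds but
#' large enough to hold thousands of probes per chromosome.
#'
#' @param lengths integer vector of chromosome lengths in bp (all > 0).
#' @param names chromosome names; must be unique. Defaults to
#'   `chr01..chrNN`.
#' @return a `data.frame` with columns `chrom`, `length`, of class
#'   `genome_model`.
#' @examples
#' g <- genome_model()
#' nrow(g)       # 12
#' sum(g$length) # 12 Mb
#' @export
genome_model <- function(lengths = rep(1e6, 12),
                         names = sprintf("chr%02d", seq_along(lengths))) {
  lengths <- as.numeric(lengths)
  if (length(lengths) < 1L || any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive and finite")
  if (length(names) != length(lengths))
    stop("'names' and 'lengths' must have equal length")
  if (anyDuplicated(names))
    stop("chromosome names must be unique: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  structure(
    data.frame(chrom = as.character(names), length = lengths,
               stringsAsFactors = FALSE),
    class = c("genome_model", "data.frame")
  )
}

#' Default 20-cultivar panel metadata
#'
#' Sample sheet for a rice diversity panel of 20 cultivars: two subspecies
#' (indica, japonica) subdivided into six groups -- indica (6) and aus (3)
#' within ssp. indica; rayada (2), aromatic (2), tropical japonica (3) and
#' temperate japonica (4) within ssp. japonica. Sample names are synthetic.
#'
#' @return `data.frame` with columns `sample`, `subspecies`, `group`.
#' @export
default_panel <- function() {
  grp <- c(rep("indica", 6), rep("aus", 3),
           rep("rayada", 2), rep("aromatic", 2),
           rep("tropical_japonica", 3), rep("temperate_japonica", 4))
  ssp <- ifelse(grp %in% c("indica", "aus"), "indica", "japonica")
  tag <- c(sprintf("IND%02d", 1:6), sprintf("AUS%02d", 1:3),
           sprintf("RAY%02d", 1:2), sprintf("ARO%02d", 1:2),
           sprintf("TRJ%02d", 1:3), sprintf("TEJ%02d", 1:4))
  data.frame(sample = tag, subspecies = ssp, group = grp,
             stringsAsFactors = FALSE)
}

# internal: stop unless 'df' has all columns in 'cols'
.need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}

# internal: GRanges over a shared seqlevel universe, so overlap ops
# between interval sets from different sources do not warn
.gr <- function(df, levels = unique(df$chrom)) {
  GenomicRanges::GRanges(factor(df$chrom, levels = levels),
                         IRanges::IRanges(df$start, df$end))
}

# internal: half-up rounding at 'digits' decimals (round() is banker's)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
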