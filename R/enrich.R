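#' Upper-tail hypergeometric p-value
#'
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` annotated genes when `n` genes are sampled
#' without replacement from a background of `N` genes of which `K` carry
#' the annotation. Computed via `phyper` on the log scale internally for
#' numerical stability.
#'
#' @param k observed hits in the study set.
#' @param n study set size.
#' @param K hits in the background.
#' @param N background size.
#' @return p-value in `(0, 1]`.
#' @export
hypergeom_pvalue <- function(k, n, K, N) {
  if (k < 0 || k > n || k > K || n > N || K > N)
    stop("inconsistent counts: need 0 <= k <= min(n, K), n <= N, K <= N")
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE,
                    log.p = TRUE))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: with `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} ( p_(j) * m / j )`, capped at 1, mapped back to
#' the input order. Order-preserving: `q` is a monotone function of `p`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must be in [0, 1]")
  m <- length(p_values)
  if (m == 0) return(numeric(0))
  o <- order(p_values)
  q <- pmin(1, rev(cummin(rev(p_values[o] * m / seq_len(m)))))
  q[order(o)]
}

#' Hypergeometric GO enrichment of a gene set
#'
#' Over-representation of GO terms among study genes, relative to a
#' genome background, mirroring the bookkeeping of GO enrichment tools:
#' only genes with at least one annotation enter the study size `n` and
#' background size `N`; one result per term with at least one study hit;
#' q-values by [bh_fdr()] over the tested terms. Annotations are used as
#' given (no GO-graph ancestor propagation).
#'
#' @param study_genes character vector; must be a subset of
#'   `background_genes`.
#' @param background_genes character vector of all genes considered.
#' @param go_map `data.frame(gene, term)`: one row per annotation pair.
#' @return `data.frame` sorted by (`q`, `p`): `term`, `k`, `n`, `K`,
#'   `N`, `p`, `q`. Empty (with a warning) if no study gene is
#'   annotated.
#' @export
enrich_genes <- function(study_genes, background_genes, go_map) {
  extra <- setdiff(study_genes, background_genes)
  if (length(extra))
    stop("study genes absent from background: ",
         paste(utils::head(extra, 3), collapse = ", "))
  .need_cols(go_map, c("gene", "term"), "go_map")
  go_map <- unique(go_map[go_map$gene %in% background_genes, ,
                          drop = FALSE])
  annotated <- unique(go_map$gene)
  N <- length(annotated)
  study_ann <- intersect(study_genes, annotated)
  n <- length(study_ann)
  if (n == 0) {
    warning("no study gene carries a GO annotation")
    return(data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE))
  }
  K_all <- table(go_map$term)
  k_all <- table(go_map$term[go_map$gene %in% study_ann])
  terms <- names(k_all)
  res <- data.frame(
    term = terms,
    k = as.integer(k_all),
    n = n,
    K = as.integer(K_all[terms]),
    N = N,
    stringsAsFactors = FALSE)
  res$p <- mapply(hypergeom_pvalue, res$k, res$n, res$K, res$N)
  res$q <- bh_fdr(res$p)
  res <- res[order(res$q, res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}
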