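#' Category frequencies of one CNVR
#'
#' Frequency of the normal/loss/gain categories among a set of samples,
#' treating the three categories as alleles of one triallelic locus.
#'
#' @param states character vector of `"N"/"L"/"G"` states (one CNVR
#'   column of a genotype matrix).
#' @param subset optional names/indices selecting the samples to count.
#' @return named numeric vector `c(normal, loss, gain)` summing to 1.
#' @export
category_frequencies <- function(states, subset = NULL) {
  if (!is.null(subset)) states <- states[subset]
  if (length(states) == 0) stop("empty sample subset")
  n <- length(states)
  c(normal = sum(states == "N") / n,
    loss = sum(states == "L") / n,
    gain = sum(states == "G") / n)
}

#' Nei gene diversity
#'
#' `He = 1 - sum(p_i^2)`: the probability that two alleles drawn at
#' random differ. For k categories, `0 <= He <= 1 - 1/k`.
#'
#' @param p frequency vector summing to 1 (non-negative).
#' @return He (single number).
#' @export
heterozygosity <- function(p) {
  if (any(p < 0)) stop("negative frequency")
  if (abs(sum(p) - 1) > 1e-6) stop("frequencies must sum to 1")
  1 - sum(p^2)
}

#' Fst from per-subspecies category frequencies
#'
#' `Fst = 1 - Hs/Ht`, with `Hs` the unweighted mean of within-subspecies
#' gene diversities and `Ht` the gene diversity of the pooled,
#' size-weighted frequency vector. A locus monomorphic everywhere
#' (`Ht = 0`) returns `Fst = 0` by convention. `Hs` can be switched to a
#' size-weighted mean, and `Ht` to the unweighted mean-of-frequencies
#' definition.
#'
#' @param p_list list of per-subspecies frequency vectors (>= 2).
#' @param sizes subspecies sample sizes (same length).
#' @param weighted_hs average Hs by sample size instead of unweighted.
#' @param pooled_ht compute Ht from the size-weighted pooled frequencies
#'   (default) rather than the unweighted mean frequency vector.
#' @return named list `Hs`, `Ht`, `Fst`.
#' @export
fst <- function(p_list, sizes, weighted_hs = FALSE, pooled_ht = TRUE) {
  if (length(p_list) < 2) stop("need >= 2 subspecies")
  if (length(sizes) != length(p_list)) stop("sizes/p_list length mismatch")
  he <- vapply(p_list, heterozygosity, numeric(1))
  hs <- if (weighted_hs) sum(he * sizes) / sum(sizes) else mean(he)
  w <- if (pooled_ht) sizes / sum(sizes) else
    rep(1 / length(p_list), length(p_list))
  pbar <- Reduce(`+`, Map(`*`, p_list, w))
  ht <- heterozygosity(pbar)
  list(Hs = hs, Ht = ht, Fst = if (ht > 0) 1 - hs / ht else 0)
}

#' Per-CNVR diversity table (He by subspecies, Hs, Ht, Fst)
#'
#' Applies [category_frequencies()], [heterozygosity()] and [fst()] to
#' every non-complex CNVR column of a genotype matrix, splitting samples
#' by subspecies. Monomorphic columns are kept but flagged.
#'
#' @param gm a [genotype_matrix()].
#' @param polymorphic_only drop monomorphic CNVRs (any column with a
#'   single observed category). Default `FALSE`.
#' @return `data.frame`: `cnvr_id`, one `He_<subspecies>` column per
#'   subspecies, `Hs`, `Ht`, `Fst`, `polymorphic`.
#' @export
cnvr_diversity <- function(gm, polymorphic_only = FALSE) {
  panel <- attr(gm, "panel")
  excl <- attr(gm, "excluded_complex")
  ids <- setdiff(colnames(gm), excl)
  ssp <- sort(unique(panel$subspecies))
  if (length(ids) == 0) {
    res <- data.frame(cnvr_id = character(), stringsAsFactors = FALSE)
    for (s in ssp) res[[paste0("He_", s)]] <- numeric(0)
    res$Hs <- numeric(0); res$Ht <- numeric(0); res$Fst <- numeric(0)
    res$polymorphic <- logical(0)
    return(res)
  }
  rows <- lapply(ids, function(id) {
    col <- gm[, id]
    pl <- lapply(ssp, function(s)
      category_frequencies(col, panel$sample[panel$subspecies == s]))
    sizes <- vapply(ssp, function(s) sum(panel$subspecies == s), numeric(1))
    f <- fst(pl, sizes)
    he <- vapply(pl, heterozygosity, numeric(1))
    out <- data.frame(cnvr_id = id, stringsAsFactors = FALSE)
    for (i in seq_along(ssp)) out[[paste0("He_", ssp[i])]] <- he[i]
    out$Hs <- f$Hs; out$Ht <- f$Ht; out$Fst <- f$Fst
    out$polymorphic <- length(unique(col)) > 1
    out
  })
  res <- do.call(rbind, rows)
  if (polymorphic_only) res <- res[res$polymorphic, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify CNVRs as subspecies-specific or shared
#'
#' A CNVR is `indica-only` (resp. `japonica-only`) iff every carrier
#' belongs to that subspecies, and `shared` otherwise; CNVRs carried by
#' exactly one cultivar are additionally flagged `unique`. Complex CNVRs
#' are excluded. The summary attribute reports, per subspecies, how many
#' specific CNVRs are unique to one cultivar.
#'
#' @param gm a [genotype_matrix()].
#' @return `data.frame`: `cnvr_id`, `class` (`indica-only`,
#'   `japonica-only`, `shared`), `n_carriers`, `unique`; attribute
#'   `"summary"` with per-class totals and unique counts.
#' @export
subspecies_specific <- function(gm) {
  panel <- attr(gm, "panel")
  excl <- attr(gm, "excluded_complex")
  ids <- setdiff(colnames(gm), excl)
  res <- lapply(ids, function(id) {
    carriers <- rownames(gm)[gm[, id] != "N"]
    ssp <- unique(panel$subspecies[match(carriers, panel$sample)])
    cls <- if (length(ssp) == 1) paste0(ssp, "-only") else "shared"
    data.frame(cnvr_id = id, class = cls,
               n_carriers = length(carriers),
               unique = length(carriers) == 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  sm <- do.call(rbind, lapply(split(out, out$class), function(d)
    data.frame(class = d$class[1], n = nrow(d), n_unique = sum(d$unique),
               stringsAsFactors = FALSE)))
  rownames(sm) <- NULL
  attr(out, "summary") <- sm
  out
}

#' Screen CNVRs for high frequency differences among groups
#'
#' For every non-complex CNVR, computes the carrier (event) frequency in
#' each group and the largest pairwise difference between group
#' frequencies; CNVRs at or above `min_diff` are returned, sorted by
#' difference (descending). The full per-group frequency table is
#' attached as the `"group_freq"` attribute.
#'
#' @param gm a [genotype_matrix()].
#' @param min_diff screening threshold on the max pairwise group
#'   frequency difference, default 0.8.
#' @return `data.frame`: `cnvr_id`, `max_diff`, one `freq_<group>`
#'   column per group.
#' @export
group_frequency_screen <- function(gm, min_diff = 0.8) {
  panel <- attr(gm, "panel")
  excl <- attr(gm, "excluded_complex")
  ids <- setdiff(colnames(gm), excl)
  groups <- unique(panel$group)
  freq <- vapply(groups, function(g) {
    s <- panel$sample[panel$group == g]
    colMeans(gm[s, ids, drop = FALSE] != "N")
  }, numeric(length(ids)))
  freq <- matrix(freq, nrow = length(ids),
                 dimnames = list(ids, groups))
  max_diff <- apply(freq, 1, function(r) max(r) - min(r))
  tab <- data.frame(cnvr_id = ids, max_diff = max_diff,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (g in groups) tab[[paste0("freq_", g)]] <- freq[, g]
  out <- tab[tab$max_diff >= min_diff, , drop = FALSE]
  out <- out[order(-out$max_diff, out$cnvr_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "group_freq") <- tab
  attr(out, "min_diff") <- min_diff
  out
}

#' Uncentered-correlation distance matrix
#'
#' `d(u, v) = 1 - sum(u*v) / (||u|| * ||v||)`: one minus the cosine of
#' the angle between rows, without mean-centering. Scale-invariant
#' (a row and its positive multiple are at distance 0).
#'
#' @param mat numeric matrix, items in rows.
#' @return symmetric distance matrix with zero diagonal.
#' @export
uncentered_cor_dist <- function(mat) {
  mat <- as.matrix(mat)
  nrm <- sqrt(rowSums(mat^2))
  zero <- which(nrm == 0)
  if (length(zero))
    stop("zero-norm row: ",
         if (is.null(rownames(mat))) zero[1] else rownames(mat)[zero[1]])
  s <- tcrossprod(mat / nrm)
  d <- 1 - s
  d[d < 0] <- 0                # numerical guard; identical rows -> 0
  diag(d) <- 0
  d
}

#' Average-linkage hierarchical clustering on uncentered correlation
#'
#' UPGMA agglomeration: at each step the two clusters with the smallest
#' average pairwise (original) distance between their members are
#' merged; the merge height is that average. Ties are broken toward the
#' pair with the smallest cluster indices (creation order). Returns a
#' standard `hclust` object, so `plot()`, `cutree()` and
#' `ape::as.phylo()` work directly.
#'
#' @param mat numeric matrix; rows are the items to cluster (use `t()`
#'   to cluster columns). Needs >= 2 rows; zero-norm rows are an error.
#' @return object of class `hclust`.
#' @export
hierarchical_cluster <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 2) stop("need >= 2 items to cluster")
  labels <- rownames(mat)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  d0 <- uncentered_cor_dist(mat)

  members <- as.list(seq_len(n))        # original items per active cluster
  cl_id <- -seq_len(n)                  # hclust coding: -i singleton
  active <- rep(TRUE, n + 0L)
  D <- d0
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    best <- c(NA, NA); bd <- Inf
    for (a in seq_along(idx)) for (b in seq_len(a - 1L)) {
      i <- idx[b]; j <- idx[a]          # i < j in active order
      if (D[i, j] < bd - 1e-12) { bd <- D[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort(c(cl_id[i], cl_id[j]))
    height[step] <- bd
    # UPGMA: new cluster keeps averages of ORIGINAL pairwise distances
    newm <- c(members[[i]], members[[j]])
    for (k in which(active)) if (k != i && k != j)
      D[i, k] <- D[k, i] <- mean(d0[newm, members[[k]]])
    members[[i]] <- newm
    cl_id[i] <- step
    active[j] <- FALSE
  }
  ord <- local({
    rec <- function(k) if (k < 0) -k else c(rec(merge[k, 1]),
                                            rec(merge[k, 2]))
    rec(n - 1L)
  })
  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, method = "average",
                 call = match.call(),
                 dist.method = "uncentered correlation"),
            class = "hclust")
}

#' One-way fixed-effects ANOVA
#'
#' Classic between/within decomposition: `F = (SSB/(g-1)) / (SSW/(N-g))`
#' with the p-value from the F distribution. Degenerate all-identical
#' input returns `F = 0`, `p = 1`.
#'
#' @param values numeric response (e.g. CNV lengths).
#' @param groups grouping factor (e.g. cultivar), >= 2 levels.
#' @return list `F`, `p`, `df1`, `df2`.
#' @export
anova_cnv_length <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  N <- length(values)
  g <- nlevels(groups)
  if (N - g < 1) stop("need >= 2 residual degrees of freedom")
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  grand <- mean(values)
  ssb <- sum(gn * (gm - grand)^2)
  ssw <- sum((values - gm[groups])^2)
  if (ssw == 0 && ssb == 0) return(list(F = 0, p = 1, df1 = g - 1,
                                        df2 = N - g))
  f <- (ssb / (g - 1)) / (ssw / (N - g))
  list(F = f, p = stats::pf(f, g - 1, N - g, lower.tail = FALSE),
       df1 = g - 1, df2 = N - g)
}
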