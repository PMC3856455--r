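# small genotype matrix with known structure, bypassing the pipeline
toy_gm <- function() {
  panel <- data.frame(
    sample = c(paste0("I", 1:3), paste0("J", 1:3)),
    subspecies = rep(c("indica", "japonica"), each = 3),
    group = c("indica", "indica", "aus", "rayada", "aromatic", "rayada"),
    stringsAsFactors = FALSE)
  gm <- rbind(
    I1 = c("L", "L", "N", "N"),
    I2 = c("L", "N", "N", "N"),
    I3 = c("L", "N", "N", "N"),
    J1 = c("N", "N", "G", "N"),
    J2 = c("N", "L", "G", "N"),
    J3 = c("N", "N", "G", "N"))
  colnames(gm) <- paste0("R", 1:4)
  attr(gm, "panel") <- panel
  attr(gm, "excluded_complex") <- character(0)
  class(gm) <- c("genotype_matrix", class(gm))
  gm
}

test_that("category frequencies count correctly and sum to one", {
  expect_equal(category_frequencies(rep("N", 9)),
               c(normal = 1, loss = 0, gain = 0))
  expect_equal(category_frequencies(c(rep("N", 6), rep("L", 4))),
               c(normal = 0.6, loss = 0.4, gain = 0))
  p <- category_frequencies(c(rep("N", 12), rep("L", 6), rep("G", 2)))
  expect_equal(unname(p), c(0.6, 0.3, 0.1))
  expect_equal(sum(p), 1)
  expect_error(category_frequencies(character(0)), "empty")
})

test_that("Nei gene diversity matches closed forms and bounds", {
  expect_equal(heterozygosity(c(1, 0, 0)), 0)
  expect_equal(heterozygosity(c(0.5, 0.5, 0)), 0.5)
  expect_equal(heterozygosity(c(0.6, 0.3, 0.1)), 0.54)
  expect_error(heterozygosity(c(-0.1, 1.1, 0)), "negative")
  # 0 <= He <= 1 - 1/k over random frequency vectors
  set.seed(10)
  for (i in 1:50) {
    p <- as.vector(stats::rgamma(3, 1)); p <- p / sum(p)
    he <- heterozygosity(p)
    expect_gte(he, 0)
    expect_lte(he, 1 - 1 / 3 + 1e-12)
  }
})

test_that("Fst closed forms, bounds, and conventions", {
  f <- fst(list(c(0, 1, 0), c(1, 0, 0)), c(10, 10))
  expect_equal(f$Hs, 0)
  expect_equal(f$Ht, 0.5)
  expect_equal(f$Fst, 1)
  same <- fst(list(c(0.6, 0.3, 0.1), c(0.6, 0.3, 0.1)), c(9, 11))
  expect_equal(same$Fst, 0)
  mono <- fst(list(c(1, 0, 0), c(1, 0, 0)), c(5, 5))
  expect_equal(mono$Fst, 0)     # Ht = 0 convention
  set.seed(11)
  for (i in 1:50) {
    p1 <- stats::rgamma(3, 1); p1 <- p1 / sum(p1)
    p2 <- stats::rgamma(3, 1); p2 <- p2 / sum(p2)
    f <- fst(list(p1, p2), c(7, 13))
    expect_gte(f$Fst, -1e-12)
    expect_lte(f$Fst, 1)
  }
  expect_error(fst(list(c(1, 0, 0)), 5), ">= 2")
})

test_that("mean estimated Fst recovers planted frequency regimes", {
  # planted: loss frequency 0.8 in subspecies 1 (n=50), 0.1 in
  # subspecies 2 (n=60). Implied by hand: He1 = 0.32, He2 = 0.18,
  # Hs = 0.25, pooled p = (50*0.8 + 60*0.1)/110, Ht = 2p(1-p),
  # Fst = 1 - Hs/Ht = 0.48624 (5 s.f.)
  set.seed(2024)
  ni <- 50; nj <- 60
  ests <- replicate(400, {
    col <- c(ifelse(stats::rbinom(ni, 1, 0.8) == 1, "L", "N"),
             ifelse(stats::rbinom(nj, 1, 0.1) == 1, "L", "N"))
    pl <- list(category_frequencies(col, seq_len(ni)),
               category_frequencies(col, ni + seq_len(nj)))
    fst(pl, c(ni, nj))$Fst
  })
  expect_lt(abs(mean(ests) - 0.48624), 0.05)
})

test_that("per-CNVR diversity table respects invariants", {
  d <- cnvr_diversity(toy_gm())
  expect_identical(d$cnvr_id, paste0("R", 1:4))
  expect_true(all(d$Fst >= 0 & d$Fst <= 1))
  expect_true(all(d$Hs >= 0 & d$Ht >= 0))
  expect_false(d$polymorphic[4])
  expect_equal(d$Fst[4], 0)
  # R1: fixed-ish loss split; hand check He_indica = 0, He_japonica = 0
  expect_equal(d$He_indica[1], 0)
  expect_equal(d$He_japonica[1], 0)
  expect_equal(d$Fst[1], 1)     # fixed difference between subspecies
})

test_that("subspecies-specific classification and conservation", {
  out <- subspecies_specific(toy_gm())
  cls <- stats::setNames(out$class, out$cnvr_id)
  expect_identical(unname(cls["R1"]), "indica-only")
  expect_identical(unname(cls["R3"]), "japonica-only")
  expect_identical(unname(cls["R2"]), "shared")
  expect_true(out$unique[out$cnvr_id == "R4"] == FALSE)  # no carriers
  sm <- attr(out, "summary")
  expect_identical(sum(sm$n), nrow(out))  # classes partition the CNVRs
})

test_that("group frequency screen matches a brute-force recount", {
  gm <- toy_gm()
  scr <- group_frequency_screen(gm, min_diff = 0.8)
  tab <- attr(scr, "group_freq")
  panel <- attr(gm, "panel")
  # independent recount of every group frequency
  for (g in unique(panel$group)) {
    s <- panel$sample[panel$group == g]
    for (id in tab$cnvr_id) {
      manual <- mean(gm[s, id] != "N")
      expect_equal(tab[tab$cnvr_id == id, paste0("freq_", g)], manual)
    }
  }
  # R1 is fixed in group 'indica' (I1, I2) and absent in rayada
  expect_true("R1" %in% scr$cnvr_id)
  expect_false("R4" %in% scr$cnvr_id)
  expect_false(is.unsorted(rev(scr$max_diff)))
  # randomized matrices: screened set equals brute-force recomputation
  set.seed(12)
  for (rep in 1:5) {
    gm2 <- gm
    vals <- sample(c("N", "L", "G"), length(gm2), replace = TRUE,
                   prob = c(0.7, 0.2, 0.1))
    gm2[seq_along(vals)] <- vals
    scr2 <- group_frequency_screen(gm2, min_diff = 0.5)
    tab2 <- attr(scr2, "group_freq")
    brute <- tab2$cnvr_id[apply(
      as.matrix(tab2[, grep("^freq_", names(tab2))]), 1,
      function(r) max(r) - min(r)) >= 0.5]
    expect_setequal(scr2$cnvr_id, brute)
  }
})

test_that("uncentered correlation distance is scale-invariant", {
  m <- rbind(x = c(1, 2, 3), y = c(2, 4, 6), z = c(3, 1, 0))
  d <- uncentered_cor_dist(m)
  expect_equal(d["x", "y"], 0)
  expect_true(all(diag(d) == 0))
  expect_error(uncentered_cor_dist(rbind(a = c(0, 0, 0), b = 1:3)), "a")
})

test_that("average-linkage clustering matches a hand computation", {
  # 4 x 3 instance worked by hand from the pairwise distance matrix:
  # d(a,b) = 0.00612, d(c,d) = 0.02381, cross average = 0.94544
  m <- rbind(a = c(1, 0, 0), b = c(0.9, 0.1, 0),
             c = c(0, 1, 0), d = c(0, 0.9, 0.2))
  hc <- hierarchical_cluster(m)
  expect_s3_class(hc, "hclust")
  expect_equal(hc$height, c(0.00612, 0.02381, 0.94544), tolerance = 1e-3)
  expect_identical(sort(hc$merge[1, ]), c(-2L, -1L))
  expect_identical(sort(hc$merge[2, ]), c(-4L, -3L))
  expect_identical(unname(stats::cutree(hc, 2)[c("a", "b", "c", "d")]),
                   c(1L, 1L, 2L, 2L))
  # identical rows merge at height zero
  hc0 <- hierarchical_cluster(rbind(u = c(1, 1), v = c(1, 1),
                                    w = c(5, 0)))
  expect_equal(hc0$height[1], 0)
  expect_error(hierarchical_cluster(m[1, , drop = FALSE]), ">= 2")
})

test_that("one-way ANOVA hand values and null calibration", {
  expect_equal(anova_cnv_length(c(1, 2, 3, 4, 5, 6),
                                rep(c("a", "b"), each = 3))$F, 13.5)
  ident <- anova_cnv_length(rep(2, 6), rep(c("a", "b"), each = 3))
  expect_equal(ident$F, 0)
  expect_error(anova_cnv_length(1:5, rep("a", 5)), ">= 2 groups")
  set.seed(99)
  rej <- mean(replicate(400, {
    anova_cnv_length(rnorm(60), rep(1:6, each = 10))$p < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})
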