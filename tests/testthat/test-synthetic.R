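test_that("probe layout respects construction contract and determinism", {
  g <- genome_model(1e5, "chrA")
  lay <- make_probe_layout(g, 500, seed = 3)
  expect_s3_class(lay, "probe_layout")
  expect_gt(nrow(lay), 150)
  expect_lt(nrow(lay), 260)
  expect_false(is.unsorted(lay$start))
  expect_true(all(lay$length >= 50 & lay$length <= 75))
  expect_true(all(lay$end <= 1e5))
  expect_true(all(lay$end - lay$start + 1 == lay$length))
  expect_false(anyDuplicated(lay[, c("grid_x", "grid_y")]) > 0)
  expect_identical(lay, make_probe_layout(g, 500, seed = 3))
  expect_false(identical(lay, make_probe_layout(g, 500, seed = 4)))
})

test_that("median probe spacing tracks the request on a 12 x 1 Mb genome", {
  lay <- make_probe_layout(genome_model(), 500, seed = 11)
  gaps <- unlist(tapply(lay$start, lay$chrom, function(s) diff(sort(s))),
                 use.names = FALSE)
  expect_gte(median(gaps), 450)
  expect_lte(median(gaps), 550)
})

test_that("layout construction rejects bad inputs", {
  expect_error(make_probe_layout(genome_model(), 50), "median_spacing_bp")
  expect_error(make_probe_layout(genome_model(c(1e6, 300), c("chr1", "tiny")),
                                 500),
               "tiny")
  expect_error(genome_model(c(1e5, 1e5), c("a", "a")), "unique")
  expect_error(genome_model(numeric(0)), "positive")
})

test_that("plant_cnvs honours counts, disjointness and loss fraction", {
  lay <- tiny_layout()
  expect_identical(nrow(plant_cnvs(lay, "A", n_events_per_sample = 0)), 0L)
  tr <- plant_cnvs(lay, c("A", "B"), n_events_per_sample = 10,
                   loss_fraction = 1, seed = 5)
  expect_identical(nrow(tr), 20L)
  expect_true(all(tr$type == "loss"))
  expect_true(all(tr$end - tr$start + 1 >= 1000))
  # per-sample disjointness
  for (s in unique(tr$sample)) {
    d <- tr[tr$sample == s, ]
    for (cc in unique(d$chrom)) {
      dc <- d[d$chrom == cc, ]
      if (nrow(dc) > 1) {
        dc <- dc[order(dc$start), ]
        expect_true(all(dc$start[-1] > dc$end[-nrow(dc)]))
      }
    }
  }
  # every event covers >= 1 probe midpoint
  mid <- (lay$start + lay$end) / 2
  covered <- vapply(seq_len(nrow(tr)), function(i)
    any(lay$chrom == tr$chrom[i] & mid >= tr$start[i] & mid <= tr$end[i]),
    logical(1))
  expect_true(all(covered))
  expect_error(plant_cnvs(lay, "A", length_range = c(500, 900)), "1000")
  expect_error(plant_cnvs(lay, "A", loss_fraction = 1.5), "loss_fraction")
  expect_error(
    plant_cnvs(make_probe_layout(genome_model(2e4, "c"), 500, seed = 1),
               "A", n_events_per_sample = 50,
               length_range = c(1000, 1500), seed = 1),
    "too small")
})

test_that("loss share matches loss_fraction within binomial error", {
  lay <- tiny_layout()
  tr <- plant_cnvs(lay, sprintf("S%02d", 1:20), n_events_per_sample = 50,
                   length_range = c(1000, 2000), loss_fraction = 0.9,
                   seed = 8)
  expect_identical(nrow(tr), 1000L)
  share <- mean(tr$type == "loss")
  expect_gte(share, 0.88)
  expect_lte(share, 0.92)
})

test_that("noiseless scans carry exactly the planted signal", {
  lay <- tiny_layout()
  sc0 <- simulate_scan(lay, NULL, noise_sd = 0, spatial_amp = 0,
                       dye_bias_strength = 0, seed = 2)
  expect_identical(nrow(sc0), nrow(lay))     # conservation
  expect_true(all(sc0$log2ratio == 0))
  expect_true(all(sc0$test > 0 & sc0$ref > 0))

  tr <- data.frame(sample = "S1", chrom = lay$chrom[1],
                   start = 20000, end = 30000, type = "loss",
                   copy_ratio = -2.5)
  sc1 <- simulate_scan(lay, tr, sample = "S1", noise_sd = 0,
                       spatial_amp = 0, dye_bias_strength = 0, seed = 2)
  mid <- (lay$start + lay$end) / 2
  inside <- lay$chrom == tr$chrom & mid >= tr$start & mid <= tr$end
  expect_true(all(sc1$log2ratio[inside] == -2.5))
  expect_true(all(sc1$log2ratio[!inside] == 0))
  # sample absent from the truth set: a valid event-free scan
  sc2 <- simulate_scan(lay, tr, sample = "ghost", noise_sd = 0,
                       spatial_amp = 0, dye_bias_strength = 0, seed = 2)
  expect_true(all(sc2$log2ratio == 0))
})

test_that("in-event mean of noisy ratios sits at the copy ratio", {
  lay <- tiny_layout()
  tr <- data.frame(sample = "S1", chrom = lay$chrom[1],
                   start = 5000, end = 32000, type = "loss",
                   copy_ratio = -2.5)
  sc <- simulate_scan(lay, tr, sample = "S1", noise_sd = 0.15,
                      spatial_amp = 0, dye_bias_strength = 0, seed = 13)
  mid <- (lay$start + lay$end) / 2
  inside <- lay$chrom == tr$chrom & mid >= tr$start & mid <= tr$end
  n_in <- sum(inside)
  expect_gte(n_in, 40)
  expect_lt(abs(mean(sc$log2ratio[inside]) + 2.5),
            3 * 0.15 / sqrt(n_in))
})

test_that("scans are deterministic under a fixed seed", {
  lay <- tiny_layout()
  a <- simulate_self_self(lay, seed = 42)
  b <- simulate_self_self(lay, seed = 42)
  expect_identical(a, b)
  expect_lt(abs(mean(a$log2ratio)), 0.02)
})
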