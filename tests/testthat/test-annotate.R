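cnvr_fixture <- function() {
  data.frame(cnvr_id = c("R1", "R2"), chrom = c("chr1", "chr2"),
             start = c(100, 1000), end = c(400, 2000), type = "loss",
             stringsAsFactors = FALSE)
}

test_that("gene overlap statuses partition the gene set", {
  genes <- data.frame(
    gene_id = c("g_in", "g_part", "g_out", "g_exact"),
    chrom = "chr1",
    start = c(200, 350, 500, 100),
    end = c(300, 500, 600, 400), stringsAsFactors = FALSE)
  ov <- gene_overlap(cnvr_fixture(), genes)
  st <- stats::setNames(ov$status, ov$gene_id)
  expect_identical(unname(st["g_in"]), "wholly_contained")
  expect_identical(unname(st["g_part"]), "partial")
  expect_identical(unname(st["g_out"]), "none")
  expect_identical(unname(st["g_exact"]), "wholly_contained")  # non-strict
  expect_setequal(attr(ov, "cnvr_genes")$R1, c("g_in", "g_part", "g_exact"))
})

test_that("SD overlap counts and percentage match brute force", {
  cv <- cnvr_fixture()
  expect_equal(sd_overlap(cv, cv[0, ])$fraction_pct, 0)
  sds <- data.frame(chrom = c("chr1", "chr3"), start = c(390, 1),
                    end = c(1000, 50), stringsAsFactors = FALSE)
  r <- sd_overlap(cv, sds)
  expect_identical(r$n_overlap, 1L)
  expect_equal(r$fraction_pct, 50)
  # randomized toy set vs brute-force pairwise check
  set.seed(21)
  for (rep in 1:5) {
    cv2 <- data.frame(cnvr_id = sprintf("R%d", 1:30),
                      chrom = sample(c("c1", "c2"), 30, TRUE),
                      start = s <- sample(1e4, 30), end = s + sample(500, 30),
                      stringsAsFactors = FALSE)
    sd2 <- data.frame(chrom = sample(c("c1", "c2"), 10, TRUE),
                      start = s2 <- sample(1e4, 10), end = s2 + sample(800, 10),
                      stringsAsFactors = FALSE)
    brute <- sum(vapply(seq_len(30), function(i)
      any(sd2$chrom == cv2$chrom[i] & sd2$start <= cv2$end[i] &
            sd2$end >= cv2$start[i]), logical(1)))
    expect_identical(sd_overlap(cv2, sd2)$n_overlap, brute)
  }
})

test_that("repeat content unions masked bases before counting", {
  regions <- data.frame(chrom = "chr1", start = 1, end = 1000)
  reps0 <- data.frame(chrom = "chr2", start = 1, end = 10, class = "LTR")
  r0 <- repeat_content(regions, reps0)
  expect_equal(r0$repeat_pct, 0)
  # full cover by one LTR feature
  reps1 <- data.frame(chrom = "chr1", start = 1, end = 1000, class = "LTR")
  r1 <- repeat_content(regions, reps1)
  expect_equal(r1$repeat_pct, 100)
  expect_identical(unname(attr(r1, "class_regions")["LTR"]), 1L)
  # overlapping features must not double-count
  reps2 <- data.frame(chrom = "chr1", start = c(1, 301), end = c(500, 700),
                      class = c("LINE", "LINE"))
  r2 <- repeat_content(regions, reps2)
  expect_equal(r2$repeat_bp, 700)
  expect_equal(r2$repeat_pct, 70)
  expect_true(all(r2$repeat_pct >= 0 & r2$repeat_pct <= 100))
  expect_lte(r2$repeat_bp, r2$total_bp)
})

test_that("RepeatMasker .out parsing maps classes and round-trips", {
  hdr <- c("   SW  perc perc perc  query     position in query",
           "score  div. del. ins.  sequence  begin  end",
           "")
  mk <- function(chrom, st, en, cls)
    sprintf("  463 13.0  6.0  5.0  %s  %d  %d  (0)  +  RepFam  %s  1  100  (0)  1",
            chrom, st, en, cls)
  set.seed(31)
  feats <- data.frame(chrom = sample(c("chr1", "chr2"), 50, TRUE),
                      start = s <- sample(1e5, 50), end = s + sample(5000, 50),
                      cls = sample(c("LTR/Gypsy", "LINE/L1", "SINE/tRNA",
                                     "DNA/hAT", "Simple_repeat",
                                     "Low_complexity", "Unknown"), 50, TRUE),
                      stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".out")
  writeLines(c(hdr, mk(feats$chrom, feats$start, feats$end, feats$cls)), f)
  got <- read_repeatmasker(f)
  expect_identical(nrow(got), 50L)
  expect_identical(got$chrom, feats$chrom)
  expect_identical(got$start, as.numeric(feats$start))
  expect_identical(got$end, as.numeric(feats$end))
  map <- c("LTR/Gypsy" = "LTR", "LINE/L1" = "LINE", "SINE/tRNA" = "SINE",
           "DNA/hAT" = "DNA", "Simple_repeat" = "simple",
           "Low_complexity" = "simple", "Unknown" = "other")
  expect_identical(got$class, unname(map[feats$cls]))
  # malformed line is reported with its line number
  writeLines(c(hdr, mk("chr1", 1, 100, "LTR/Copia"), "  broken line"), f)
  expect_error(read_repeatmasker(f), "line 5")
})

test_that("BED round trip preserves 1-based inclusive coordinates", {
  iv <- data.frame(chrom = c("chr1", "chr2"), start = c(101, 5001),
                   end = c(200, 5100), name = c("a", "b"),
                   stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".bed")
  utils::write.table(
    data.frame(iv$chrom, iv$start - 1, iv$end, iv$name), f,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  back <- read_bed_intervals(f)
  expect_equal(back$start, iv$start)
  expect_equal(back$end, iv$end)
  expect_identical(back$name, iv$name)
})
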