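test_that("expectedCq implements the dosage model", {
  expect_equal(expectedCq(1, 20, 1), 20)
  expect_equal(expectedCq(2, 20, 1) - expectedCq(1, 20, 1), -1)
  expect_equal(expectedCq(2, 20, 0.8) - expectedCq(1, 20, 0.8),
               -log(2) / log(1.8))
  expect_error(expectedCq(0, 20, 1), "dose")
  expect_error(expectedCq(1, 20, 1.2), "efficiency")
})

test_that("the noiseless batch hits the analytic dosage values exactly", {
  sim <- simulateCqBatch(3, 3, replicate_sd = 0, sample_offset_sd = 0,
                         seed = 1)
  agg <- aggregate(cq ~ sample_id + target, sim$measurements, mean)
  wide <- merge(agg[agg$target == "autosome", c("sample_id", "cq")],
                agg[agg$target == "sex", c("sample_id", "cq")],
                by = "sample_id", suffixes = c("_auto", "_sex"))
  wide <- merge(wide, sim$truth)
  d <- wide$cq_auto - wide$cq_sex
  expect_equal(d[wide$sex == "male"], rep(0, 3))
  expect_equal(d[wide$sex == "female"], rep(-1, 3))
})

test_that("simulation is reproducible from the seed alone", {
  a <- simulateCqBatch(5, 5, replicate_sd = 0.2, sample_offset_sd = 1,
                       outlier_prob = 0.1, seed = 9)
  b <- simulateCqBatch(5, 5, replicate_sd = 0.2, sample_offset_sd = 1,
                       outlier_prob = 0.1, seed = 9)
  expect_identical(a, b)
  c <- simulateCqBatch(5, 5, replicate_sd = 0.2, sample_offset_sd = 1,
                       outlier_prob = 0.1, seed = 10)
  expect_false(identical(a$measurements$cq, c$measurements$cq))
  # the global RNG stream is left untouched
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(simulateCqBatch(2, 2, seed = 1)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("mean male-female delta-Cq converges to the efficiency form", {
  eff <- 0.8
  sim <- simulateCqBatch(800, 800, efficiency = eff, replicate_sd = 0.2,
                         n_replicates = 2L, seed = 11)
  agg <- aggregate(cq ~ sample_id + target, sim$measurements, mean)
  wide <- merge(agg[agg$target == "autosome", c("sample_id", "cq")],
                agg[agg$target == "sex", c("sample_id", "cq")],
                by = "sample_id", suffixes = c("_auto", "_sex"))
  wide <- merge(wide, sim$truth)
  d <- wide$cq_auto - wide$cq_sex
  gap <- mean(d[wide$sex == "male"]) - mean(d[wide$sex == "female"])
  expected <- log(2) / log(1 + eff)
  se <- sqrt(var(d[wide$sex == "male"]) / 800 +
               var(d[wide$sex == "female"]) / 800)
  expect_lt(abs(gap - expected), 3 * se)
})

test_that("delta-Cq distribution is invariant to shared sample offsets", {
  noOff <- simulateCqBatch(200, 200, replicate_sd = 0.1,
                           sample_offset_sd = 0, seed = 12)
  bigOff <- simulateCqBatch(200, 200, replicate_sd = 0.1,
                            sample_offset_sd = 5, seed = 13)
  dOf <- function(sim) {
    agg <- aggregate(cq ~ sample_id + target, sim$measurements, mean)
    wide <- merge(agg[agg$target == "autosome", c("sample_id", "cq")],
                  agg[agg$target == "sex", c("sample_id", "cq")],
                  by = "sample_id", suffixes = c("_auto", "_sex"))
    wide$cq_auto - wide$cq_sex
  }
  d1 <- dOf(noOff); d2 <- dOf(bigOff)
  expect_equal(mean(d1), mean(d2), tolerance = 0.05)
  expect_equal(sd(d1), sd(d2), tolerance = 0.05)
})

test_that("simulateGenome plants sites verbatim and is seed-stable", {
  site <- "GGCCGTCCTCTACTTGTAATG"
  cfg <- data.frame(sequence = c(site, site), seqid = c("chr1", "chr1"),
                    position = c(100L, 300L), strand = c("+", "-"),
                    stringsAsFactors = FALSE)
  sim <- simulateGenome(c(chr1 = 1000L), planted_sites = cfg, seed = 14)
  g <- as.character(sim$genome[["chr1"]])
  expect_identical(substr(g, 101, 121), site)
  expect_identical(substr(g, 301, 321), revComp(site))
  sim2 <- simulateGenome(c(chr1 = 1000L), planted_sites = cfg, seed = 14)
  expect_identical(as.character(sim$genome), as.character(sim2$genome))

  clash <- data.frame(sequence = c(site, site), seqid = "chr1",
                      position = c(100L, 110L), strand = "+",
                      stringsAsFactors = FALSE)
  expect_error(simulateGenome(c(chr1 = 1000L), planted_sites = clash,
                              seed = 14), "overlaps")
  outside <- data.frame(sequence = site, seqid = "chr1", position = 995L,
                        strand = "+", stringsAsFactors = FALSE)
  expect_error(simulateGenome(c(chr1 = 1000L), planted_sites = outside,
                              seed = 14), "outside")
})

test_that("planted convergent sites produce exactly one predicted amplicon", {
  f <- "CACTTCAGCCCGATGGAATAAG"
  r <- "GCCGAGACCACAAACAATAAC"
  # place the reverse site so the amplicon spans exactly 150 bp
  cfg <- data.frame(
    sequence = c(f, r), seqid = "chr1",
    position = c(200L, 200L + 150L - nchar(r)),
    strand = c("+", "-"), stringsAsFactors = FALSE)
  sim <- simulateGenome(c(chr1 = 2000L), planted_sites = cfg, seed = 15)
  res <- scanSpecificity(list(forward = f, reverse = r), sim$genome)
  expect_identical(ampliconCount(res), 1L)
  expect_identical(amplicons(res)$size, 150L)
})

test_that("contigs cut from the simulated genome carry exact PAF records", {
  sim <- simulateGenome(c(chr1 = 20000L, chrZ = 20000L), n_contigs = 6L,
                        contig_length = 5000L, seed = 16)
  expect_length(sim$contigs, 6L)
  # PAF records validate through the parser round-trip
  path <- withr::local_tempfile(fileext = ".paf")
  write.table(sim$paf, path, sep = "\t", col.names = FALSE,
              row.names = FALSE, quote = FALSE)
  back <- readPaf(path)
  expect_equal(back, sim$paf, ignore_attr = TRUE)
  # each contig is the verbatim slice its PAF record claims
  for (i in seq_len(nrow(sim$paf))) {
    rec <- sim$paf[i, ]
    chrom <- as.character(sim$genome[[rec$target_name]])
    expect_identical(as.character(sim$contigs[[rec$query_name]]),
                     substr(chrom, rec$target_start + 1L, rec$target_end))
  }
})

test_that("sex recovery is perfect at low noise and degrades as noise grows", {
  sigmas <- c(0.05, 0.1, 0.2, 0.35, 0.5)
  acc <- vapply(seq_along(sigmas), function(j) {
    mean(vapply(1:20, function(i) {
      sim <- simulateCqBatch(8, 8, replicate_sd = sigmas[j],
                             seed = 2000L + 100L * j + i)
      r <- runBatch(sim$measurements, truth = sim$truth)
      validation(r)$n_correct / validation(r)$n_total
    }, numeric(1)))
  }, numeric(1))
  expect_equal(acc[sigmas <= 0.1], rep(1, 2))
  # at sigma = 0.2 an isolated miscall is within Monte Carlo noise of a
  # perfect-recovery regime; the curve is a sanity check, not a sharp
  # threshold
  expect_gte(acc[3], 0.995)
  expect_lt(acc[4], 1)
  expect_lte(acc[5], acc[4])
  expect_true(all(diff(acc) <= 0))
})
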