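test_that("filterReplicates applies the single-pass one-cycle rule", {
  out <- filterReplicates(c(20.1, 20.2, 19.9, 22.0))
  expect_equal(out$kept, c(20.1, 20.2, 19.9))
  expect_equal(out$dropped, 22.0)
  expect_true(out$usable)

  out <- filterReplicates(rep(20, 4))
  expect_length(out$dropped, 0)

  # symmetric two-point case: both deviate by 2 from the mean
  out <- filterReplicates(c(18, 22))
  expect_length(out$kept, 0)
  expect_false(out$usable)

  expect_error(filterReplicates(20.0), "at least 2")
})

test_that("summarizeGroup computes mean and SEM with n-1 denominator", {
  s <- summarizeGroup(c(20, 20))
  expect_equal(s$mean_cq, 20)
  expect_equal(s$sem, 0)
  s <- summarizeGroup(c(19, 21))
  expect_equal(s$mean_cq, 20)
  expect_equal(s$sem, 1)
  s <- summarizeGroup(c(20.1, 20.2, 19.9, 20.2))
  expect_equal(s$mean_cq, 20.1)
  expect_equal(s$sem, sd(c(20.1, 20.2, 19.9, 20.2)) / 2)
  expect_equal(s$sem, 0.0707, tolerance = 1e-3)
  expect_error(summarizeGroup(20), "at least 2")
})

test_that("deltaCq subtracts sex from autosome and sums SEMs", {
  a <- summarizeGroup(c(20, 20))
  s <- summarizeGroup(c(19, 19))
  d <- deltaCq(a, s)
  expect_equal(d$delta_cq, 1)
  expect_equal(deltaCq(a, a)$delta_cq, 0)
  d <- deltaCq(list(mean_cq = 20, sem = 0.05), list(mean_cq = 19, sem = 0.07))
  expect_equal(d$sem_total, 0.12)
  dq <- deltaCq(list(mean_cq = 20, sem = 0.05), list(mean_cq = 19, sem = 0.07),
                quadrature = TRUE)
  expect_equal(dq$sem_total, sqrt(0.05^2 + 0.07^2))
})

test_that("splitClusters separates dosage groups and detects single-sex batches", {
  cl <- splitClusters(c(a = -0.02, b = 0.01, c = 0.98, d = 1.02))
  expect_setequal(names(cl$high), c("c", "d"))
  expect_setequal(names(cl$low), c("a", "b"))
  expect_equal(cl$max_gap, 0.97)

  expect_true(splitClusters(c(1.0, 1.01, 1.02, 0.99))$single_cluster)

  cl <- splitClusters(c(x = 0, y = 1))
  expect_equal(unname(cl$high), 1)
  expect_equal(unname(cl$low), 0)

  expect_error(splitClusters(0.5), "at least 2")
})

test_that("splitClusters is not derailed by a single extreme sample", {
  set.seed(71)
  males <- rnorm(40, 0, 0.12)
  females <- rnorm(40, -1, 0.12)
  x <- setNames(c(males, 0.55, females),
                c(paste0("m", 1:40), "m41", paste0("f", 1:40)))
  cl <- splitClusters(x)
  expect_false(cl$single_cluster)
  expect_setequal(names(cl$high), paste0("m", 1:41))
  expect_setequal(names(cl$low), paste0("f", 1:40))
})

test_that("normalizeDdcq maps the male median to zero", {
  d <- c(m1 = 1.00, m2 = 1.02, f1 = 0.02, f2 = -0.01)
  cl <- splitClusters(d)
  norm <- normalizeDdcq(d, cl)
  expect_equal(norm$reference, 1.01)
  expect_equal(unname(norm$ddcq["m1"]), -0.01)
  expect_equal(unname(norm$ddcq["f1"]), 0.02 - 1.01)
  std <- normalizeDdcq(c(s = 0.95), male_standard = 0.95)
  expect_equal(unname(std$ddcq), 0)
  expect_error(
    normalizeDdcq(d, list(single_cluster = TRUE)),
    "reference required")
})

test_that("callSex picks the nearest dosage target and flags the midpoint", {
  expect_identical(callSex(0), "male")
  expect_identical(callSex(-1), "female")
  expect_identical(callSex(-0.5), "ambiguous")
  expect_identical(callSex(c(0.1, -0.9, -0.49)),
                   c("male", "female", "ambiguous"))
  # outside a narrow margin the nearest target wins on either side
  expect_identical(callSex(-0.49, ambiguity_margin = 0.005), "male")
  expect_identical(callSex(-0.51, ambiguity_margin = 0.005), "female")
})

test_that("separationMetrics reports median distance and minimum gap", {
  m <- separationMetrics(high = 0, low = -1)
  expect_equal(m$median_distance, 1)
  expect_equal(m$min_gap, 1)
  m <- separationMetrics(high = c(-0.02, 0.03), low = c(-0.95, -1.05))
  expect_equal(m$median_distance, 1.005)
  expect_equal(m$min_gap, 0.93)
  # overlapping clusters: negative gap reported as-is
  m <- separationMetrics(high = c(0, -0.6), low = c(-1, -0.5))
  expect_lt(m$min_gap, 0)
  expect_error(separationMetrics(numeric(0), -1), "non-empty")
})

test_that("exactBinomialP is exact and matches binom.test", {
  expect_identical(exactBinomialP(8, 8), 0.5^8)
  expect_identical(exactBinomialP(8, 8), 0.00390625)
  expect_equal(exactBinomialP(81, 81), 2^-81)
  expect_equal(exactBinomialP(0, 8), 1)
  for (n in c(5L, 8L, 81L)) {
    ks <- unique(c(0L, 1L, n %/% 2L, n - 1L, n))
    p <- vapply(ks, exactBinomialP, numeric(1), n_total = n)
    # independent route: base R's exact binomial test
    ref <- vapply(ks, function(k)
      binom.test(k, n, 0.5, alternative = "greater")$p.value, numeric(1))
    expect_equal(p, ref)
    expect_true(all(diff(p) <= 0))
  }
})

test_that("runBatch composes the pipeline on a clean synthetic batch", {
  sim <- simulateCqBatch(4, 4, replicate_sd = 0.1, seed = 3)
  res <- runBatch(sim$measurements, truth = sim$truth)
  v <- validation(res)
  expect_identical(v$n_correct, 8L)
  expect_identical(v$n_total, 8L)
  expect_identical(v$p_value, 0.00390625)
  expect_identical(res@male_median, 0)
  expect_equal(res@female_median, -1, tolerance = 0.2)
  expect_identical(res@n_male, 4L)
  expect_identical(res@n_female, 4L)
  expect_gte(separation(res)[["median_distance"]],
             separation(res)[["min_gap"]])
})

test_that("runBatch is deterministic and survives a noiseless batch", {
  cq <- cleanCqTable()
  r1 <- runBatch(cq)
  r2 <- runBatch(cq)
  expect_identical(sexCalls(r1), sexCalls(r2))
  calls <- sexCalls(r1)
  expect_identical(calls$predicted_sex[calls$sample_id == "m1"], "male")
  expect_identical(calls$predicted_sex[calls$sample_id == "f1"], "female")
  expect_equal(calls$delta_cq, c(0, -1))
  expect_equal(calls$ddcq, c(0, -1))
})

test_that("single-sex batches require a male standard", {
  sim <- simulateCqBatch(6, 0, replicate_sd = 0.1, seed = 4)
  expect_error(runBatch(sim$measurements), "reference required")
  res <- runBatch(sim$measurements, male_standard = 0)
  expect_identical(unique(sexCalls(res)$predicted_sex), "male")
})

test_that("outlier replicates are dropped and flagged, not fatal", {
  sim <- simulateCqBatch(4, 4, replicate_sd = 0.05, outlier_prob = 0.2,
                         outlier_shift = 3, seed = 5)
  res <- runBatch(sim$measurements, truth = sim$truth)
  expect_true(any(grepl("outliers-dropped", sexCalls(res)$qc_flags)))
  expect_identical(validation(res)$n_correct, validation(res)$n_total)
})

test_that("borderline ddcq values are flagged but still called", {
  cq <- cleanCqTable()
  # shift the female sample to the ambiguous zone: sex Cq 20.45 -> ddcq -0.45
  cq$cq[cq$sample_id == "f1" & cq$target == "sex"] <- 20.45
  res <- runBatch(cq, min_gap = 0.2)
  calls <- sexCalls(res)
  f <- calls[calls$sample_id == "f1", ]
  expect_identical(f$predicted_sex, "male")  # nearest target wins
  expect_match(f$qc_flags, "ambiguous-zone")
})

test_that("delta-Cq is invariant under shared per-sample Cq shifts", {
  set.seed(72)
  for (i in 1:30) {
    auto <- 20 + rnorm(4, 0, 0.1)
    sex <- 19.5 + rnorm(4, 0, 0.1)
    shift <- rnorm(1, 0, 3)
    d0 <- deltaCq(summarizeGroup(auto), summarizeGroup(sex))$delta_cq
    d1 <- deltaCq(summarizeGroup(auto + shift),
                  summarizeGroup(sex + shift))$delta_cq
    expect_equal(d1, d0)
  }
})

test_that("reports serialize calls and validation to CSV and JSON", {
  sim <- simulateCqBatch(3, 3, replicate_sd = 0.05, seed = 6)
  res <- runBatch(sim$measurements, truth = sim$truth)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  writeCalls(res, csv)
  writeReport(res, js)
  back <- read.csv(csv, stringsAsFactors = FALSE)
  expect_identical(nrow(back), 6L)
  rep <- jsonlite::read_json(js)
  expect_equal(rep$n_samples, 6)
  expect_equal(rep$validation$n_correct, 6)
  expect_equal(rep$male_median_ddcq, 0)
})
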