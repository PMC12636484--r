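test_that("candidate enumeration emits the closed-form count", {
  prof <- designProfile(size_range = c(18L, 22L), opt_size = 20L,
                        product_size = c(25L, 40L), gc_clamp = 0L,
                        tm_range = c(0, 100), gc_range = c(0, 100),
                        max_poly_x = 10L)
  tpl <- setNames(randomDna(30), "t30")
  set.seed(31)
  cand <- enumerateCandidates(tpl, prof)
  # 13 + 12 + 11 + 10 + 9 = 55 start positions per strand
  expect_identical(nrow(cand), 110L)
  expect_identical(sum(cand$strand == "+"), 55L)

  # general closed form on random clean templates
  for (L in c(40L, 65L)) {
    tpl <- setNames(randomDna(L), "t")
    cand <- enumerateCandidates(tpl, prof)
    sizes <- 18:22
    expect_identical(nrow(cand), 2L * sum(L - sizes + 1L))
  }
})

test_that("candidate sequences equal strand-adjusted template slices", {
  set.seed(32)
  tplSeq <- randomDna(40)
  prof <- designProfile(size_range = c(18L, 20L), product_size = c(25L, 40L))
  cand <- enumerateCandidates(setNames(tplSeq, "t"), prof)
  for (i in sample(nrow(cand), 20)) {
    slice <- substr(tplSeq, cand$start[i] + 1L, cand$end[i])
    expected <- if (cand$strand[i] == "+") slice else revComp(slice)
    expect_identical(cand$sequence[i], expected)
  }
})

test_that("homopolymer templates are rejected wholesale", {
  tpl <- setNames(strrep("A", 120), "polyA")
  cand <- enumerateCandidates(tpl, geneiousProfile())
  expect_true(all(grepl("poly-x", cand$reject_reasons)))
})

test_that("a published primer embedded in a template passes the stringent profile", {
  primer <- "GGTGTTGTTCGCTCAGTTATC"
  set.seed(33)
  flankL <- "ATCGGATCGGATCGGATCGGATCGGATCGGATCGGATCGGATCGGATCGGATCGGATCGG"
  flankR <- "ATCGGATCGGATCGGATCGGATCGGATCGGATCGGATCGGATCGG"
  tpl <- setNames(paste0(flankL, primer, flankR), "t")
  cand <- enumerateCandidates(tpl, geneiousProfile())
  hit <- cand[cand$sequence == primer & cand$strand == "+", ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$reject_reasons, "")
  expect_identical(hit$start, nchar(flankL))
})

test_that("templates shorter than the product range are refused", {
  expect_error(enumerateCandidates(setNames(randomDna(50), "t"),
                                   geneiousProfile()),
               "shorter than the minimum product")
})

test_that("pairPrimers respects the product size window", {
  prof <- pipelineProfile()  # product 150-300
  # two clean primer sites 150 bp product
  f <- "CACTTCAGCCCGATGGAATAAG"
  r <- "CTTTGTAAATGCCGCACCTATATC"
  set.seed(34)
  mid <- randomDna(150 - nchar(f) - nchar(r))
  tpl <- setNames(paste0(f, mid, revComp(r)), "t")
  cand <- data.frame(
    sequence = c(f, r), template_id = "t",
    start = c(0L, 150L - nchar(r)), end = c(nchar(f), 150L),
    strand = c("+", "-"), length = c(nchar(f), nchar(r)),
    tm = c(nnTm(f), nnTm(r)), gc = c(gcContent(f), gcContent(r)),
    clamp_run = 1L, max_run = 3L, self_dimer_tm = 0,
    reject_reasons = "", stringsAsFactors = FALSE)
  pairs <- pairPrimers(cand, prof)
  expect_identical(nrow(pairs), 1L)
  expect_identical(pairs$product_size, 150L)
  # shrink the product below range: excluded
  cand2 <- cand
  cand2$start[2] <- 100L - nchar(r)
  cand2$end[2] <- 100L
  expect_identical(nrow(pairPrimers(cand2, prof)), 0L)
})

test_that("every returned pair satisfies the profile constraints", {
  set.seed(35)
  prof <- designProfile(size_range = c(18L, 22L), product_size = c(60L, 120L),
                        tm_range = c(45, 65), gc_clamp = 1L,
                        max_poly_x = 4L, max_dimer_tm = 35)
  tpl <- setNames(randomDna(140), "t")
  pairs <- designPrimers(tpl, prof, top = 150)
  expect_gt(nrow(pairs), 0)
  prim <- unique(c(pairs$forward, pairs$reverse))
  tm <- vapply(prim, nnTm, numeric(1))
  expect_true(all(tm >= prof@tm_range[1] & tm <= prof@tm_range[2]))
  expect_true(all(vapply(prim, gcClampRun, integer(1)) >= prof@gc_clamp))
  expect_true(all(vapply(prim, maxHomopolymer, integer(1)) <=
                    prof@max_poly_x))
  expect_true(all(vapply(prim, function(s) dimerTm(s, s), numeric(1)) <=
                    prof@max_dimer_tm))
  expect_true(all(pairs$product_size >= prof@product_size[1] &
                    pairs$product_size <= prof@product_size[2]))
  expect_true(all(pairs$cross_dimer_tm <= prof@max_dimer_tm))
  expect_identical(pairs$product_size,
                   pairs$product_end - pairs$product_start)
  expect_true(!is.unsorted(pairs$penalty))
})

test_that("pair ranking is deterministic with documented tie-breaks", {
  # two identical forward candidates at different positions, one reverse
  f <- "CACTTCAGCCCGATGGAATAAG"
  r <- "GCCGAGACCACAAACAATAAC"
  cand <- data.frame(
    sequence = c(f, f, r), template_id = "t",
    start = c(0L, 10L, 180L), end = c(22L, 32L, 201L),
    strand = c("+", "+", "-"), length = c(22L, 22L, 21L),
    tm = c(nnTm(f), nnTm(f), nnTm(r)),
    gc = c(gcContent(f), gcContent(f), gcContent(r)),
    clamp_run = 1L, max_run = 3L, self_dimer_tm = 0,
    reject_reasons = "", stringsAsFactors = FALSE)
  prof <- designProfile(product_size = c(150L, 250L), tm_range = c(45, 70))
  p1 <- pairPrimers(cand, prof)
  p2 <- pairPrimers(cand, prof)
  expect_identical(p1, p2)
  # equal penalty except size terms; leftmost product start first on ties
  expect_identical(nrow(p1), 2L)
  if (p1$penalty[1] == p1$penalty[2])
    expect_lt(p1$product_start[1], p1$product_start[2])
})
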