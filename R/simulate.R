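#' Expected quantification cycle under the dosage model
#'
#' `Cq = base_cq - log(dose) / log(1 + E)`, with `dose` the template copy
#' number relative to the diploid autosomal reference (dose 1). At 100%
#' efficiency (E = 1, perfect doubling) a two-fold dose shifts Cq by
#' exactly one cycle earlier.
#'
#' @param dose relative copy number (> 0); 1 for a diploid autosome and a
#'   ZZ sex locus, 0.5 for the single-copy Z of a Z0 female
#' @param base_cq Cq of the diploid reference at the assay's input amount
#' @param efficiency per-cycle amplification efficiency E in (0, 1]
#' @return expected Cq, cycles
#' @examples
#' expectedCq(1, 20, 1)                      # 20
#' expectedCq(2, 20, 1) - expectedCq(1, 20, 1)  # -1
#' @export
expectedCq <- function(dose, base_cq = 20, efficiency = 1) {
  if (any(dose <= 0)) stop("dose must be > 0")
  if (any(efficiency <= 0) || any(efficiency > 1))
    stop("efficiency must be in (0, 1]")
  base_cq - log(dose) / log(1 + efficiency)
}

#' Simulate a technical-replicate Cq batch with known genotypes
#'
#' Emulates a plate of qPCR reactions for a mixed-sex batch: every sample
#' carries autosome dose 1; ZZ males carry sex-locus dose 1 and Z0
#' females dose 0.5 relative to the diploid autosome. A shared per-sample
#' offset (Normal, `sample_offset_sd`) models template-concentration
#' differences and applies to both targets, so it cancels in delta-Cq;
#' independent per-replicate noise (Normal, `replicate_sd`) models
#' technical scatter; with probability `outlier_prob` a replicate is
#' shifted by +/- `outlier_shift` cycles (sign chosen at random) to
#' exercise the outlier filter. Fully reproducible from `seed`.
#'
#' @param n_male,n_female numbers of ZZ and Z0 samples
#' @param base_cq diploid reference Cq (default 20)
#' @param efficiency amplification efficiency E in (0, 1] (default 1)
#' @param replicate_sd per-replicate Gaussian noise SD, cycles
#'   (default 0.1, the clean-assay setting; 0.2 is a realistic one)
#' @param sample_offset_sd per-sample shared offset SD, cycles (default 0)
#' @param n_replicates technical replicates per target (default 4)
#' @param outlier_prob per-replicate probability of an outlier shift
#'   (default 0)
#' @param outlier_shift magnitude of the outlier shift, cycles (default 2)
#' @param seed integer seed; all randomness flows from it
#' @return list with `measurements` (data.frame `sample_id`, `target`,
#'   `cq`) and `truth` (data.frame `sample_id`, `sex`, `genotype`)
#' @examples
#' sim <- simulateCqBatch(4, 4, replicate_sd = 0.1, seed = 1)
#' head(sim$measurements)
#' @export
simulateCqBatch <- function(n_male, n_female, base_cq = 20, efficiency = 1,
                            replicate_sd = 0.1, sample_offset_sd = 0,
                            n_replicates = 4L, outlier_prob = 0,
                            outlier_shift = 2, seed = 1L) {
  stopifnot(n_male >= 0, n_female >= 0, n_male + n_female >= 1,
            n_replicates >= 2L, replicate_sd >= 0, sample_offset_sd >= 0,
            outlier_prob >= 0, outlier_prob <= 1)
  n <- n_male + n_female
  withr_seed <- .localSeed(seed)
  on.exit(withr_seed())
  sex <- c(rep("male", n_male), rep("female", n_female))
  ord <- sample.int(n)  # interleave sexes so sample order carries no signal
  sex <- sex[ord]
  ids <- sprintf("s%03d", seq_len(n))
  offsets <- rnorm(n, 0, sample_offset_sd)
  rows <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    doses <- c(autosome = 1, sex = if (sex[i] == "male") 1 else 0.5)
    for (j in seq_along(doses)) {
      tg <- names(doses)[j]
      mu <- expectedCq(doses[[j]], base_cq, efficiency) + offsets[i]
      cqs <- mu + rnorm(n_replicates, 0, replicate_sd)
      if (outlier_prob > 0) {
        hit <- runif(n_replicates) < outlier_prob
        signs <- sample(c(-1, 1), n_replicates, replace = TRUE)
        cqs <- cqs + ifelse(hit, signs * outlier_shift, 0)
      }
      rows[[2L * (i - 1L) + j]] <- data.frame(
        sample_id = ids[i], target = tg, cq = cqs,
        stringsAsFactors = FALSE)
    }
  }
  list(
    measurements = do.call(rbind, rows),
    truth = data.frame(sample_id = ids, sex = sex,
                       genotype = ifelse(sex == "male", "ZZ", "Z0"),
                       stringsAsFactors = FALSE)
  )
}

# Scoped RNG: sets the seed, returns a restorer for on.exit, so that no
# global RNG state leaks in or out of the simulators.
.localSeed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Simulate a genome with planted primer sites, and an optional contig set
#'
#' Generates random chromosome sequences, writes the supplied
#' `planted_sites` (e.g. primer binding sites) into them at exact
#' positions (minus-strand sites are planted as their reverse
#' complement), and optionally cuts a set of contigs from the
#' chromosomes together with the corresponding exact-match PAF records —
#' fixtures for contig-to-chromosome assignment and specificity
#' scanning.
#'
#' @param lengths named integer vector of chromosome lengths
#' @param planted_sites optional data.frame with columns `sequence`,
#'   `seqid`, `position` (0-based start), `strand` (+/-); sites must fit
#'   within their chromosome and must not overlap one another
#' @param n_contigs number of contigs to cut (0 = none)
#' @param contig_length length of each cut contig, bp
#' @param seed integer seed
#' @return list with `genome` (a [Biostrings::DNAStringSet]), `contigs`
#'   (DNAStringSet, possibly empty) and `paf` (data.frame of exact
#'   alignment records as [readPaf()] would return)
#' @export
simulateGenome <- function(lengths, planted_sites = NULL, n_contigs = 0L,
                           contig_length = 10000L, seed = 1L) {
  stopifnot(length(lengths) >= 1L, all(lengths > 0))
  if (is.null(names(lengths)))
    names(lengths) <- sprintf("chr%d", seq_along(lengths))
  restore <- .localSeed(seed)
  on.exit(restore())
  seqs <- vapply(lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  if (!is.null(planted_sites)) {
    stopifnot(all(c("sequence", "seqid", "position", "strand") %in%
                    names(planted_sites)))
    occ <- lapply(names(lengths), function(x) integer(0))
    names(occ) <- names(lengths)
    for (i in seq_len(nrow(planted_sites))) {
      sid <- planted_sites$seqid[i]
      if (!sid %in% names(seqs)) stop("unknown seqid: ", sid)
      s <- toupper(planted_sites$sequence[i])
      if (planted_sites$strand[i] == "-") s <- revComp(s)
      p0 <- planted_sites$position[i]
      span <- (p0 + 1L):(p0 + nchar(s))
      if (p0 < 0L || p0 + nchar(s) > lengths[[sid]])
        stop("planted site ", i, " falls outside ", sid)
      if (any(span %in% occ[[sid]]))
        stop("planted site ", i, " overlaps a previously planted site on ",
             sid)
      occ[[sid]] <- c(occ[[sid]], span)
      substr(seqs[[sid]], p0 + 1L, p0 + nchar(s)) <- s
    }
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- names(lengths)

  contigs <- Biostrings::DNAStringSet()
  paf <- data.frame(
    query_name = character(0), query_len = integer(0),
    query_start = integer(0), query_end = integer(0), strand = character(0),
    target_name = character(0), target_len = integer(0),
    target_start = integer(0), target_end = integer(0),
    n_matches = integer(0), block_len = integer(0), mapq = integer(0),
    stringsAsFactors = FALSE)
  if (n_contigs > 0L) {
    eligible <- names(lengths)[lengths >= contig_length]
    if (!length(eligible))
      stop("no chromosome is long enough to cut contigs of ",
           contig_length, " bp")
    src <- sample(eligible, n_contigs, replace = TRUE)
    cseqs <- character(n_contigs)
    rows <- vector("list", n_contigs)
    for (i in seq_len(n_contigs)) {
      L <- lengths[[src[i]]]
      st0 <- sample.int(L - contig_length + 1L, 1L) - 1L
      cseqs[i] <- substr(seqs[[src[i]]], st0 + 1L, st0 + contig_length)
      rows[[i]] <- data.frame(
        query_name = sprintf("contig%03d", i),
        query_len = contig_length, query_start = 0L,
        query_end = contig_length, strand = "+",
        target_name = src[i], target_len = L,
        target_start = st0, target_end = st0 + contig_length,
        n_matches = contig_length, block_len = contig_length,
        mapq = 60L, stringsAsFactors = FALSE)
    }
    contigs <- Biostrings::DNAStringSet(cseqs)
    names(contigs) <- sprintf("contig%03d", seq_len(n_contigs))
    paf <- do.call(rbind, rows)
  }
  list(genome = genome, contigs = contigs, paf = paf)
}
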