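# Shared fixture builders and independent oracles.

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

writeTempFasta <- function(seqs, width = 60L) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  con <- file(path, "w")
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  close(con)
  path
}

# Brute-force in-silico PCR oracle: per-position mismatch scan of a primer
# against every sequence and strand, with the 3'-terminal seed required to
# match exactly. Independent of the package's Biostrings-anchored scan.
bruteForceSites <- function(primer, genomeChars, seed_len, max_mismatch) {
  out <- list()
  plen <- nchar(primer)
  pf <- strsplit(toupper(primer), "")[[1]]
  pr <- strsplit(cephsex::revComp(primer), "")[[1]]
  for (sid in names(genomeChars)) {
    g <- genomeChars[[sid]]
    L <- length(g)
    if (L < plen) next
    for (p in 1:(L - plen + 1L)) {
      win <- g[p:(p + plen - 1L)]
      # plus: primer equals top strand, seed = last seed_len bases
      mm <- sum(win != pf)
      if (mm <= max_mismatch &&
          all(win[(plen - seed_len + 1L):plen] ==
                pf[(plen - seed_len + 1L):plen]))
        out[[length(out) + 1L]] <- data.frame(
          seqid = sid, start = p - 1L, end = p - 1L + plen, strand = "+",
          mismatches = mm, stringsAsFactors = FALSE)
      # minus: revcomp(primer) equals top strand, seed = first seed_len
      mm <- sum(win != pr)
      if (mm <= max_mismatch && all(win[1:seed_len] == pr[1:seed_len]))
        out[[length(out) + 1L]] <- data.frame(
          seqid = sid, start = p - 1L, end = p - 1L + plen, strand = "-",
          mismatches = mm, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(seqid = character(0), start = integer(0), end = integer(0),
               strand = character(0), mismatches = integer(0))
}

bruteForceAmplicons <- function(sites, max_amplicon) {
  plus <- sites[sites$strand == "+", , drop = FALSE]
  minus <- sites[sites$strand == "-", , drop = FALSE]
  out <- list()
  if (nrow(plus) && nrow(minus)) {
    for (i in seq_len(nrow(plus))) for (j in seq_len(nrow(minus))) {
      if (plus$seqid[i] == minus$seqid[j] &&
          minus$start[j] >= plus$end[i] &&
          minus$end[j] - plus$start[i] <= max_amplicon)
        out[[length(out) + 1L]] <- data.frame(
          seqid = plus$seqid[i], start = plus$start[i], end = minus$end[j],
          size = minus$end[j] - plus$start[i], stringsAsFactors = FALSE)
    }
  }
  if (length(out)) unique(do.call(rbind, out)) else
    data.frame(seqid = character(0), start = integer(0), end = integer(0),
               size = integer(0))
}

# Exhaustive complementary-window search between two oligos (antiparallel,
# ungapped), independent of dimerTm's rle-based scan: enumerates every
# (offset, window start, window length) triple directly.
bruteForceBestWindow <- function(a, b) {
  av <- strsplit(toupper(a), "")[[1]]
  rc <- strsplit(cephsex::revComp(b), "")[[1]]
  na <- length(av); nb <- length(rc)
  wins <- character(0)
  for (off in (-(nb - 1L)):(na - 1L)) {
    idx <- max(1L, 1L + off):min(na, nb + off)
    for (s in seq_along(idx)) {
      run <- 0L
      for (e in s:length(idx)) {
        if (av[idx[e]] == rc[idx[e] - off]) run <- run + 1L else break
      }
      if (run >= 4L)
        wins <- c(wins, paste(av[idx[s:(s + run - 1L)]], collapse = ""))
    }
  }
  unique(wins)
}

# Fixed qPCR noise-free Cq table for two samples (one male-like, one
# female-like) used by several caller tests.
cleanCqTable <- function() {
  data.frame(
    sample_id = rep(c("m1", "m1", "f1", "f1"), each = 4),
    target = rep(rep(c("autosome", "sex"), each = 4), times = 2),
    cq = c(rep(20, 4), rep(20, 4),   # male: auto 20, sex 20
           rep(20, 4), rep(21, 4)),  # female: auto 20, sex 21
    stringsAsFactors = FALSE
  )
}
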