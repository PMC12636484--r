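#' Scan a genome for primer binding sites and predicted amplicons
#'
#' In-silico PCR in the MFEprimer style: a primer binds a genomic position
#' when its `seed_len` 3'-terminal bases match exactly and the total
#' number of mismatches over the full primer is at most `max_mismatch`.
#' Both primers of the pair are scanned in both orientations; every
#' convergent (plus site, minus site) combination on one sequence with a
#' span of at most `max_amplicon` is a predicted amplicon. The pair is
#' `unique` when exactly one amplicon is predicted and — if the intended
#' template is part of the scanned genome — that amplicon lies at the
#' intended product coordinates.
#'
#' @param pair a one-row data.frame from [pairPrimers()], or a list with
#'   elements `forward` and `reverse` (primer sequences 5' to 3') and
#'   optionally `template_id`, `product_start`, `product_end`
#' @param genome a [Biostrings::DNAStringSet]
#' @param max_amplicon maximum amplicon span in bp (default 1000)
#' @param seed_len 3'-terminal exact-match seed length in nt (default 12)
#' @param max_mismatch maximum mismatches over the full primer (default 3)
#' @return a [SpecificityResult-class]
#' @export
scanSpecificity <- function(pair, genome, max_amplicon = 1000L,
                            seed_len = 12L, max_mismatch = 3L) {
  stopifnot(methods::is(genome, "DNAStringSet"), length(genome) > 0L)
  p <- .asPairRow(pair)
  primers <- c(forward = toupper(p$forward), reverse = toupper(p$reverse))
  sites <- do.call(rbind, lapply(names(primers), function(role) {
    .findBindingSites(primers[[role]], genome, seed_len, max_mismatch, role)
  }))
  if (is.null(sites)) sites <- .emptySiteFrame()
  amps <- .predictAmplicons(sites, max_amplicon)
  unique <- nrow(amps) == 1L
  if (unique && !is.null(p$template_id) && !is.na(p$template_id) &&
      p$template_id %in% names(genome) &&
      !is.null(p$product_start) && !is.na(p$product_start)) {
    unique <- amps$seqid[1] == p$template_id &&
      amps$start[1] == p$product_start &&
      amps$end[1] == p$product_end
  }
  methods::new("SpecificityResult", pair = p, binding_sites = sites,
               amplicons = amps, unique = unique)
}

.asPairRow <- function(pair) {
  if (is.data.frame(pair)) {
    stopifnot(nrow(pair) == 1L,
              all(c("forward", "reverse") %in% names(pair)))
    return(pair)
  }
  stopifnot(is.list(pair), !is.null(pair$forward), !is.null(pair$reverse))
  data.frame(
    forward = pair$forward, reverse = pair$reverse,
    template_id = pair$template_id %||% NA_character_,
    product_start = pair$product_start %||% NA_integer_,
    product_end = pair$product_end %||% NA_integer_,
    stringsAsFactors = FALSE
  )
}

# Binding sites of one primer over all genome sequences and both strands.
# A "+" site primes rightward synthesis (primer text matches the top
# strand, 3' end at the site's right edge); a "-" site primes leftward
# (primer text matches the bottom strand, 3' end at the site's left edge).
# Coordinates are 0-based half-open.
.findBindingSites <- function(primer, genome, seed_len, max_mismatch, role) {
  len <- nchar(primer)
  seed_len <- min(seed_len, len)
  pFwd <- Biostrings::DNAString(primer)
  pRev <- Biostrings::DNAString(revComp(primer))
  seedFwd <- Biostrings::subseq(pFwd, len - seed_len + 1L, len)
  seedRev <- Biostrings::subseq(pRev, 1L, seed_len)
  rows <- list()
  for (sid in names(genome)) {
    subject <- genome[[sid]]
    L <- length(subject)
    # plus orientation: seed sits at the 3' (right) end of the match
    anchors <- Biostrings::start(Biostrings::matchPattern(seedFwd, subject))
    starts <- anchors - (len - seed_len)
    starts <- starts[starts >= 1L]
    if (length(starts)) {
      mm <- Biostrings::neditStartingAt(pFwd, subject, starting.at = starts)
      ok <- mm <= max_mismatch
      if (any(ok))
        rows[[length(rows) + 1L]] <- data.frame(
          seqid = sid, start = starts[ok] - 1L, end = starts[ok] - 1L + len,
          strand = "+", primer = role, mismatches = mm[ok],
          stringsAsFactors = FALSE)
    }
    # minus orientation: scan with the reverse complement; seed at left end
    anchors <- Biostrings::start(Biostrings::matchPattern(seedRev, subject))
    starts <- anchors[anchors + len - 1L <= L]
    if (length(starts)) {
      mm <- Biostrings::neditStartingAt(pRev, subject, starting.at = starts)
      ok <- mm <= max_mismatch
      if (any(ok))
        rows[[length(rows) + 1L]] <- data.frame(
          seqid = sid, start = starts[ok] - 1L, end = starts[ok] - 1L + len,
          strand = "-", primer = role, mismatches = mm[ok],
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

.emptySiteFrame <- function() {
  data.frame(seqid = character(0), start = integer(0), end = integer(0),
             strand = character(0), primer = character(0),
             mismatches = integer(0), stringsAsFactors = FALSE)
}

.predictAmplicons <- function(sites, max_amplicon) {
  empty <- data.frame(seqid = character(0), start = integer(0),
                      end = integer(0), size = integer(0),
                      plus_primer = character(0), minus_primer = character(0),
                      stringsAsFactors = FALSE)
  plus <- sites[sites$strand == "+", , drop = FALSE]
  minus <- sites[sites$strand == "-", , drop = FALSE]
  if (!nrow(plus) || !nrow(minus)) return(empty)
  rows <- list()
  for (i in seq_len(nrow(plus))) {
    cand <- minus[minus$seqid == plus$seqid[i] &
                    minus$start >= plus$end[i] &
                    minus$end - plus$start[i] <= max_amplicon, ,
                  drop = FALSE]
    if (nrow(cand))
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = cand$seqid, start = plus$start[i], end = cand$end,
        size = cand$end - plus$start[i],
        plus_primer = plus$primer[i], minus_primer = cand$primer,
        stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$seqid, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @describeIn scanSpecificity number of predicted amplicons
#' @param x a SpecificityResult
#' @export
ampliconCount <- function(x) {
  stopifnot(methods::is(x, "SpecificityResult"))
  nrow(x@amplicons)
}

#' @describeIn scanSpecificity predicted amplicons as a data.frame
#' @export
amplicons <- function(x) {
  stopifnot(methods::is(x, "SpecificityResult"))
  x@amplicons
}

#' @describeIn scanSpecificity primer binding sites as a data.frame
#' @export
bindingSites <- function(x) {
  stopifnot(methods::is(x, "SpecificityResult"))
  x@binding_sites
}

#' @describeIn scanSpecificity TRUE when the pair amplifies a single,
#'   intended locus
#' @export
isUnique <- function(x) {
  stopifnot(methods::is(x, "SpecificityResult"))
  x@unique
}

setMethod("show", "SpecificityResult", function(object) {
  cat("SpecificityResult:", nrow(object@binding_sites), "binding site(s),",
      nrow(object@amplicons), "predicted amplicon(s);",
      if (object@unique) "unique" else "NOT unique", "\n")
})
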