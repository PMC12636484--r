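#' Refine a primer pair to a related species' consensus
#'
#' Replaces each primer's bases with the consensus alleles at the primer's
#' template coordinates, so that primers designed on a reference species
#' match the variants of a related target species. The consensus must be
#' in template coordinates (positionally 1:1 over both primer regions,
#' e.g. a reference-guided consensus of the same length). A pair is
#' rejected when the consensus carries an ambiguity code or an alignment
#' gap (`-`) within the 3'-terminal 5 nt of either primer — variation
#' there compromises extension — and flagged (but still returned) when an
#' ambiguity falls elsewhere in a primer. Thermodynamics are recomputed
#' and profile constraints re-checked on the refined sequences.
#'
#' @param pair one-row data.frame from [pairPrimers()] (needs
#'   `forward_start`/`forward_end`/`reverse_start`/`reverse_end`)
#' @param consensus species consensus as a [Biostrings::DNAStringSet] of
#'   length 1 or a character string, in template coordinates; may contain
#'   IUPAC ambiguity codes and `-` gaps
#' @param template the original design template (same coordinate system)
#' @param profile a [DesignProfile-class] for re-checking constraints
#' @param conditions a [ThermoConditions-class]
#' @return the input row augmented with refined sequences, recomputed
#'   `forward_tm`/`reverse_tm`, `forward_mismatches`/`reverse_mismatches`
#'   (substitutions vs the original primers), `accepted` (logical) and
#'   `reject_reasons`
#' @export
refineToSpecies <- function(pair, consensus, template,
                            profile = geneiousProfile(),
                            conditions = thermoConditions()) {
  p <- pair
  stopifnot(is.data.frame(p), nrow(p) == 1L,
            all(c("forward", "reverse", "forward_start", "forward_end",
                  "reverse_start", "reverse_end") %in% names(p)))
  consSeq <- .asRawSequence(consensus)
  tplSeq <- .asRawSequence(template)
  reasons <- character(0)

  ref <- list(
    forward = .refineOne(p$forward, p$forward_start, p$forward_end, "+",
                         consSeq, tplSeq),
    reverse = .refineOne(p$reverse, p$reverse_start, p$reverse_end, "-",
                         consSeq, tplSeq)
  )
  for (role in names(ref)) {
    if (ref[[role]]$threePrimeVariant)
      reasons <- c(reasons, paste0("3prime-variant-", role))
    else if (ref[[role]]$ambiguous)
      reasons <- c(reasons, paste0("ambiguous-", role))
  }
  p$forward <- ref$forward$seq
  p$reverse <- ref$reverse$seq
  p$forward_mismatches <- ref$forward$mismatches
  p$reverse_mismatches <- ref$reverse$mismatches
  clean <- !ref$forward$ambiguous && !ref$reverse$ambiguous &&
    !ref$forward$threePrimeVariant && !ref$reverse$threePrimeVariant
  if (clean) {
    p$forward_tm <- .nnTmCore(p$forward, conditions)
    p$reverse_tm <- .nnTmCore(p$reverse, conditions)
    p$forward_gc <- gcContent(p$forward)
    p$reverse_gc <- gcContent(p$reverse)
    for (role in c("forward", "reverse")) {
      s <- p[[role]]
      tm <- p[[paste0(role, "_tm")]]
      gc <- p[[paste0(role, "_gc")]]
      if (tm < profile@tm_range[1] || tm > profile@tm_range[2])
        reasons <- c(reasons, paste0("tm-range-", role))
      if (gc < profile@gc_range[1] || gc > profile@gc_range[2])
        reasons <- c(reasons, paste0("gc-range-", role))
      if (gcClampRun(s) < profile@gc_clamp)
        reasons <- c(reasons, paste0("gc-clamp-", role))
      if (maxHomopolymer(s) > profile@max_poly_x)
        reasons <- c(reasons, paste0("poly-x-", role))
    }
  } else {
    p$forward_tm <- p$reverse_tm <- NA_real_
  }
  p$accepted <- length(reasons) == 0L
  p$reject_reasons <- paste(reasons, collapse = ";")
  p
}

.asRawSequence <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    stopifnot(length(x) == 1L)
    toupper(as.character(x[[1]]))
  } else if (methods::is(x, "DNAString")) {
    toupper(as.character(x))
  } else {
    stopifnot(is.character(x), length(x) == 1L)
    toupper(x)
  }
}

# Refine one primer region. start/end are 0-based half-open template
# coordinates; minus-strand primers are stored 5'->3', i.e. as the
# reverse complement of the template slice, with the 3' end at the
# template-leftmost position.
.refineOne <- function(primer, start0, end0, strand, consSeq, tplSeq) {
  if (end0 > nchar(consSeq))
    stop("consensus (", nchar(consSeq), " nt) does not cover the primer ",
         "region [", start0, ", ", end0, ")")
  slice <- substr(consSeq, start0 + 1L, end0)
  # alignment gaps are recoded to N so they behave as ambiguity below
  slice <- gsub("-", "N", slice, fixed = TRUE)
  newSeq <- if (strand == "-") revComp(slice) else slice
  chars <- strsplit(newSeq, "")[[1]]
  nonACGT <- which(!chars %in% c("A", "C", "G", "T"))
  n <- length(chars)
  threeWin <- (n - 4L):n  # 3'-terminal 5 nt of the oriented primer
  threePrimeVariant <- any(nonACGT %in% threeWin)
  oldChars <- strsplit(toupper(primer), "")[[1]]
  mismatches <- if (length(oldChars) == n) sum(oldChars != chars) else NA_integer_
  list(seq = newSeq, mismatches = mismatches,
       ambiguous = length(nonACGT) > 0L,
       threePrimeVariant = threePrimeVariant)
}
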