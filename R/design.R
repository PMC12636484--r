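#' Enumerate and annotate primer candidates on a template
#'
#' Emits every substring of the template whose length lies in the
#' profile's size range, on both strands, annotated with GC content,
#' melting temperature, 3' GC-clamp run, longest homopolymer and (for
#' candidates that pass all other filters, when the profile sets a dimer
#' cutoff) self-dimer Tm. `reject_reasons` lists every violated
#' constraint; a candidate passes the profile iff it is empty.
#' Coordinates are 0-based half-open on the template; minus-strand
#' candidates carry the reverse-complemented sequence (5' to 3').
#'
#' @param template a [Biostrings::DNAStringSet] of length 1, a named
#'   character string, or a [Biostrings::DNAString]
#' @param profile a [DesignProfile-class]
#' @param conditions a [ThermoConditions-class]
#' @return a data.frame with columns `sequence`, `template_id`, `start`,
#'   `end`, `strand`, `length`, `tm`, `gc`, `clamp_run`, `max_run`,
#'   `self_dimer_tm`, `reject_reasons` (semicolon-joined; "" = pass)
#' @export
enumerateCandidates <- function(template, profile = geneiousProfile(),
                                conditions = thermoConditions()) {
  tpl <- .asSingleSequence(template)
  seqStr <- tpl$seq
  L <- nchar(seqStr)
  if (L < profile@product_size[1])
    stop("template (", L, " nt) is shorter than the minimum product size (",
         profile@product_size[1], " bp)")
  sizes <- seq(profile@size_range[1], profile@size_range[2])
  sizes <- sizes[sizes <= L]
  rows <- vector("list", 2L * sum(L - sizes + 1L))
  n <- 0L
  for (len in sizes) {
    for (start0 in 0:(L - len)) {
      sub <- substr(seqStr, start0 + 1L, start0 + len)
      for (strand in c("+", "-")) {
        s <- if (strand == "+") sub else revComp(sub)
        n <- n + 1L
        rows[[n]] <- .annotateCandidate(s, tpl$id, start0, start0 + len,
                                        strand, profile, conditions)
      }
    }
  }
  out <- do.call(rbind, rows[seq_len(n)])
  rownames(out) <- NULL
  # self-dimer screening is the expensive constraint: evaluate it only for
  # candidates that survive everything else
  if (!is.na(profile@max_dimer_tm)) {
    idx <- which(out$reject_reasons == "")
    for (i in idx) {
      dtm <- dimerTm(out$sequence[i], out$sequence[i], conditions)
      out$self_dimer_tm[i] <- dtm
      if (dtm > profile@max_dimer_tm)
        out$reject_reasons[i] <- "self-dimer"
    }
  }
  out
}

.asSingleSequence <- function(template) {
  if (methods::is(template, "DNAStringSet")) {
    stopifnot(length(template) == 1L)
    list(id = names(template) %||% "template",
         seq = as.character(template[[1]]))
  } else if (methods::is(template, "DNAString")) {
    list(id = "template", seq = as.character(template))
  } else {
    stopifnot(is.character(template), length(template) == 1L)
    list(id = names(template) %||% "template", seq = toupper(template))
  }
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

.annotateCandidate <- function(s, template_id, start0, end0, strand,
                               profile, conditions) {
  reasons <- character(0)
  ambiguous <- grepl("[^ACGT]", s)
  tm <- gc <- NA_real_
  if (ambiguous) {
    reasons <- c(reasons, "ambiguous-base")
  } else {
    gc <- gcContent(s)
    tm <- .nnTmCore(s, conditions)
    if (tm < profile@tm_range[1] || tm > profile@tm_range[2])
      reasons <- c(reasons, "tm-range")
    if (gc < profile@gc_range[1] || gc > profile@gc_range[2])
      reasons <- c(reasons, "gc-range")
  }
  clamp <- gcClampRun(s)
  if (clamp < profile@gc_clamp) reasons <- c(reasons, "gc-clamp")
  run <- maxHomopolymer(s)
  if (run > profile@max_poly_x) reasons <- c(reasons, "poly-x")
  data.frame(
    sequence = s, template_id = template_id,
    start = start0, end = end0, strand = strand,
    length = nchar(s), tm = tm, gc = gc,
    clamp_run = clamp, max_run = run,
    self_dimer_tm = NA_real_,
    reject_reasons = paste(reasons, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Pair passing primer candidates into ranked amplifiable pairs
#'
#' Combines every passing plus-strand (forward) candidate with every
#' passing, non-overlapping minus-strand (reverse) candidate downstream of
#' it whose implied product size is within the profile range. Pairs whose
#' cross-dimer Tm exceeds the profile cutoff (when set) are rejected. The
#' remaining pairs are ranked by a penalty that rewards proximity to the
#' profile optima:
#' `|tm_f - opt_tm| + |tm_r - opt_tm| + |tm_f - tm_r| +
#'  0.1 (|gc_f - opt_gc| + |gc_r - opt_gc|) +
#'  |size_f - opt_size| + |size_r - opt_size|`,
#' ties broken by leftmost product start, then smallest product size.
#'
#' @param candidates data.frame from [enumerateCandidates()]
#' @param profile a [DesignProfile-class]
#' @param conditions a [ThermoConditions-class]
#' @param top keep at most this many pairs (NULL = all)
#' @return a data.frame of pairs, ascending penalty: forward/reverse
#'   sequences and coordinates, `product_start`, `product_end`,
#'   `product_size`, `cross_dimer_tm`, `penalty`
#' @export
pairPrimers <- function(candidates, profile = geneiousProfile(),
                        conditions = thermoConditions(), top = NULL) {
  pass <- candidates[candidates$reject_reasons == "", , drop = FALSE]
  fwd <- pass[pass$strand == "+", , drop = FALSE]
  rev <- pass[pass$strand == "-", , drop = FALSE]
  if (!nrow(fwd) || !nrow(rev)) return(.emptyPairFrame())
  grid <- expand.grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(rev)))
  psize <- rev$end[grid$r] - fwd$start[grid$f]
  ok <- psize >= profile@product_size[1] & psize <= profile@product_size[2] &
    rev$start[grid$r] >= fwd$end[grid$f]
  grid <- grid[ok, , drop = FALSE]
  psize <- psize[ok]
  if (!nrow(grid)) return(.emptyPairFrame())
  f <- fwd[grid$f, ]; r <- rev[grid$r, ]
  penalty <- abs(f$tm - profile@opt_tm) + abs(r$tm - profile@opt_tm) +
    abs(f$tm - r$tm) +
    0.1 * (abs(f$gc - profile@opt_gc) + abs(r$gc - profile@opt_gc)) +
    abs(f$length - profile@opt_size) + abs(r$length - profile@opt_size)
  out <- data.frame(
    template_id = f$template_id,
    forward = f$sequence, reverse = r$sequence,
    forward_start = f$start, forward_end = f$end,
    reverse_start = r$start, reverse_end = r$end,
    forward_tm = f$tm, reverse_tm = r$tm,
    forward_gc = f$gc, reverse_gc = r$gc,
    product_start = f$start, product_end = r$end,
    product_size = psize,
    cross_dimer_tm = NA_real_,
    penalty = penalty,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$penalty, out$product_start, out$product_size), ,
             drop = FALSE]
  # cross-dimer screening, cheapest-first so --top exits early
  keep <- logical(nrow(out))
  limit <- if (is.null(top)) nrow(out) else top
  nKept <- 0L
  for (i in seq_len(nrow(out))) {
    ct <- dimerTm(out$forward[i], out$reverse[i], conditions)
    out$cross_dimer_tm[i] <- ct
    if (is.na(profile@max_dimer_tm) || ct <= profile@max_dimer_tm) {
      keep[i] <- TRUE
      nKept <- nKept + 1L
      if (nKept >= limit) break
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.emptyPairFrame <- function() {
  data.frame(
    template_id = character(0), forward = character(0),
    reverse = character(0), forward_start = integer(0),
    forward_end = integer(0), reverse_start = integer(0),
    reverse_end = integer(0), forward_tm = numeric(0),
    reverse_tm = numeric(0), forward_gc = numeric(0),
    reverse_gc = numeric(0), product_start = integer(0),
    product_end = integer(0), product_size = integer(0),
    cross_dimer_tm = numeric(0), penalty = numeric(0),
    stringsAsFactors = FALSE
  )
}

#' Design ranked primer pairs for a template
#'
#' Convenience wrapper: [enumerateCandidates()] then [pairPrimers()].
#'
#' @inheritParams enumerateCandidates
#' @inheritParams pairPrimers
#' @return a ranked pair data.frame (see [pairPrimers()])
#' @export
designPrimers <- function(template, profile = geneiousProfile(),
                          conditions = thermoConditions(), top = NULL) {
  pairPrimers(enumerateCandidates(template, profile, conditions),
              profile, conditions, top = top)
}
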