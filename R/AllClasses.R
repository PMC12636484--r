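#' @import methods
#' @importFrom stats median pbinom rnorm runif sd setNames
NULL

#' Thermodynamic reaction conditions for melting-temperature calculations
#'
#' Holds the buffer and oligo concentrations under which nearest-neighbor
#' melting temperatures are evaluated. Divalent cations are folded into a
#' monovalent (Na+) equivalent before the entropic salt correction is
#' applied.
#'
#' @slot monovalent_mM monovalent cation concentration (mM Na+ equivalent)
#' @slot divalent_mM divalent cation concentration (mM)
#' @slot oligo_nM total oligonucleotide strand concentration (nM)
#' @slot nn_parameter_set identifier of the nearest-neighbor table in use
#'
#' @seealso [thermoConditions()], [nnTm()]
#' @export
setClass("ThermoConditions",
  representation(
    monovalent_mM = "numeric",
    divalent_mM = "numeric",
    oligo_nM = "numeric",
    nn_parameter_set = "character"
  )
)

setValidity("ThermoConditions", function(object) {
  msg <- character()
  if (object@monovalent_mM < 0 || object@divalent_mM < 0 || object@oligo_nM < 0)
    msg <- c(msg, "all concentrations must be >= 0")
  if (object@monovalent_mM + 120 * sqrt(object@divalent_mM) <= 0)
    msg <- c(msg, "Na+-equivalent concentration must be positive")
  if (object@oligo_nM == 0)
    msg <- c(msg, "oligo_nM must be positive")
  if (length(msg)) msg else TRUE
})

#' Primer design constraint profile
#'
#' A set of Primer3-style constraints used to filter primer candidates and
#' pairs: optimal/min/max primer size, melting temperature and GC content,
#' allowed amplicon size range, the required 3' GC clamp, the maximum
#' homopolymer run, and (optionally) the maximum tolerated primer-dimer
#' melting temperature.
#'
#' @slot opt_size optimal primer length (nt)
#' @slot size_range min/max primer length (nt)
#' @slot opt_tm optimal melting temperature (deg C)
#' @slot tm_range min/max melting temperature (deg C)
#' @slot opt_gc optimal GC content (percent)
#' @slot gc_range min/max GC content (percent)
#' @slot product_size min/max amplicon size (bp)
#' @slot gc_clamp required number of consecutive G/C at the 3' terminus
#' @slot max_poly_x maximum allowed single-base run length
#' @slot max_dimer_tm maximum tolerated self/cross dimer Tm (deg C); NA to
#'   disable dimer screening
#' @slot name profile label
#'
#' @seealso [designProfile()], [geneiousProfile()], [pipelineProfile()]
#' @export
setClass("DesignProfile",
  representation(
    opt_size = "integer",
    size_range = "integer",
    opt_tm = "numeric",
    tm_range = "numeric",
    opt_gc = "numeric",
    gc_range = "numeric",
    product_size = "integer",
    gc_clamp = "integer",
    max_poly_x = "integer",
    max_dimer_tm = "numeric",
    name = "character"
  )
)

setValidity("DesignProfile", function(object) {
  msg <- character()
  chkRange <- function(rng, opt, what) {
    if (length(rng) != 2L || rng[1] > rng[2])
      return(sprintf("%s range must be c(min, max) with min <= max", what))
    if (opt < rng[1] || opt > rng[2])
      return(sprintf("optimal %s must lie inside its range", what))
    NULL
  }
  msg <- c(msg,
    chkRange(object@size_range, object@opt_size, "size"),
    chkRange(object@tm_range, object@opt_tm, "Tm"),
    chkRange(object@gc_range, object@opt_gc, "GC"))
  if (length(object@product_size) != 2L ||
      object@product_size[1] > object@product_size[2])
    msg <- c(msg, "product_size must be c(min, max) with min <= max")
  if (object@gc_clamp < 0L) msg <- c(msg, "gc_clamp must be >= 0")
  if (object@max_poly_x < 1L) msg <- c(msg, "max_poly_x must be >= 1")
  if (length(msg)) msg else TRUE
})

#' In-silico PCR specificity scan result
#'
#' Produced by [scanSpecificity()]. Records every genomic binding site of
#' the two primers of a pair (exact 3'-seed match, bounded total
#' mismatches), every predicted amplicon formed by a convergent site pair,
#' and whether the pair is unique (exactly one predicted amplicon, at the
#' intended locus when the intended template is part of the scanned
#' genome).
#'
#' @slot pair one-row data.frame describing the scanned primer pair
#' @slot binding_sites data.frame: seqid, start, end (0-based half-open),
#'   strand, primer (forward/reverse), mismatches
#' @slot amplicons data.frame: seqid, start, end, size, plus_primer,
#'   minus_primer
#' @slot unique logical
#' @export
setClass("SpecificityResult",
  representation(
    pair = "data.frame",
    binding_sites = "data.frame",
    amplicons = "data.frame",
    unique = "logical"
  )
)

#' Batch sex-genotyping result
#'
#' The result of [runBatch()]: one row per sample with mean Cq per locus,
#' delta-Cq (autosome minus sex locus), normalized delta-delta-Cq, summed
#' SEM, cluster membership and the predicted sex, plus batch-level cluster
#' separation statistics and (when a truth table was supplied) an exact
#' binomial validation of the call accuracy.
#'
#' @slot calls data.frame of per-sample calls
#' @slot male_median median delta-delta-Cq of the male (high) cluster
#' @slot female_median median delta-delta-Cq of the female (low) cluster
#' @slot median_distance male_median - female_median (cycles)
#' @slot min_gap smallest delta-Cq distance between the two clusters
#'   (negative when they overlap)
#' @slot n_male,n_female cluster sizes
#' @slot validation list(n_correct, n_total, p_value) or empty list
#' @slot params list of the options the batch was run with
#' @export
setClass("SexCallBatch",
  representation(
    calls = "data.frame",
    male_median = "numeric",
    female_median = "numeric",
    median_distance = "numeric",
    min_gap = "numeric",
    n_male = "integer",
    n_female = "integer",
    validation = "list",
    params = "list"
  )
)

setValidity("SexCallBatch", function(object) {
  msg <- character()
  need <- c("sample_id", "delta_cq", "ddcq", "sem", "cluster",
            "predicted_sex", "qc_flags")
  if (!all(need %in% names(object@calls)))
    msg <- c(msg, paste("calls must have columns:", paste(need, collapse = ", ")))
  if (length(object@median_distance) == 1L && !is.na(object@median_distance) &&
      object@median_distance < 0)
    msg <- c(msg, "median_distance must be >= 0 (male cluster has the greater delta-Cq)")
  if (length(msg)) msg else TRUE
})
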