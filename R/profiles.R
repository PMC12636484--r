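#' Construct a primer design profile
#'
#' @param opt_size optimal primer length (nt)
#' @param size_range min/max primer length
#' @param opt_tm optimal melting temperature (deg C)
#' @param tm_range min/max melting temperature
#' @param opt_gc optimal GC content (percent)
#' @param gc_range min/max GC content
#' @param product_size min/max amplicon size (bp)
#' @param gc_clamp required 3'-terminal G/C run (0 disables)
#' @param max_poly_x maximum homopolymer run
#' @param max_dimer_tm maximum tolerated dimer Tm (deg C), NA to disable
#' @param name profile label
#' @return a [DesignProfile-class] object
#' @seealso [geneiousProfile()], [pipelineProfile()]
#' @export
designProfile <- function(opt_size = 20L, size_range = c(18L, 27L),
                          opt_tm = 59, tm_range = c(52, 62),
                          opt_gc = 50, gc_range = c(30, 70),
                          product_size = c(100L, 200L),
                          gc_clamp = 1L, max_poly_x = 3L,
                          max_dimer_tm = NA_real_,
                          name = "custom") {
  methods::new("DesignProfile",
    opt_size = as.integer(opt_size),
    size_range = as.integer(size_range),
    opt_tm = as.numeric(opt_tm),
    tm_range = as.numeric(tm_range),
    opt_gc = as.numeric(opt_gc),
    gc_range = as.numeric(gc_range),
    product_size = as.integer(product_size),
    gc_clamp = as.integer(gc_clamp),
    max_poly_x = as.integer(max_poly_x),
    max_dimer_tm = as.numeric(max_dimer_tm),
    name = name
  )
}

#' GUI-style stringent design profile
#'
#' The profile used for species with chromosome-level assemblies: optimal
#' size 20 nt, optimal Tm 59 deg C, optimal GC 50%, product 100-200 bp,
#' GC clamp of 1, max poly-X 3, max dimer Tm 30 deg C. Size/Tm/GC min-max
#' ranges are package defaults; the Tm band is set low relative to the
#' optimum because the default 50 mM Na+ conditions (no divalent
#' correction) read a few degrees below instrument-buffer conditions.
#'
#' @return a [DesignProfile-class]
#' @export
geneiousProfile <- function() {
  designProfile(opt_size = 20L, size_range = c(18L, 27L),
                opt_tm = 59, tm_range = c(52, 62),
                opt_gc = 50, gc_range = c(30, 70),
                product_size = c(100L, 200L),
                gc_clamp = 1L, max_poly_x = 3L, max_dimer_tm = 30,
                name = "geneious-2025")
}

#' Command-line pipeline design profile
#'
#' The profile used when designing from exon FASTA extracted via a GFF:
#' optimal size 20 nt, optimal Tm 60 deg C, optimal GC 50%, product
#' 150-300 bp, max poly-X 5; no GC-clamp requirement and no dimer-Tm
#' cutoff.
#'
#' @return a [DesignProfile-class]
#' @export
pipelineProfile <- function() {
  designProfile(opt_size = 20L, size_range = c(18L, 27L),
                opt_tm = 60, tm_range = c(52, 63),
                opt_gc = 50, gc_range = c(30, 70),
                product_size = c(150L, 300L),
                gc_clamp = 0L, max_poly_x = 5L, max_dimer_tm = NA_real_,
                name = "pipeline")
}

#' @describeIn designProfile look up a named preset
#' @param x preset name, `"geneious-2025"` or `"pipeline"`
#' @export
namedProfile <- function(x) {
  switch(x,
    "geneious-2025" = geneiousProfile(),
    "pipeline" = pipelineProfile(),
    stop("unknown profile preset: ", x)
  )
}

setMethod("show", "DesignProfile", function(object) {
  cat("DesignProfile <", object@name, ">\n", sep = "")
  cat(sprintf("  size %d nt [%d-%d]  Tm %.1f C [%.1f-%.1f]  GC %.0f%% [%.0f-%.0f]\n",
              object@opt_size, object@size_range[1], object@size_range[2],
              object@opt_tm, object@tm_range[1], object@tm_range[2],
              object@opt_gc, object@gc_range[1], object@gc_range[2]))
  cat(sprintf("  product %d-%d bp  gc_clamp %d  max_poly_x %d  max_dimer_tm %s\n",
              object@product_size[1], object@product_size[2],
              object@gc_clamp, object@max_poly_x,
              ifelse(is.na(object@max_dimer_tm), "off",
                     sprintf("%.1f C", object@max_dimer_tm))))
})
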