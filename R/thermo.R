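# Unified DNA nearest-neighbor parameters (Allawi & SantaLucia 1997 /
# SantaLucia 1998 unified set). dH in kcal/mol, dS in cal/(K mol), duplex
# propagation 5'->3' on the top strand; a stack and its reverse complement
# share parameters.
NN_DH <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
)
NN_DS <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
)
# duplex initiation per terminal base pair
NN_INIT_DH <- c(GC = 0.1, AT = 2.3)
NN_INIT_DS <- c(GC = -2.8, AT = 4.1)
GAS_CONSTANT <- 1.987  # cal/(K mol)

#' Construct thermodynamic conditions
#'
#' Defaults mirror common primer-design settings: 50 mM monovalent salt,
#' no divalent cations, 250 nM oligo. Divalent cations, when present, are
#' folded into a Na+ equivalent as `monovalent + 120 * sqrt(divalent)`
#' (concentrations in mM) before the entropic salt correction.
#'
#' @param monovalent_mM monovalent cation concentration, mM (default 50)
#' @param divalent_mM divalent cation concentration, mM (default 0)
#' @param oligo_nM total oligo strand concentration, nM (default 250)
#' @return a [ThermoConditions-class] object
#' @export
thermoConditions <- function(monovalent_mM = 50, divalent_mM = 0,
                             oligo_nM = 250) {
  methods::new("ThermoConditions",
    monovalent_mM = as.numeric(monovalent_mM),
    divalent_mM = as.numeric(divalent_mM),
    oligo_nM = as.numeric(oligo_nM),
    nn_parameter_set = "unified-1998"
  )
}

.checkPlainDna <- function(seq, what = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  if (nchar(s) == 0L) stop(what, " must be non-empty")
  if (grepl("[^ACGT]", s))
    stop(what, " contains a non-A/C/G/T character; ambiguity codes are not ",
         "accepted here")
  s
}

#' GC content of a sequence, in percent
#'
#' @param seq an unambiguous A/C/G/T string
#' @return 100 * (#G + #C) / length
#' @examples
#' gcContent("GGTGTTGTTCGCTCAGTTATC")  # 47.62
#' @export
gcContent <- function(seq) {
  s <- .checkPlainDna(seq)
  chars <- strsplit(s, "")[[1]]
  100 * sum(chars %in% c("G", "C")) / length(chars)
}

#' Longest homopolymer run (poly-X)
#'
#' @param seq a non-empty nucleotide string
#' @return length of the longest run of a single repeated base
#' @export
maxHomopolymer <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L)
  max(rle(strsplit(toupper(seq), "")[[1]])$lengths)
}

#' 3'-terminal GC run (GC clamp)
#'
#' Number of consecutive G or C bases at the 3' end of the primer; a
#' design profile with `gc_clamp = k` requires a run of at least k.
#'
#' @param seq a non-empty nucleotide string, written 5' to 3'
#' @return integer run length (0 when the 3' base is A or T)
#' @export
gcClampRun <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L)
  chars <- rev(strsplit(toupper(seq), "")[[1]])
  run <- 0L
  for (ch in chars) {
    if (ch %in% c("G", "C")) run <- run + 1L else break
  }
  run
}

# Core NN Tm: no length restriction, used for both full primers and dimer
# windows. Returns Tm in deg C.
.nnTmCore <- function(s, conditions) {
  n <- nchar(s)
  chars <- strsplit(s, "")[[1]]
  stacks <- paste0(chars[-n], chars[-1])
  dH <- sum(NN_DH[stacks])
  dS <- sum(NN_DS[stacks])
  ends <- ifelse(chars[c(1L, n)] %in% c("G", "C"), "GC", "AT")
  dH <- dH + sum(NN_INIT_DH[ends])
  dS <- dS + sum(NN_INIT_DS[ends])
  selfComp <- identical(s, revComp(s))
  if (selfComp) dS <- dS - 1.4
  naEq <- (conditions@monovalent_mM +
             120 * sqrt(max(conditions@divalent_mM, 0))) / 1000
  dS <- dS + 0.368 * (n - 1) * log(naEq)
  ct <- conditions@oligo_nM * 1e-9
  divisor <- if (selfComp) 1 else 4
  1000 * dH / (dS + GAS_CONSTANT * log(ct / divisor)) - 273.15
}

#' Nearest-neighbor melting temperature
#'
#' Duplex melting temperature of a primer against its perfect complement,
#' from nearest-neighbor enthalpy/entropy accumulation with terminal
#' initiation terms, a self-complementarity symmetry correction, and the
#' entropic monovalent-salt correction
#' `dS + 0.368 (N-1) ln[Na+]`. Deterministic given the conditions.
#'
#' @param seq an unambiguous A/C/G/T string of 8-36 nt, 5' to 3'
#' @param conditions a [ThermoConditions-class] object
#' @return melting temperature in degrees Celsius
#' @examples
#' nnTm("GGTGTTGTTCGCTCAGTTATC")
#' @export
nnTm <- function(seq, conditions = thermoConditions()) {
  s <- .checkPlainDna(seq, "primer")
  n <- nchar(s)
  if (n < 8L || n > 36L)
    stop("primer length must be 8-36 nt, got ", n)
  methods::validObject(conditions)
  .nnTmCore(s, conditions)
}

#' Primer-dimer melting temperature
#'
#' Scans all ungapped antiparallel alignments of `seq_a` against `seq_b`,
#' locates the contiguous complementary window forming the most stable
#' duplex, and returns that window's nearest-neighbor melting temperature.
#' Windows shorter than 4 complementary base pairs are ignored (returns
#' 0). The self-dimer of a primer is `dimerTm(s, s)`; a primer against its
#' perfect reverse complement recovers `nnTm(s)`.
#'
#' @param seq_a,seq_b primer sequences, 5' to 3'
#' @param conditions a [ThermoConditions-class] object
#' @return melting temperature (deg C) of the strongest complementary
#'   window, or 0 when no window of at least 4 bp exists
#' @export
dimerTm <- function(seq_a, seq_b, conditions = thermoConditions()) {
  a <- .checkPlainDna(seq_a, "seq_a")
  b <- .checkPlainDna(seq_b, "seq_b")
  # antiparallel pairing of a against b == parallel matching of a against
  # revcomp(b)
  rc <- strsplit(revComp(b), "")[[1]]
  av <- strsplit(a, "")[[1]]
  na <- length(av); nb <- length(rc)
  best <- 0
  found <- FALSE
  for (off in (-(nb - 1L)):(na - 1L)) {
    i <- max(1L, 1L + off):min(na, nb + off)
    match <- av[i] == rc[i - off]
    r <- rle(match)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= 4L)) {
      # every sub-window of a maximal complementary run is itself a valid
      # duplex window; short GC-rich sub-windows can out-melt the full run
      for (ws in starts[k]:(ends[k] - 3L)) {
        for (we in (ws + 3L):ends[k]) {
          win <- paste(av[i[ws:we]], collapse = "")
          tm <- .nnTmCore(win, conditions)
          if (!found || tm > best) {
            best <- tm
            found <- TRUE
          }
        }
      }
    }
  }
  if (!found) 0 else best
}
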