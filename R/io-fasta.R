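IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", U = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

#' Read a FASTA file into a DNAStringSet
#'
#' Sequences are validated against the IUPAC nucleotide alphabet and stored
#' uppercase; soft-masking (lowercase) is discarded. Record order is
#' preserved and names are the first whitespace-delimited token of each
#' header, with the remainder kept as the element metadata column
#' `description`.
#'
#' @param path path to a FASTA file
#' @return a [Biostrings::DNAStringSet] with one element per record
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">chr1 demo", "ACGTACGT"), fa)
#' readFasta(fa)
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(raw))
  ids <- sub("\\s.*$", "", names(raw))
  desc <- sub("^\\S+\\s*", "", names(raw))
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0L)
      stop("record '", ids[i], "' has an empty sequence")
    bad <- which(!strsplit(seqs[i], "")[[1]] %in% IUPAC_CHARS)
    if (length(bad))
      stop("non-IUPAC character '",
           substr(seqs[i], bad[1], bad[1]),
           "' in record '", ids[i], "' at position ", bad[1])
  }
  # RNA-style U is a legal IUPAC code on input; stored as T in the DNA set
  out <- Biostrings::DNAStringSet(gsub("U", "T", seqs, fixed = TRUE))
  names(out) <- ids
  S4Vectors::mcols(out)$description <- ifelse(desc == ids, "", desc)
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs a [Biostrings::DNAStringSet] (or named character vector)
#' @param path output path
#' @param width line width for wrapping
#' @return `path`, invisibly
#' @export
writeFasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs))
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Reverse-complement a nucleotide sequence
#'
#' Handles the full IUPAC alphabet, mapping each ambiguity code to its
#' complement (R to Y, B to V, ...).
#'
#' @param seq a single nucleotide string (case-insensitive)
#' @return the reverse complement, uppercase
#' @examples
#' revComp("AAGT")  # "ACTT"
#' revComp("ARN")   # "NYT"
#' @export
revComp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- which(!chars %in% names(IUPAC_COMPLEMENT))
  if (length(bad))
    stop("invalid nucleotide character '", chars[bad[1]],
         "' at position ", bad[1])
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}
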