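#' Read a GFF3 annotation file into a GRanges
#'
#' A line-validating GFF3 reader: comment (`#`) and blank lines are
#' skipped, coordinates are checked (1-based inclusive, start <= end) and
#' malformed lines are reported with their line number. Column 9
#' attributes are parsed into a named character list stored in
#' `mcols(x)$attributes`; `ID` (when present) is also lifted into its own
#' metadata column.
#'
#' @param path path to a GFF3 file
#' @return a [GenomicRanges::GRanges] with metadata columns `source`,
#'   `type`, `score`, `phase`, `attributes`, `ID`
#' @export
readGff3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 9L))
    stop("GFF3 line ", idx[which(ncols < 9L)[1]],
         ": expected 9 tab-separated columns, found ",
         ncols[which(ncols < 9L)[1]])
  m <- do.call(rbind, lapply(fields, `[`, 1:9))
  seqid <- m[, 1]
  if (any(seqid == "")) stop("GFF3 line ", idx[which(seqid == "")[1]],
                             ": empty seqid")
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  badnum <- which(is.na(start) | is.na(end))
  if (length(badnum))
    stop("GFF3 line ", idx[badnum[1]], ": non-numeric coordinates")
  badord <- which(end < start | start < 1L)
  if (length(badord))
    stop("GFF3 line ", idx[badord[1]], ": invalid interval [",
         start[badord[1]], ", ", end[badord[1]], "]")
  strand <- m[, 7]
  strand[!strand %in% c("+", "-")] <- "*"
  attrs <- lapply(m[, 9], .parseGffAttributes)
  gr <- GenomicRanges::GRanges(
    seqnames = seqid,
    ranges = IRanges::IRanges(start = start, end = end),
    strand = strand
  )
  S4Vectors::mcols(gr)$source <- m[, 2]
  S4Vectors::mcols(gr)$type <- m[, 3]
  S4Vectors::mcols(gr)$score <- suppressWarnings(as.numeric(m[, 6]))
  S4Vectors::mcols(gr)$phase <- m[, 8]
  S4Vectors::mcols(gr)$attributes <- attrs
  S4Vectors::mcols(gr)$ID <- vapply(
    attrs, function(a) if ("ID" %in% names(a)) a[["ID"]] else NA_character_,
    character(1)
  )
  gr
}

.parseGffAttributes <- function(s) {
  if (is.na(s) || s == "." || s == "") return(character(0))
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  kv <- strsplit(parts, "=", fixed = TRUE)
  setNames(
    vapply(kv, function(x) paste(x[-1], collapse = "="), character(1)),
    vapply(kv, function(x) trimws(x[1]), character(1))
  )
}

#' Extract annotated features as sequences
#'
#' Slices each matching annotation out of the genome (1-based inclusive
#' coordinates) and reverse-complements minus-strand features, mirroring
#' the usual BEDTools-style exon extraction step that builds primer-design
#' input FASTA files. Output names encode the location as
#' `seqid:start-end(strand)`.
#'
#' @param genome a [Biostrings::DNAStringSet]
#' @param annotations a [GenomicRanges::GRanges] as from [readGff3()]
#' @param feature_type feature type to keep (e.g. `"exon"`); NULL keeps all
#' @param seqid optional: restrict to one chromosome/contig
#' @return a [Biostrings::DNAStringSet] of feature sequences
#' @export
extractFeatures <- function(genome, annotations, feature_type = NULL,
                            seqid = NULL) {
  stopifnot(methods::is(genome, "DNAStringSet"),
            methods::is(annotations, "GRanges"))
  gr <- annotations
  if (!is.null(feature_type))
    gr <- gr[S4Vectors::mcols(gr)$type %in% feature_type]
  if (!is.null(seqid))
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) %in% seqid]
  if (!length(gr)) return(Biostrings::DNAStringSet())
  sid <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(sid), names(genome))
  if (length(unknown))
    stop("seqid not present in genome: ", paste(unknown, collapse = ", "))
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)
  lens <- Biostrings::width(genome)[match(sid, names(genome))]
  over <- which(en > lens)
  if (length(over))
    stop("feature ", sid[over[1]], ":", st[over[1]], "-", en[over[1]],
         " extends beyond sequence length ", lens[over[1]])
  strand <- as.character(GenomicRanges::strand(gr))
  out <- Biostrings::DNAStringSet(vapply(seq_along(gr), function(i) {
    s <- as.character(Biostrings::subseq(genome[[sid[i]]], st[i], en[i]))
    if (strand[i] == "-") revComp(s) else s
  }, character(1)))
  names(out) <- sprintf("%s:%d-%d(%s)", sid, st, en,
                        ifelse(strand %in% c("+", "-"), strand, "."))
  out
}
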