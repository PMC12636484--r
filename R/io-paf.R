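#' Read minimap2 pairwise alignments (PAF)
#'
#' Parses the 12 mandatory tab-separated PAF columns; optional SAM-style
#' tags beyond column 12 are ignored. Coordinates are 0-based half-open as
#' emitted by minimap2. Each line is checked against the PAF invariants
#' (coordinates within sequence lengths, matches <= block length) and
#' violations are reported with their line number.
#'
#' @param path path to a PAF file
#' @return a data.frame with columns `query_name`, `query_len`,
#'   `query_start`, `query_end`, `strand`, `target_name`, `target_len`,
#'   `target_start`, `target_end`, `n_matches`, `block_len`, `mapq`
#' @export
readPaf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cols <- c("query_name", "query_len", "query_start", "query_end", "strand",
            "target_name", "target_len", "target_start", "target_end",
            "n_matches", "block_len", "mapq")
  if (!length(lines)) {
    out <- data.frame(matrix(nrow = 0, ncol = 12))
    names(out) <- cols
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 12L)
  if (length(short))
    stop("PAF line ", short[1], ": expected >= 12 tab-separated columns, found ",
         lengths(fields)[short[1]])
  m <- do.call(rbind, lapply(fields, `[`, 1:12))
  numcol <- c(2:4, 7:12)
  out <- data.frame(
    query_name = m[, 1],
    query_len = as.integer(m[, 2]),
    query_start = as.integer(m[, 3]),
    query_end = as.integer(m[, 4]),
    strand = m[, 5],
    target_name = m[, 6],
    target_len = as.integer(m[, 7]),
    target_start = as.integer(m[, 8]),
    target_end = as.integer(m[, 9]),
    n_matches = as.integer(m[, 10]),
    block_len = as.integer(m[, 11]),
    mapq = as.integer(m[, 12]),
    stringsAsFactors = FALSE
  )
  if (anyNA(out[numcol]))
    stop("PAF line ", which(rowSums(is.na(out[numcol])) > 0)[1],
         ": non-numeric value in a numeric column")
  bad <- which(
    out$query_start < 0L | out$query_start >= out$query_end |
      out$query_end > out$query_len |
      out$target_start < 0L | out$target_start >= out$target_end |
      out$target_end > out$target_len |
      out$n_matches > out$block_len |
      !out$strand %in% c("+", "-") |
      out$mapq < 0L | out$mapq > 255L
  )
  if (length(bad))
    stop("PAF line ", bad[1], ": invariant violation (coordinates, strand, ",
         "mapq range, or n_matches > block_len)")
  out
}
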