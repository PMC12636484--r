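#' Aggregate PAF alignments into per-contig, per-chromosome evidence
#'
#' Sums matching bases (`n_matches`) for every (query contig, target
#' chromosome) combination after discarding alignments below the mapping
#' quality or block length cutoffs. Secondary/supplementary records are
#' not distinguished (optional PAF tags are ignored); mapq is the only
#' quality gate.
#'
#' @param paf data.frame as returned by [readPaf()]
#' @param min_mapq minimum mapping quality (default 10)
#' @param min_block minimum alignment block length in bp (default 1000)
#' @return a data.frame with columns `query_name`, `target_name`,
#'   `aligned_bases`
#' @export
aggregateAlignments <- function(paf, min_mapq = 10L, min_block = 1000L) {
  cols <- c("query_name", "target_name", "n_matches", "mapq", "block_len")
  stopifnot(all(cols %in% names(paf)))
  keep <- paf$mapq >= min_mapq & paf$block_len >= min_block
  paf <- paf[keep, , drop = FALSE]
  if (!nrow(paf)) {
    return(data.frame(query_name = character(0), target_name = character(0),
                      aligned_bases = integer(0), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(
    list(aligned_bases = paf$n_matches),
    by = list(query_name = paf$query_name, target_name = paf$target_name),
    FUN = sum
  )
  agg[order(agg$query_name, -agg$aligned_bases), , drop = FALSE]
}

#' Assign contigs to chromosomes and flag putative Z-linked contigs
#'
#' For each contig, the chromosome collecting the most aligned bases wins
#' if it holds at least `min_fraction` of the contig's total aligned bases
#' and the total is at least `min_bases`; otherwise the contig is left
#' unassigned. Boundary cases are treated conservatively: two chromosomes
#' with equal best evidence, or a best fraction sitting exactly on the
#' threshold, are never assigned (a fraction of exactly 1 — all evidence on
#' one chromosome — always qualifies). A false Z call is the costly error
#' for downstream primer design. A contig is flagged `is_z` when its
#' assigned chromosome equals `z_id`.
#'
#' @param aggregate data.frame from [aggregateAlignments()]
#' @param z_id identifier of the reference Z chromosome
#' @param min_fraction minimum fraction of aligned bases on the best
#'   chromosome, in (0.5, 1] (default 0.6)
#' @param min_bases minimum total aligned bases (default 5000)
#' @return a data.frame with one row per contig: `contig_id`,
#'   `assigned_target`, `total_aligned`, `best_fraction`, `is_z`
#' @examples
#' paf <- data.frame(query_name = "c1", target_name = c("chrZ", "chr1"),
#'                   n_matches = c(8000L, 2000L), mapq = 60L,
#'                   block_len = c(9000L, 2500L))
#' assignContigs(aggregateAlignments(paf), z_id = "chrZ")
#' @export
assignContigs <- function(aggregate, z_id, min_fraction = 0.6,
                          min_bases = 5000L) {
  if (!(min_fraction > 0.5 && min_fraction <= 1))
    stop("min_fraction must be in (0.5, 1]")
  stopifnot(all(c("query_name", "target_name", "aligned_bases") %in%
                  names(aggregate)))
  if (!nrow(aggregate)) {
    return(data.frame(contig_id = character(0),
                      assigned_target = character(0),
                      total_aligned = integer(0), best_fraction = numeric(0),
                      is_z = logical(0), stringsAsFactors = FALSE))
  }
  contigs <- unique(aggregate$query_name)
  rows <- lapply(contigs, function(ct) {
    sub <- aggregate[aggregate$query_name == ct, , drop = FALSE]
    total <- sum(sub$aligned_bases)
    best <- max(sub$aligned_bases)
    bestTargets <- sub$target_name[sub$aligned_bases == best]
    frac <- best / total
    tie <- length(bestTargets) > 1L
    passFrac <- frac > min_fraction || frac == 1
    assigned <- if (!tie && passFrac && total >= min_bases)
      bestTargets[1] else NA_character_
    data.frame(
      contig_id = ct,
      assigned_target = assigned,
      total_aligned = total,
      best_fraction = frac,
      is_z = !is.na(assigned) && assigned == z_id,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
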