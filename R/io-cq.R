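CQ_TARGETS <- c("autosome", "sex")

#' Read a technical-replicate Cq table
#'
#' The on-disk schema is a comma-separated file with header
#' `sample_id,target,cq` and one row per technical replicate; `target`
#' must be `autosome` or `sex`. Rows are validated (finite, positive Cq)
#' and reported with their row number on failure. Replicate order within
#' each (sample, target) group is preserved.
#'
#' @param path path to a CSV file
#' @return a data.frame with columns `sample_id`, `target`, `cq`
#' @seealso [writeCqTable()], [runBatch()]
#' @export
readCqTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "character"))
  need <- c("sample_id", "target", "cq")
  if (!all(need %in% names(df)))
    stop("Cq table must have header columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  badTarget <- which(!df$target %in% CQ_TARGETS)
  if (length(badTarget))
    stop("row ", badTarget[1], ": unknown target '", df$target[badTarget[1]],
         "' (expected one of: ", paste(CQ_TARGETS, collapse = ", "), ")")
  cq <- suppressWarnings(as.numeric(df$cq))
  badCq <- which(is.na(cq) | !is.finite(cq) | cq <= 0)
  if (length(badCq))
    stop("row ", badCq[1], ": unparseable or non-positive cq value '",
         df$cq[badCq[1]], "'")
  data.frame(sample_id = df$sample_id, target = df$target, cq = cq,
             stringsAsFactors = FALSE)
}

#' Write a Cq table
#'
#' @param cq data.frame with columns `sample_id`, `target`, `cq`
#' @param path output path
#' @return `path`, invisibly
#' @export
writeCqTable <- function(cq, path) {
  stopifnot(all(c("sample_id", "target", "cq") %in% names(cq)))
  utils::write.csv(cq[, c("sample_id", "target", "cq")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Group a Cq table into per-(sample, target) replicate sets
#'
#' @param cq data.frame as returned by [readCqTable()]
#' @param minReplicates minimum replicates per group (error below it)
#' @return a data.frame with one row per (sample_id, target) and a
#'   list-column `replicate_cqs`
#' @export
groupMeasurements <- function(cq, minReplicates = 1L) {
  stopifnot(all(c("sample_id", "target", "cq") %in% names(cq)))
  key <- paste(cq$sample_id, cq$target, sep = "\r")
  groups <- split(cq$cq, factor(key, levels = unique(key)))
  ids <- strsplit(names(groups), "\r", fixed = TRUE)
  out <- data.frame(
    sample_id = vapply(ids, `[`, character(1), 1),
    target = vapply(ids, `[`, character(1), 2),
    stringsAsFactors = FALSE
  )
  out$replicate_cqs <- unname(groups)
  small <- lengths(out$replicate_cqs) < minReplicates
  if (any(small))
    stop("fewer than ", minReplicates, " replicates for sample '",
         out$sample_id[which(small)[1]], "', target '",
         out$target[which(small)[1]], "'")
  out
}
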