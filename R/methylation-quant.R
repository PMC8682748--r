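#' Binarize a log-likelihood ratio into a methylation call
#'
#' In the default three-way semantics a call is `"methylated"` when
#' `llr >= threshold`, `"unmethylated"` when `llr <= -threshold`, and
#' `"uncalled"` in between; uncalled rows are excluded from frequency
#' denominators. The `"two_way"` mode (used by the ROC threshold scan)
#' predicts `"methylated"` iff `llr >= threshold` and `"unmethylated"`
#' otherwise. The default threshold of 5 is the stringent calling cut-off;
#' the upstream caller's own default is 2.5.
#'
#' @param llr Numeric vector of log-likelihood ratios.
#' @param threshold Positive calling threshold (default 5).
#' @param mode `"three_way"` (default) or `"two_way"`.
#' @return Character vector of calls.
#' @export
binarize_call <- function(llr, threshold = 5, mode = c("three_way", "two_way")) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0)
  if (mode == "two_way") {
    return(ifelse(llr >= threshold, "methylated", "unmethylated"))
  }
  ifelse(llr >= threshold, "methylated",
         ifelse(llr <= -threshold, "unmethylated", "uncalled"))
}

#' Split grouped CpG calls into per-site calls
#'
#' Joint-calling callers emit one LLR per group of neighbouring CpGs. This
#' fans each group row out to one row per member CpG, every member inheriting
#' the group's LLR (and therefore its classification), so that per-site
#' frequencies can be computed. The group span must contain exactly
#' `num_motifs` CpGs of the genome, otherwise a data-integrity error is
#' raised.
#'
#' @param calls Call table (columns `start`, `end`, `num_motifs`,
#'   `read_name`, `strand`, `log_lik_ratio`).
#' @param cpg_positions Sorted 1-based CpG positions of the reference the
#'   calls were made against.
#' @return data.frame of per-site calls: `position`, `read_name`, `strand`,
#'   `log_lik_ratio`.
#' @export
split_groups <- function(calls, cpg_positions) {
  if (!nrow(calls)) {
    return(data.frame(position = integer(), read_name = character(),
                      strand = character(), log_lik_ratio = numeric(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(calls$start, calls$end)
  spans <- !duplicated(key)
  span_sites <- lapply(which(spans), function(i) {
    cpg_positions[cpg_positions >= calls$start[i] &
                    cpg_positions <= calls$end[i]]
  })
  names(span_sites) <- key[spans]
  expected <- calls$num_motifs[spans]
  found <- lengths(span_sites)
  if (any(found != expected)) {
    bad <- which(found != expected)[1L]
    stop(sprintf(
      "group %s contains %d CpGs in the reference but num_motifs = %d",
      names(span_sites)[bad], found[bad], expected[bad]
    ))
  }
  span_id <- match(key, names(span_sites))
  times <- found[span_id]
  rows <- rep.int(seq_len(nrow(calls)), times)
  data.frame(
    position = unlist(span_sites[span_id], use.names = FALSE),
    read_name = calls$read_name[rows],
    strand = calls$strand[rows],
    log_lik_ratio = calls$log_lik_ratio[rows],
    stringsAsFactors = FALSE
  )
}

#' Per-site methylation frequencies from per-site calls
#'
#' Calls are classified three-way at `threshold`; uncalled rows are dropped.
#' Per position, `called_reads` is the number of classified calls,
#' `methylated_reads` the number classified methylated, and
#' `frequency = methylated_reads / called_reads`. Positions with no classified
#' call are omitted.
#'
#' @param site_calls data.frame from [split_groups()].
#' @param threshold Calling threshold (default 5).
#' @return data.frame with columns `position`, `called_reads`,
#'   `methylated_reads`, `frequency`, `masked`, `blacklist_hit` (the last two
#'   initialised `FALSE`).
#' @export
site_frequency <- function(site_calls, threshold = 5) {
  cls <- binarize_call(site_calls$log_lik_ratio, threshold)
  keep <- cls != "uncalled"
  pos <- site_calls$position[keep]
  meth <- cls[keep] == "methylated"
  if (!length(pos)) {
    return(data.frame(position = integer(), called_reads = integer(),
                      methylated_reads = integer(), frequency = numeric(),
                      masked = logical(), blacklist_hit = logical()))
  }
  agg <- rowsum(cbind(called = 1L, methylated = as.integer(meth)), group = pos)
  out <- data.frame(
    position = as.integer(rownames(agg)),
    called_reads = as.integer(agg[, "called"]),
    methylated_reads = as.integer(agg[, "methylated"])
  )
  out$frequency <- out$methylated_reads / out$called_reads
  out$masked <- FALSE
  out$blacklist_hit <- FALSE
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genome-wide mean methylation (percent)
#'
#' Unweighted mean of per-site frequencies over sites that are neither masked
#' nor blacklisted (unless `include_masked`), expressed in percent. A
#' depth-weighted mean (total methylated calls over total called) is available
#' via `weighted = TRUE`.
#'
#' @param sites data.frame from [site_frequency()].
#' @param include_masked Include masked/blacklisted sites (default `FALSE`).
#' @param weighted Use the call-weighted mean instead of the per-site mean.
#' @return Mean methylation in percent.
#' @export
genome_mean_methylation <- function(sites, include_masked = FALSE,
                                    weighted = FALSE) {
  use <- if (include_masked) sites else
    sites[!sites$masked & !sites$blacklist_hit, , drop = FALSE]
  if (!nrow(use)) stop("no unmasked sites: genome mean undefined")
  if (weighted) {
    100 * sum(use$methylated_reads) / sum(use$called_reads)
  } else {
    100 * mean(use$frequency)
  }
}

#' Call table to per-site frequency table
#'
#' Convenience composition: [split_groups()] then [site_frequency()]. The mean
#' per-site called-read count is attached as attribute `mean_depth`.
#'
#' @param calls Call table (grouped rows).
#' @param genome A [circular_genome()] (supplies the CpG positions).
#' @param threshold Calling threshold.
#' @return Per-site table as from [site_frequency()].
#' @export
call_table_frequencies <- function(calls, genome, threshold = 5) {
  sites <- site_frequency(split_groups(calls, genome$cpg_positions), threshold)
  attr(sites, "mean_depth") <-
    if (nrow(sites)) mean(sites$called_reads) else 0
  sites
}
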