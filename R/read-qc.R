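#' Filter read summaries on length and quality
#'
#' Retains reads with `min_len <= length <= max_len` and `mean_q >= min_q`;
#' all three boundaries are inclusive. The defaults (4,000-17,000 bases,
#' Phred >= 9) enrich for linear full-length mitochondrial molecules while
#' excluding short species such as 7S DNA (~650 bases) and most nuclear
#' mitochondrial-like sequences.
#'
#' @param reads data.frame with columns `length` and `mean_q`.
#' @param min_len,max_len Length bounds in bases.
#' @param min_q Minimum mean per-read Phred quality.
#' @return The retained subset (idempotent).
#' @export
filter_reads <- function(reads, min_len = 4000L, max_len = 17000L, min_q = 9) {
  stopifnot(min_len < max_len)
  keep <- reads$length >= min_len & reads$length <= max_len &
    reads$mean_q >= min_q
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rotate circular coordinates to/from an alternative origin
#'
#' Linear aligners split reads that cross the reference origin. Re-origining
#' the reference at the restriction cut site avoids this for enzyme-linearised
#' libraries; this helper translates 1-based positions between the original
#' and the rotated coordinate systems. `offset` is the 0-based position of the
#' new origin (new origin base minus one), so rotating base 14,259 with
#' `offset = 14258` gives base 1.
#'
#' @param pos Integer vector of 1-based positions in `[1, genome_length]`.
#' @param offset 0-based offset of the new origin.
#' @param genome_length Circle length.
#' @param direction `"to_rotated"` or `"to_original"`; the two are exact
#'   inverses.
#' @return Integer vector of translated 1-based positions.
#' @export
rotate_coordinates <- function(pos, offset, genome_length,
                               direction = c("to_rotated", "to_original")) {
  direction <- match.arg(direction)
  L <- as.integer(genome_length)
  if (offset < 0 || offset >= L) stop("offset must lie in [0, genome_length)")
  if (any(pos < 1L | pos > L)) stop("positions must lie in [1, genome_length]")
  if (direction == "to_rotated") {
    ((pos - 1L - offset) %% L) + 1L
  } else {
    ((pos - 1L + offset) %% L) + 1L
  }
}

#' Rescue origin-spanning supplementary alignments for one read
#'
#' A supplementary alignment is accepted only if it maps to the mitochondrial
#' target on the same strand and in the same orientation as the primary, and
#' the primary/supplementary pair jointly spans the reference origin: one
#' segment ends within `junction_slack` bases of the genome end and the other
#' starts within `junction_slack` bases of base 1. A read with any
#' supplementary alignment on the nuclear genome is excluded entirely and
#' flagged as a possible NuMT. Other failing supplementaries are rejected
#' while the primary is kept.
#'
#' @param primary One-row data.frame: the primary alignment.
#' @param supplementaries data.frame of supplementary alignments (may be
#'   empty); all records must share the primary's `read_name`.
#' @param genome_length Circle length.
#' @param junction_slack Allowed distance (bases) from the origin junction.
#' @return List with `accepted` (data.frame of kept alignments),
#'   `excluded` (logical: whole read dropped), `possible_numt` (logical) and
#'   `origin_spanning` (logical).
#' @export
rescue_supplementary <- function(primary, supplementaries, genome_length,
                                 junction_slack = 50L) {
  if (nrow(primary) != 1L) stop("exactly one primary alignment expected")
  if (nrow(supplementaries) &&
      any(supplementaries$read_name != primary$read_name)) {
    stop("all alignments must share the primary's read_name")
  }
  L <- as.integer(genome_length)
  if (nrow(supplementaries) && any(supplementaries$target == "nuclear")) {
    return(list(
      accepted = primary[0L, , drop = FALSE],
      excluded = TRUE, possible_numt = TRUE, origin_spanning = FALSE
    ))
  }
  spans_origin <- function(a_end, b_start) {
    (L - a_end) <= junction_slack && (b_start - 1L) <= junction_slack
  }
  ok <- logical(nrow(supplementaries))
  for (i in seq_len(nrow(supplementaries))) {
    s <- supplementaries[i, ]
    same <- s$target == "mito" &&
      s$strand == primary$strand &&
      s$orientation == primary$orientation
    junction <- spans_origin(min(primary$end, L), s$start) ||
      spans_origin(min(s$end, L), primary$start)
    ok[i] <- same && junction
  }
  list(
    accepted = rbind(primary, supplementaries[ok, , drop = FALSE]),
    excluded = FALSE,
    possible_numt = FALSE,
    origin_spanning = any(ok)
  )
}

#' Apply supplementary-alignment rescue across a whole alignment table
#'
#' @param alignments data.frame of alignment records (several rows per read;
#'   exactly one non-supplementary row per read).
#' @param genome_length Circle length.
#' @param junction_slack See [rescue_supplementary()].
#' @return List with `accepted` (data.frame of all kept alignments) and
#'   `numt_reads` (character vector of excluded read names).
#' @export
rescue_all <- function(alignments, genome_length, junction_slack = 50L) {
  pieces <- split(alignments, alignments$read_name)
  kept <- vector("list", length(pieces))
  numt <- character()
  for (i in seq_along(pieces)) {
    a <- pieces[[i]]
    prim <- a[!a$is_supplementary, , drop = FALSE]
    if (nrow(prim) != 1L) stop("duplicate primary records for read ",
                               a$read_name[1L])
    res <- rescue_supplementary(prim, a[a$is_supplementary, , drop = FALSE],
                                genome_length, junction_slack)
    if (res$excluded) {
      numt <- c(numt, prim$read_name)
    } else {
      kept[[i]] <- res$accepted
    }
  }
  accepted <- do.call(rbind, kept[!vapply(kept, is.null, logical(1))])
  if (is.null(accepted)) accepted <- alignments[0L, , drop = FALSE]
  rownames(accepted) <- NULL
  list(accepted = accepted, numt_reads = numt)
}

#' Enrichment statistics for a read set
#'
#' @param reads data.frame of read summaries (column `target` marks `mito`
#'   versus `nuclear`).
#' @param genome_length Mitochondrial genome length in bases.
#' @param full_length_min Length at or above which a mitochondrial read counts
#'   as full-length (default 15,000 bases).
#' @return List with `mito_read_fraction`, `full_length_fraction` (among mito
#'   reads), `mean_depth` (mito aligned bases / genome length) and
#'   `per_strand_fractions` (named numeric, H and L, among mito reads).
#' @export
enrichment_stats <- function(reads, genome_length, full_length_min = 15000L) {
  if (!nrow(reads)) stop("empty read set")
  mito <- reads[reads$target == "mito", , drop = FALSE]
  strands <- c(H = 0, L = 0)
  if (nrow(mito)) {
    tab <- table(factor(mito$strand, levels = c("H", "L")))
    strands <- as.numeric(tab) / nrow(mito)
    names(strands) <- c("H", "L")
  }
  list(
    mito_read_fraction = nrow(mito) / nrow(reads),
    full_length_fraction =
      if (nrow(mito)) mean(mito$length >= full_length_min) else NA_real_,
    mean_depth = sum(pmin(mito$length, genome_length)) / genome_length,
    per_strand_fractions = strands
  )
}
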