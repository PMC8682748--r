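#' Build a false-positive blacklist from negative-control methylation
#'
#' In an unmethylated control every apparent methylation frequency is noise.
#' Positions whose frequency is strictly greater than
#' `mean + k * sd` of the negative-control per-site frequencies are
#' blacklisted (sample standard deviation, n - 1). With `k = 2` this is the
#' "above two standard deviations from the negative-control mean" rule.
#'
#' @param nc_sites Per-site table (from [site_frequency()]) of the negative
#'   control; at least 2 sites.
#' @param k Standard-deviation multiplier (default 2).
#' @return Object of class `blacklist`: list with `positions`, `nc_mean`,
#'   `nc_sd`, `cutoff` and `k`.
#' @export
build_blacklist <- function(nc_sites, k = 2) {
  if (nrow(nc_sites) < 2L) stop("need at least 2 negative-control sites")
  f <- nc_sites$frequency
  mu <- mean(f)
  sdev <- stats::sd(f)
  cutoff <- mu + k * sdev
  structure(
    list(
      positions = nc_sites$position[f > cutoff],
      nc_mean = mu, nc_sd = sdev, cutoff = cutoff, k = k
    ),
    class = "blacklist"
  )
}

#' @export
print.blacklist <- function(x, ...) {
  cat(sprintf(
    "<blacklist> %d positions (NC mean %.4f, sd %.4f, cutoff %.4f, k = %g)\n",
    length(x$positions), x$nc_mean, x$nc_sd, x$cutoff, x$k
  ))
  invisible(x)
}

#' Flag blacklisted positions in a per-site table
#'
#' Only flags are set; frequencies are never altered.
#'
#' @param sites Per-site table.
#' @param blacklist A [build_blacklist()] result (or integer positions).
#' @return `sites` with `blacklist_hit` updated.
#' @export
apply_blacklist <- function(sites, blacklist) {
  pos <- if (inherits(blacklist, "blacklist")) blacklist$positions else blacklist
  sites$blacklist_hit <- sites$position %in% pos
  sites
}

#' Mask CpG sites near heteroplasmic variants
#'
#' A nucleotide variant within the caller's k-mer window shifts the expected
#' signal and produces false methylation calls at neighbouring CpGs. A CpG at
#' position p (the called C) is masked iff some variant with
#' `vaf < het_cutoff` lies at circular distance <= `window` from p (boundary
#' inclusive). Homoplasmic variants (vaf at or above the cutoff) are handled
#' by consensus substitution instead, see [build_consensus()].
#'
#' @param cpg_positions Integer vector of 1-based CpG positions.
#' @param variants Variant table (columns `position`, `vaf`).
#' @param window Window half-width in nt (default 5).
#' @param het_cutoff Heteroplasmy cutoff (default 0.9, strict `<`).
#' @param genome_length Circle length.
#' @return Integer vector of masked CpG positions.
#' @export
proximity_mask <- function(cpg_positions, variants, window = 5L,
                           het_cutoff = 0.9, genome_length) {
  stopifnot(window >= 0)
  het <- variants$position[variants$vaf < het_cutoff]
  if (!length(het) || !length(cpg_positions)) return(integer())
  d <- outer(cpg_positions, het,
             function(a, b) circular_distance(a, b, genome_length))
  sort(cpg_positions[apply(d <= window, 1L, any)])
}

#' Flag masked positions in a per-site table
#' @param sites Per-site table.
#' @param masked_positions Integer positions from [proximity_mask()].
#' @return `sites` with `masked` updated.
#' @export
apply_mask <- function(sites, masked_positions) {
  sites$masked <- sites$position %in% masked_positions
  sites
}

#' Build a sample-specific consensus reference
#'
#' Substitutes the alternate allele at every variant position with
#' `vaf > major_cutoff` (major alleles), leaving length unchanged, and
#' rescans CpG positions on the new sequence — a CpG destroyed by a
#' substitution disappears from the consensus CpG list, and a substitution may
#' create new CpGs. Only single-nucleotide substitutions are supported; rows
#' with multi-base alleles are rejected.
#'
#' @param reference A [circular_genome()].
#' @param variants Variant table (columns `position`, `ref_allele`,
#'   `alt_allele`, `vaf`).
#' @param major_cutoff Allele-fraction cutoff for substitution (default 0.5,
#'   strict `>`).
#' @return A [circular_genome()] named `<reference name>_consensus`.
#' @export
build_consensus <- function(reference, variants, major_cutoff = 0.5) {
  stopifnot(inherits(reference, "circular_genome"))
  major <- variants[variants$vaf > major_cutoff, , drop = FALSE]
  if (any(nchar(major$ref_allele) != 1L | nchar(major$alt_allele) != 1L)) {
    stop("only single-nucleotide substitutions are supported")
  }
  if (anyDuplicated(major$position)) {
    dup <- major[major$position %in% major$position[duplicated(major$position)], ]
    if (nrow(unique(dup[c("position", "alt_allele")])) > length(unique(dup$position))) {
      stop("conflicting major alleles at position ",
           paste(unique(dup$position), collapse = ", "))
    }
    major <- major[!duplicated(major$position), , drop = FALSE]
  }
  chars <- strsplit(reference$sequence, "", fixed = TRUE)[[1]]
  if (nrow(major)) {
    mismatch <- chars[major$position] != major$ref_allele
    if (any(mismatch)) {
      warning(sum(mismatch), " variant(s) whose ref allele does not match the reference")
    }
    chars[major$position] <- major$alt_allele
  }
  circular_genome(paste(chars, collapse = ""),
                  name = paste0(reference$name, "_consensus"))
}

#' Check that consensus recalling removes variant-adjacent artifacts
#'
#' Methylation calling against a mismatching reference produces false
#' positives at CpGs near homoplasmic (major-allele) variants; recalling
#' against the sample consensus should remove them. For each homoplasmic
#' variant, CpGs within `window` nt whose reference-called frequency exceeds
#' `cutoff` are listed, with their consensus-called frequency (`NA` when the
#' CpG no longer exists or was not called on the consensus) and a `resolved`
#' flag (consensus frequency at or below the cutoff, or site absent).
#'
#' @param site_table_ref Per-site table called against the generic reference.
#' @param site_table_consensus Per-site table called against the consensus.
#' @param variants Variant table (columns `position`, `vaf`).
#' @param cutoff Frequency above which a site counts as an apparent positive
#'   (typically the blacklist cutoff).
#' @param window Window half-width in nt (default 5).
#' @param hom_cutoff Allele fraction at or above which a variant counts as
#'   homoplasmic (default 0.9).
#' @param genome_length Circle length.
#' @return List with `flagged` (data.frame: `variant_position`,
#'   `cpg_position`, `freq_reference`, `freq_consensus`, `resolved`) and
#'   `n_removed` (count of resolved sites).
#' @export
consensus_recall_check <- function(site_table_ref, site_table_consensus,
                                   variants, cutoff, window = 5L,
                                   hom_cutoff = 0.9, genome_length) {
  hom <- variants$position[variants$vaf >= hom_cutoff]
  rows <- list()
  for (v in hom) {
    d <- circular_distance(site_table_ref$position, v, genome_length)
    near <- site_table_ref[d <= window & site_table_ref$frequency > cutoff, ,
                           drop = FALSE]
    if (!nrow(near)) next
    fc <- site_table_consensus$frequency[
      match(near$position, site_table_consensus$position)]
    rows[[length(rows) + 1L]] <- data.frame(
      variant_position = v,
      cpg_position = near$position,
      freq_reference = near$frequency,
      freq_consensus = fc,
      resolved = is.na(fc) | fc <= cutoff
    )
  }
  flagged <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant_position = integer(), cpg_position = integer(),
               freq_reference = numeric(), freq_consensus = numeric(),
               resolved = logical())
  rownames(flagged) <- NULL
  list(flagged = flagged, n_removed = sum(flagged$resolved))
}
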