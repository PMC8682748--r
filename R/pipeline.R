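#' Run the full methylation audit over a cohort
#'
#' Composes the pipeline in its natural order for every sample:
#' quantification (binarize at the LLR threshold, split grouped CpGs, per-site
#' frequencies), negative-control blacklisting, heteroplasmic-variant
#' proximity masking, consensus rebuild with recall checking (when a
#' consensus-based call table is supplied, it becomes the sample's call table,
#' mirroring methylation calling against a sample-specific reference), then
#' background-noise fitting on the negative control and a per-sample verdict.
#'
#' @param samples Named list; each element is a list with components
#'   `calls` (grouped call table, required), `variants` (variant table or
#'   `NULL`) and `consensus_calls` (call table produced against the sample
#'   consensus, or `NULL`).
#' @param nc_calls Grouped call table of the unmethylated negative control.
#' @param genome The reference [circular_genome()].
#' @param threshold LLR calling threshold (default 5).
#' @param window Variant-proximity window in nt (default 5).
#' @param het_cutoff Heteroplasmy cutoff for masking (default 0.9).
#' @param blacklist_k Blacklist standard-deviation multiplier (default 2).
#' @param consensus_cutoff Allele fraction above which the consensus carries
#'   the alternate allele (default 0.9; variants at or above it are treated as
#'   major alleles).
#' @param fractions Subsampling fractions for the noise fit (default 30
#'   log-spaced values).
#' @param seed Integer seed driving the subsampling.
#' @param outdir Optional directory; when given, per-sample site tables, the
#'   report, the blacklist and the noise model are written there.
#' @return Object of class `audit_result`: list with `reports` (data.frame,
#'   one row per sample: `sample_id`, `mean_depth`, `n_sites_called`,
#'   `n_blacklisted`, `n_masked`, `mean_methylation_pct`,
#'   `predicted_noise_pct`, `verdict`), `noise_model`, `blacklist`,
#'   `recall_checks` and `site_tables`.
#' @export
run_audit <- function(samples, nc_calls, genome,
                      threshold = 5, window = 5L, het_cutoff = 0.9,
                      blacklist_k = 2, consensus_cutoff = 0.9,
                      fractions = NULL, seed = 1L, outdir = NULL) {
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    stop("samples must be a named list")
  }
  if (is.null(nc_calls)) {
    stop("a negative-control call table is required to fit the noise model")
  }

  nc_sites <- call_table_frequencies(nc_calls, genome, threshold)
  blacklist <- build_blacklist(nc_sites, k = blacklist_k)
  message(sprintf("blacklist: %d position(s) above NC mean + %g sd",
                  length(blacklist$positions), blacklist_k))

  points <- subsample_calls(nc_calls, genome, fractions = fractions,
                            seed = seed, threshold = threshold)
  model <- fit_noise_model(points)
  message(sprintf(
    "noise model: m = %.4g, t = %.4g, b = %.4g (R^2 = %s, %d points)",
    model$m, model$t, model$b,
    if (is.na(model$r_squared)) "NA" else sprintf("%.3f", model$r_squared),
    nrow(model$data)))

  reports <- vector("list", length(samples))
  recalls <- list()
  site_tables <- list()
  for (i in seq_along(samples)) {
    id <- names(samples)[i]
    s <- samples[[i]]
    variants <- s$variants

    sample_genome <- genome
    active_calls <- s$calls
    if (!is.null(s$consensus_calls)) {
      if (is.null(variants)) {
        stop("sample ", id, ": consensus_calls supplied without variants")
      }
      sample_genome <- build_consensus(
        genome, variants, major_cutoff = consensus_cutoff - 1e-9)
      active_calls <- s$consensus_calls
    }

    sites <- call_table_frequencies(active_calls, sample_genome, threshold)
    mean_depth <- attr(sites, "mean_depth")
    n_called <- nrow(sites)

    if (!is.null(s$consensus_calls)) {
      ref_sites <- call_table_frequencies(s$calls, genome, threshold)
      recalls[[id]] <- consensus_recall_check(
        ref_sites, sites, variants, cutoff = blacklist$cutoff,
        window = window, hom_cutoff = consensus_cutoff,
        genome_length = genome$length)
      message(sprintf(
        "%s: consensus recall resolved %d variant-adjacent site(s)",
        id, recalls[[id]]$n_removed))
    }

    sites <- apply_blacklist(sites, blacklist)
    if (!is.null(variants)) {
      masked <- proximity_mask(sample_genome$cpg_positions, variants,
                               window = window, het_cutoff = het_cutoff,
                               genome_length = genome$length)
      sites <- apply_mask(sites, masked)
    }
    message(sprintf(
      "%s: %d sites called, %d blacklisted, %d masked",
      id, n_called, sum(sites$blacklist_hit), sum(sites$masked)))

    mean_meth <- genome_mean_methylation(sites)
    verdict <- noise_verdict(mean_meth, mean_depth, model)
    site_tables[[id]] <- sites
    reports[[i]] <- data.frame(
      sample_id = id,
      mean_depth = mean_depth,
      n_sites_called = n_called,
      n_blacklisted = sum(sites$blacklist_hit),
      n_masked = sum(sites$masked),
      mean_methylation_pct = mean_meth,
      predicted_noise_pct = verdict$predicted_noise,
      verdict = if (verdict$above_noise) "above_noise" else "below_noise",
      stringsAsFactors = FALSE
    )
  }
  report <- do.call(rbind, reports)
  rownames(report) <- NULL

  result <- structure(
    list(reports = report, noise_model = model, blacklist = blacklist,
         recall_checks = recalls, site_tables = site_tables,
         noise_points = points),
    class = "audit_result"
  )
  if (!is.null(outdir)) write_audit_result(result, outdir)
  result
}

#' @export
print.audit_result <- function(x, ...) {
  cat(sprintf("<audit_result> %d sample(s)\n", nrow(x$reports)))
  print(x$reports)
  invisible(x)
}

#' Write an audit result to disk
#'
#' Emits `report.tsv`, `blacklist.tsv`, `noise_model.json`,
#' `noise_points.tsv` and one `sites_<sample>.tsv` per sample under `outdir`.
#'
#' @param result An `audit_result`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_audit_result <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv_write(result$reports, file.path(outdir, "report.tsv"))
  tsv_write(data.frame(position = result$blacklist$positions),
            file.path(outdir, "blacklist.tsv"))
  tsv_write(result$noise_points, file.path(outdir, "noise_points.tsv"))
  jsonlite::write_json(
    list(m = result$noise_model$m, t = result$noise_model$t,
         b = result$noise_model$b, r_squared = result$noise_model$r_squared),
    file.path(outdir, "noise_model.json"), auto_unbox = TRUE, digits = NA)
  for (id in names(result$site_tables)) {
    tsv_write(result$site_tables[[id]],
              file.path(outdir, paste0("sites_", id, ".tsv")))
  }
  invisible(outdir)
}
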