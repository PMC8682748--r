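#' Construct a circular genome object
#'
#' A `circular_genome` holds a nucleotide sequence that is topologically
#' circular, as the ~16.6 kb mitochondrial genome is. CpG positions (the 1-based
#' position of the C of each forward-strand CpG dinucleotide) are recomputed
#' from the sequence by [find_cpg_sites()], so the listed positions always
#' agree with a rescan, including the wrap-around pair (last base, first base).
#'
#' All coordinates in this package are 1-based and inclusive, following the
#' convention used by mitochondrial variant nomenclature and by the file
#' formats the package reads and writes.
#'
#' @param sequence Nucleotide string (A/C/G/T).
#' @param name Sequence name used in emitted files.
#' @return An object of class `circular_genome`: a list with elements `name`,
#'   `sequence`, `length` and `cpg_positions` (sorted, 1-based).
#' @export
circular_genome <- function(sequence, name = "chrM_synthetic") {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) {
    stop("sequence may only contain A, C, G, T")
  }
  g <- list(
    name = name,
    sequence = sequence,
    length = nchar(sequence),
    cpg_positions = find_cpg_sites(sequence)
  )
  class(g) <- "circular_genome"
  g
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf(
    "<circular_genome> %s: %d bp, %d CpG sites\n",
    x$name, x$length, length(x$cpg_positions)
  ))
  invisible(x)
}

#' Locate CpG dinucleotides on a circular sequence
#'
#' Returns the 1-based positions p such that `sequence[p] == "C"` and the
#' circularly-next base is `"G"` (so a C at the final base followed by a G at
#' base 1 counts).
#'
#' @param sequence Nucleotide string.
#' @return Sorted integer vector of C positions.
#' @export
find_cpg_sites <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  if (length(chars) < 2L) return(integer())
  nxt <- c(chars[-1L], chars[1L])
  which(chars == "C" & nxt == "G")
}

#' Circular (shortest-arc) distance between positions
#'
#' @param a,b Integer position vectors (recycled).
#' @param genome_length Length of the circle in bases.
#' @return Integer vector of shortest distances along the circle.
#' @export
circular_distance <- function(a, b, genome_length) {
  stopifnot(genome_length > 0)
  d <- abs(a - b) %% genome_length
  pmin(d, genome_length - d)
}

#' Generate a random circular genome with a controlled CpG density
#'
#' Draws a random sequence, removes every incidental CpG dinucleotide, then
#' plants `round(cpg_density * length)` CG dinucleotides at random positions
#' at least 2 bases apart, so that the set of CpG sites is exactly the planted
#' set. The default length mirrors the human mitochondrial reference (rCRS,
#' 16,569 bp).
#'
#' @param length Genome length in bases (>= 100).
#' @param cpg_density Target CpG sites per base, in [0, 0.25).
#' @param seed Integer seed; fixed seed gives an identical genome.
#' @param name Sequence name.
#' @return A [circular_genome()].
#' @export
generate_genome <- function(length = 16569L, cpg_density = 0.03, seed = NULL,
                            name = "chrM_synthetic") {
  if (!is.numeric(length) || length < 100) {
    stop("length must be a positive integer >= 100")
  }
  length <- as.integer(length)
  if (!is.numeric(cpg_density) || cpg_density < 0 || cpg_density >= 0.25) {
    stop("cpg_density must lie in [0, 0.25)")
  }
  if (!is.null(seed)) set.seed(seed)

  chars <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  # strip incidental CpGs (circularly): turn the G of each CG into an A
  repeat {
    nxt <- c(chars[-1L], chars[1L])
    hit <- which(chars == "C" & nxt == "G")
    if (!length(hit)) break
    chars[ifelse(hit == length, 1L, hit + 1L)] <- "A"
  }

  k <- round(cpg_density * length)
  planted <- integer()
  if (k > 0) {
    occupied <- logical(length)
    candidates <- sample.int(length - 1L)  # avoid the wrap position
    for (p in candidates) {
      if (length(planted) >= k) break
      lo <- max(1L, p - 1L)
      hi <- min(length, p + 2L)
      if (!any(occupied[lo:hi])) {
        planted <- c(planted, p)
        occupied[p] <- TRUE
        occupied[p + 1L] <- TRUE
      }
    }
    if (length(planted) < k) {
      stop("could not place the requested number of CpG sites; lower cpg_density")
    }
    chars[planted] <- "C"
    chars[planted + 1L] <- "G"
  }
  circular_genome(paste(chars, collapse = ""), name = name)
}

#' Plant homoplasmic and heteroplasmic variants on a genome
#'
#' Simulates single-nucleotide variants: homoplasmic variants carry
#' `true_fraction = 1` (the fraction of molecules bearing the alternate
#' allele), heteroplasmic variants carry the supplied fractions. To exercise
#' the downstream variant-proximity filters, the first variant of each class is
#' placed within 5 nt (circular distance) of a CpG site; the remainder are
#' placed uniformly. No two variants share a position.
#'
#' @param genome A [circular_genome()].
#' @param n_homoplasmic,n_heteroplasmic Variant counts per class.
#' @param het_fractions Numeric vector of length `n_heteroplasmic`, each in
#'   (0, 1).
#' @param seed Integer seed.
#' @return data.frame with columns `position` (1-based), `ref_allele`,
#'   `alt_allele`, `true_fraction`, sorted by position.
#' @export
plant_variants <- function(genome, n_homoplasmic, n_heteroplasmic,
                           het_fractions = numeric(), seed = NULL) {
  stopifnot(inherits(genome, "circular_genome"))
  if (length(het_fractions) != n_heteroplasmic) {
    stop("het_fractions must have length n_heteroplasmic")
  }
  if (n_heteroplasmic > 0 &&
      (any(het_fractions <= 0) || any(het_fractions >= 1))) {
    stop("heteroplasmic fractions must lie strictly in (0, 1)")
  }
  n <- n_homoplasmic + n_heteroplasmic
  L <- genome$length
  if (n > L) stop("more variants requested than available positions")
  if (!is.null(seed)) set.seed(seed)

  occupied <- logical(L)
  near_cpg <- function() {
    if (!length(genome$cpg_positions)) return(NA_integer_)
    for (i in seq_len(200L)) {
      c0 <- sample(genome$cpg_positions, 1L)
      off <- sample(c(-5:-1, 1:5), 1L)
      p <- ((c0 - 1L + off) %% L) + 1L
      if (!occupied[p]) return(p)
    }
    NA_integer_
  }
  uniform_free <- function(k) {
    free <- which(!occupied)
    sample(free, k)
  }

  pos <- integer()
  frac <- numeric()
  take <- function(p, f) {
    occupied[p] <<- TRUE
    pos <<- c(pos, p)
    frac <<- c(frac, f)
  }
  if (n_homoplasmic > 0) {
    p <- near_cpg()
    if (!is.na(p)) take(p, 1.0)
  }
  het_left <- het_fractions
  if (n_heteroplasmic > 0) {
    p <- near_cpg()
    if (!is.na(p)) {
      take(p, het_left[1L])
      het_left <- het_left[-1L]
    }
  }
  n_hom_left <- n_homoplasmic - sum(frac == 1.0)
  if (n_hom_left > 0) for (p in uniform_free(n_hom_left)) take(p, 1.0)
  if (length(het_left)) {
    ps <- uniform_free(length(het_left))
    for (i in seq_along(ps)) take(ps[i], het_left[i])
  }

  bases <- c("A", "C", "G", "T")
  ref <- substring(genome$sequence, pos, pos)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  out <- data.frame(
    position = pos, ref_allele = ref, alt_allele = unname(alt),
    true_fraction = frac, stringsAsFactors = FALSE
  )
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert simulated variants to an observed variant-call table
#'
#' Fills in the bookkeeping fields a variant caller would report (depth and
#' quality), with the observed allele fraction equal to the simulated molecular
#' fraction.
#'
#' @param simulated data.frame from [plant_variants()].
#' @param depth Read depth to report per variant.
#' @param qs Quality score to report per variant.
#' @return data.frame with columns `position`, `ref_allele`, `alt_allele`,
#'   `vaf`, `depth`, `qs`.
#' @export
as_variant_calls <- function(simulated, depth = 1000L, qs = 30) {
  data.frame(
    position = simulated$position,
    ref_allele = simulated$ref_allele,
    alt_allele = simulated$alt_allele,
    vaf = simulated$true_fraction,
    depth = rep_len(depth, nrow(simulated)),
    qs = rep_len(qs, nrow(simulated)),
    stringsAsFactors = FALSE
  )
}

#' Write a genome to FASTA
#' @param genome A [circular_genome()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome$sequence)
  names(x) <- genome$name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read the first sequence of a FASTA file as a circular genome
#' @param path FASTA file path.
#' @return A [circular_genome()] (CpG positions rescanned).
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (!length(x)) stop("no sequences in ", path)
  circular_genome(as.character(x[[1L]]), name = names(x)[1L])
}
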