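#' Simulation configuration
#'
#' Bundles the knobs of the genome-evolution simulator. The defaults encode
#' the study system the package's analyses target: a 24-chromosome ancestral
#' karyotype (the inferred pre-fission state behind extant 2N = 48/50
#' teleost karyotypes), per-site divergences of 0.18 for ancient (3R-like)
#' duplicate pairs, 0.06 for recent-WGD (4R-like) pairs and under 0.03 for
#' very recent duplicates, a 13-tissue expression panel, and a two-father
#' half-sib family of 48 + 44 progeny.
#'
#' @param seed integer; fully determines every simulator output.
#' @param n_chromosomes_ancestral ancestral chromosome count (>= 1).
#' @param genes_per_chromosome genes placed on each chromosome.
#' @param gene_length_range integer pair, min/max gene length in bp.
#' @param divergence_3r,divergence_4r,divergence_recent per-site divergence
#'   used for the corresponding duplication events (fractions in `[0, 1]`).
#' @param indel_rate per-site indel rate (0 by default so that identity
#'   bookkeeping stays exact; enable only for aligner stress tests).
#' @param loss_fraction fraction of post-WGD duplicate copies deleted.
#' @param scaffold_n number of scaffolds to fragment the genome into.
#' @param chimera_inject logical; join segments from two chromosomes into
#'   flagged chimeric scaffolds during fragmentation.
#' @param n_progeny_per_father integer vector of progeny counts.
#' @param missing_rate genotype missingness (missing completely at random).
#' @param n_tissues,n_specialized_per_tissue,baseline_dispersion expression
#'   panel size, planted specializations per tissue, and log-normal
#'   between-tissue dispersion of baseline means.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes_ancestral = 24L,
                       genes_per_chromosome = 10L,
                       gene_length_range = c(300L, 600L),
                       divergence_3r = 0.18,
                       divergence_4r = 0.06,
                       divergence_recent = 0.03,
                       indel_rate = 0,
                       loss_fraction = 0,
                       scaffold_n = 48L,
                       chimera_inject = FALSE,
                       n_progeny_per_father = c(48L, 44L),
                       missing_rate = 0.05,
                       n_tissues = 13L,
                       n_specialized_per_tissue = 5L,
                       baseline_dispersion = 0.25) {
  frac <- function(x, nm) {
    if (!is.numeric(x) || any(x < 0) || any(x > 1))
      stop(nm, " must be a fraction in [0, 1]")
    x
  }
  stopifnot(length(seed) == 1, is.finite(seed))
  if (n_chromosomes_ancestral < 1)
    stop("n_chromosomes_ancestral must be >= 1")
  stopifnot(genes_per_chromosome >= 1, length(gene_length_range) == 2,
            gene_length_range[1] >= 3, diff(gene_length_range) >= 0,
            scaffold_n >= 1, n_tissues >= 1)
  cfg <- list(seed = as.integer(seed),
              n_chromosomes_ancestral = as.integer(n_chromosomes_ancestral),
              genes_per_chromosome = as.integer(genes_per_chromosome),
              gene_length_range = as.integer(gene_length_range),
              divergence_3r = frac(divergence_3r, "divergence_3r"),
              divergence_4r = frac(divergence_4r, "divergence_4r"),
              divergence_recent = frac(divergence_recent,
                                       "divergence_recent"),
              indel_rate = frac(indel_rate, "indel_rate"),
              loss_fraction = frac(loss_fraction, "loss_fraction"),
              scaffold_n = as.integer(scaffold_n),
              chimera_inject = isTRUE(chimera_inject),
              n_progeny_per_father = as.integer(n_progeny_per_father),
              missing_rate = frac(missing_rate, "missing_rate"),
              n_tissues = as.integer(n_tissues),
              n_specialized_per_tissue =
                as.integer(n_specialized_per_tissue),
              baseline_dispersion = baseline_dispersion)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:\n")
  for (nm in names(x))
    cat(sprintf("  %-26s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  invisible(x)
}
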