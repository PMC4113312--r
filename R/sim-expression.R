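#' Simulate a tissue expression matrix with planted specializations
#'
#' Baseline counts follow a minimal overdispersed model: each transcript
#' has a log-normal base mean, each (transcript, tissue) cell multiplies it
#' by a log-normal tissue factor with standard deviation
#' \code{baseline_dispersion} (on the log scale), and counts are Poisson
#' around that mean. Planted specialized transcripts get a fold-boost in
#' exactly one tissue, large enough to exceed a mean + 3 SD call in
#' expectation.
#'
#' @param n_transcripts number of transcripts.
#' @param n_tissues number of tissues (default 13).
#' @param n_specialized_per_tissue planted specializations per tissue
#'   (distinct transcripts; requires
#'   \code{n_specialized_per_tissue * n_tissues <= n_transcripts}).
#' @param baseline_dispersion log-scale SD of the per-cell tissue factor.
#' @param boost fold-change applied to a planted cell (default 100).
#' @param base_meanlog log mean of the per-transcript base expression.
#' @param lengths optional transcript lengths in bp (sampled 300-3000 if
#'   missing).
#' @param tissues optional tissue names.
#' @return list with \code{counts} (matrix transcripts x tissues),
#'   \code{lengths} (named), and \code{truth} (data.frame transcript,
#'   tissue of planted specializations).
#' @export
simulate_expression <- function(n_transcripts, n_tissues = 13L,
                                n_specialized_per_tissue = 5L,
                                baseline_dispersion = 0.25, boost = 100,
                                base_meanlog = log(30), lengths = NULL,
                                tissues = NULL) {
  if (n_specialized_per_tissue * n_tissues > n_transcripts)
    stop("n_specialized_per_tissue x n_tissues exceeds n_transcripts")
  tx <- sprintf("t%05d", seq_len(n_transcripts))
  if (is.null(tissues))
    tissues <- sprintf("tissue%02d", seq_len(n_tissues))
  if (is.null(lengths))
    lengths <- sample(300:3000, n_transcripts, replace = TRUE)
  lengths <- setNames(as.integer(lengths), tx)
  base <- exp(rnorm(n_transcripts, base_meanlog, 1))
  mu <- base * exp(matrix(rnorm(n_transcripts * n_tissues, 0,
                                baseline_dispersion),
                          n_transcripts, n_tissues))
  truth <- data.frame(transcript = character(0), tissue = character(0),
                      stringsAsFactors = FALSE)
  if (n_specialized_per_tissue > 0) {
    planted <- sample(tx, n_specialized_per_tissue * n_tissues)
    truth <- data.frame(
      transcript = planted,
      tissue = rep(tissues, each = n_specialized_per_tissue),
      stringsAsFactors = FALSE)
    mu[cbind(match(truth$transcript, tx),
             match(truth$tissue, tissues))] <-
      mu[cbind(match(truth$transcript, tx),
               match(truth$tissue, tissues))] * boost
  }
  counts <- matrix(rpois(length(mu), mu), n_transcripts, n_tissues,
                   dimnames = list(tx, tissues))
  # guarantee positive library totals per transcript row
  zero <- rowSums(counts) == 0
  while (any(zero)) {
    counts[zero, ] <- rpois(sum(zero) * n_tissues, mu[zero, ])
    zero <- rowSums(counts) == 0
  }
  list(counts = counts, lengths = lengths, truth = truth)
}
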