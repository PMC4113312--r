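#' Default alignment scoring scheme
#'
#' Match/mismatch and affine gap parameters for the local aligner. A gap of
#' length \eqn{k} costs \code{gap_open + k * gap_extend}. The default score
#' threshold used by [best_hits()] (\code{min_score = 40}) plays the role of
#' the usual database-search significance cutoff: with unit match scores a
#' raw score of 40 on transcript-scale sequences is comparably stringent,
#' and the 100-column minimum alignment length filter dominates in practice.
#'
#' @param match,mismatch per-column scores (integers).
#' @param gap_open,gap_extend affine gap penalties (negative integers).
#' @return A named list of scoring parameters.
#' @export
align_scoring <- function(match = 1L, mismatch = -1L, gap_open = -2L,
                          gap_extend = -1L) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  list(match = as.integer(match), mismatch = as.integer(mismatch),
       gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend))
}

check_sequences <- function(x, arg = "sequences") {
  if (is.null(names(x)) || anyDuplicated(names(x)))
    stop(arg, " must be a uniquely named character vector")
  if (any(!nzchar(x))) stop("empty sequence in ", arg)
  toupper(x)
}

#' Local pairwise alignment
#'
#' Affine-gap Smith-Waterman local alignment between two nucleotide
#' sequences. Percent identity counts internal gap columns in the
#' denominator (\code{100 * matches / aligned_columns}). With
#' \code{band > 0} the dynamic program is restricted to diagonals
#' \code{|j - i| <= band}: exact whenever the optimal path stays within
#' that offset of the main diagonal (always true for full-length
#' homologues of similar length) and much faster for long inputs;
#' \code{band = 0} runs the full unrestricted recursion. Banded scores
#' never exceed the unbanded optimum.
#'
#' @param a,b nucleotide sequences (single strings over A/C/G/T/N; anything
#'   outside A/C/G/T, including lower-case masked bases, never matches).
#' @param scoring see [align_scoring()].
#' @param band diagonal band half-width; 0 for the full matrix.
#' @return A one-row data.frame with columns \code{score}, \code{matches},
#'   \code{aligned_columns}, \code{pident}, \code{qstart}, \code{qend},
#'   \code{sstart}, \code{send} (1-based, inclusive).
#' @export
align_pair <- function(a, b, scoring = align_scoring(), band = 0L) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  r <- .sw_pair_cpp(a, b, scoring$match, scoring$mismatch, scoring$gap_open,
                    scoring$gap_extend, as.integer(band))
  data.frame(score = r$score, matches = r$matches,
             aligned_columns = r$aligned_columns,
             pident = if (r$aligned_columns > 0)
               100 * r$matches / r$aligned_columns else 0,
             qstart = r$qstart, qend = r$qend,
             sstart = r$sstart, send = r$send)
}

#' Non-overlapping local alignments (HSP tiling) between two sequences
#'
#' Greedy best-first selection: the highest-scoring local alignment is
#' taken, its footprint masked on both sequences, and the search repeated
#' until the score drops below \code{min_score} or \code{max_hsps} segments
#' have been collected. Selected segments are therefore mutually
#' non-overlapping on both sequences.
#'
#' @inheritParams align_pair
#' @param max_hsps maximum number of segments returned.
#' @param min_score stop when the best remaining local score falls below
#'   this value.
#' @return data.frame of HSPs (possibly zero rows) with alignment columns
#'   as in [align_pair()].
#' @export
align_hsps <- function(a, b, scoring = align_scoring(), band = 0L,
                       max_hsps = 10L, min_score = 20L) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  m <- .sw_hsps_cpp(a, b, scoring$match, scoring$mismatch, scoring$gap_open,
                    scoring$gap_extend, as.integer(band),
                    as.integer(max_hsps), as.integer(min_score))
  d <- as.data.frame(m)
  d$pident <- ifelse(d$aligned_columns > 0,
                     100 * d$matches / d$aligned_columns, 0)
  d
}

# internal: all-vs-all local alignment scores (matrix, rows = a, cols = b);
# self = TRUE computes the symmetric within-set matrix with NA diagonal.
score_all <- function(seqs_a, seqs_b = NULL, scoring = align_scoring(),
                      band = 0L, self = is.null(seqs_b)) {
  m <- .sw_score_all_cpp(unname(seqs_a),
                         if (self) character(0) else unname(seqs_b),
                         scoring$match, scoring$mismatch, scoring$gap_open,
                         scoring$gap_extend, as.integer(band), self)
  rownames(m) <- names(seqs_a)
  colnames(m) <- if (self) names(seqs_a) else names(seqs_b)
  m
}
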