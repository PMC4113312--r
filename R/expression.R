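# FPKM normalization and the 3-standard-deviation tissue-specialization
# statistic.

#' Fragments per kilobase per million mapped fragments
#'
#' \deqn{FPKM(t, i) = F(t, i) \cdot 10^9 / (L(t) \cdot M(i))}
#' where F are fragment counts, L transcript lengths in bp and M the
#' per-tissue mapped-fragment totals (column sums of F when omitted).
#'
#' @param counts matrix transcripts x tissues of fragment counts.
#' @param lengths transcript lengths in bp (vector, length nrow(counts)).
#' @param totals per-tissue mapped totals; defaults to column sums.
#' @return FPKM matrix with the same dimnames as \code{counts}.
#' @export
fpkm <- function(counts, lengths, totals = colSums(counts)) {
  counts <- as.matrix(counts)
  if (length(lengths) != nrow(counts))
    stop("lengths must match rows of counts")
  if (length(totals) != ncol(counts))
    stop("totals must match columns of counts")
  if (any(lengths <= 0)) stop("zero or negative transcript length")
  if (any(totals <= 0)) stop("zero or negative mapped-fragment total")
  sweep(sweep(counts, 1, as.numeric(lengths), "/"), 2,
        as.numeric(totals), "/") * 1e9
}

#' Tissue-specialization calls (mean + k SD rule)
#'
#' A transcript is specialized in tissue i when its FPKM there exceeds
#' its cross-tissue mean by more than \code{k} standard deviations. The
#' candidate tissue's own value is included in the mean and SD, and the
#' sample SD (n - 1 denominator) is used by default; both conventions are
#' exposed because the rule is sensitive to them.
#'
#' @param fpkm_mat FPKM matrix transcripts x tissues (>= 3 tissues;
#'   2 tissues are accepted but produce no stable calls).
#' @param k SD multiplier (default 3).
#' @param sd_denom \code{"n-1"} (sample SD, default) or \code{"n"}.
#' @return list with \code{calls} (logical matrix), \code{per_tissue}
#'   (data.frame tissue, n_specialized, sorted by descending count — the
#'   tissue complexity ranking), and \code{pairs} (data.frame transcript,
#'   tissue).
#' @export
specialized_calls <- function(fpkm_mat, k = 3, sd_denom = c("n-1", "n")) {
  sd_denom <- match.arg(sd_denom)
  fpkm_mat <- as.matrix(fpkm_mat)
  if (is.null(rownames(fpkm_mat)))
    rownames(fpkm_mat) <- sprintf("t%05d", seq_len(nrow(fpkm_mat)))
  if (is.null(colnames(fpkm_mat)))
    colnames(fpkm_mat) <- sprintf("tissue%02d", seq_len(ncol(fpkm_mat)))
  nt <- ncol(fpkm_mat)
  if (nt < 2) stop("standard deviation undefined with a single tissue")
  mu <- rowMeans(fpkm_mat)
  ss <- rowSums((fpkm_mat - mu)^2)
  sdv <- sqrt(ss / if (sd_denom == "n-1") (nt - 1) else nt)
  thr <- mu + k * sdv
  calls <- fpkm_mat > thr
  per_tissue <- data.frame(tissue = colnames(fpkm_mat),
                           n_specialized = colSums(calls),
                           stringsAsFactors = FALSE)
  per_tissue <- per_tissue[order(-per_tissue$n_specialized,
                                 per_tissue$tissue), ]
  rownames(per_tissue) <- NULL
  idx <- which(calls, arr.ind = TRUE)
  pairs <- data.frame(transcript = rownames(fpkm_mat)[idx[, 1]],
                      tissue = colnames(fpkm_mat)[idx[, 2]],
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$transcript, pairs$tissue), ]
  rownames(pairs) <- NULL
  list(calls = calls, per_tissue = per_tissue, pairs = pairs)
}

#' Top expressed transcripts per tissue
#'
#' Per tissue, the \code{per_tissue_n} transcripts with the highest FPKM,
#' optionally restricted to specialized calls; ties at the rank boundary
#' are broken by lexicographic transcript id.
#'
#' @param fpkm_mat FPKM matrix.
#' @param per_tissue_n table depth (default 10).
#' @param specialized_only logical; restrict to [specialized_calls()]
#'   (computed with default settings) when TRUE.
#' @return data.frame tissue, rank, transcript, fpkm.
#' @export
top_expressed <- function(fpkm_mat, per_tissue_n = 10L,
                          specialized_only = FALSE) {
  fpkm_mat <- as.matrix(fpkm_mat)
  calls <- if (specialized_only) specialized_calls(fpkm_mat)$calls
           else NULL
  out <- lapply(colnames(fpkm_mat), function(ti) {
    v <- fpkm_mat[, ti]
    if (!is.null(calls)) v <- v[calls[, ti]]
    if (length(v) == 0)
      return(NULL)
    ord <- order(-v, names(v))
    sel <- ord[seq_len(min(per_tissue_n, length(ord)))]
    data.frame(tissue = ti, rank = seq_along(sel),
               transcript = names(v)[sel], fpkm = unname(v[sel]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
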