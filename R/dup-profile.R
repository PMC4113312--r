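# Percent-identity duplication profiles: 1%-binned histograms, peak
# detection, similarity-band classification.

#' 1%-binned percent-identity histogram
#'
#' Bins pair identities by floor into `[i, i+1)` for i = 0..99; exactly-100
#' values are assigned to the closed top bin `[99, 100]` so self-identical
#' duplicates remain countable.
#'
#' @param pairs data.frame with a \code{pident} column (0-100), e.g. from
#'   [reciprocal_best_hits()], or a numeric vector of identities.
#' @return A \code{similarity_histogram}: data.frame with \code{bin}
#'   (lower edge 0..99) and \code{count}; attribute \code{total}.
#' @export
similarity_histogram <- function(pairs) {
  pid <- if (is.data.frame(pairs)) pairs$pident else pairs
  if (any(is.na(pid)) || any(pid < 0) || any(pid > 100))
    stop("percent identity outside [0, 100]")
  bin <- pmin(floor(pid), 99)
  counts <- tabulate(bin + 1L, nbins = 100L)
  h <- data.frame(bin = 0:99, count = counts)
  attr(h, "total") <- length(pid)
  class(h) <- c("similarity_histogram", "data.frame")
  h
}

#' Detect duplication peaks in an identity histogram
#'
#' Moving-average smoothing over \code{window} bins followed by local
#' maximum detection; a maximum is reported if its prominence (height
#' above the higher of the two flanking key valleys, computed against
#' higher neighbouring peaks) is at least
#' \code{min_prominence_frac * total}. This formalizes the by-eye peak
#' reading used on such plots.
#'
#' @param hist a [similarity_histogram()].
#' @param window odd moving-average window in bins (default 3).
#' @param min_prominence_frac prominence threshold as a fraction of the
#'   total pair count.
#' @return data.frame of peaks sorted by descending smoothed height:
#'   \code{bin}, \code{height}, \code{prominence}, \code{band}.
#' @export
detect_peaks <- function(hist, window = 3L, min_prominence_frac = 0.05) {
  stopifnot(inherits(hist, "similarity_histogram"))
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  total <- attr(hist, "total")
  x <- hist$count
  n <- length(x)
  half <- (window - 1L) / 2L
  # zero-padded moving average: edge bins are not inflated by a
  # truncated window
  sm <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    sum(x[lo:hi]) / window
  }, numeric(1))
  # local maxima on the smoothed series; within a smoothed plateau the
  # peak is placed on the bin with the largest raw count (smoothing alone
  # would systematically shift a sharp peak toward its emptier neighbour)
  is_max <- vapply(seq_len(n), function(i) {
    left <- if (i > 1) sm[i - 1] else -Inf
    right <- if (i < n) sm[i + 1] else -Inf
    sm[i] > 0 && sm[i] >= right && sm[i] > left
  }, logical(1))
  cand <- which(is_max)
  cand <- vapply(cand, function(i) {
    j <- i
    while (j < n && sm[j + 1] == sm[i]) j <- j + 1
    plateau <- i:j
    plateau[which.max(x[plateau])]
  }, integer(1))
  cand <- unique(cand)
  if (length(cand) == 0 || total == 0)
    return(data.frame(bin = integer(0), height = numeric(0),
                      prominence = numeric(0), band = character(0)))
  prom <- vapply(cand, function(i) {
    h <- sm[i]
    key <- function(side) {
      idx <- if (side < 0) seq(i - 1, 1) else if (i < n) seq(i + 1, n)
             else integer(0)
      if (i == 1 && side < 0) return(0)
      valley <- h
      for (j in idx) {
        if (sm[j] > h) return(valley)  # reached a strictly higher peak
        valley <- min(valley, sm[j])
      }
      0  # ran off the histogram: prominence measured from zero
    }
    h - max(min(key(-1), key(1)), 0)
  }, numeric(1))
  keep <- prom >= min_prominence_frac * total
  out <- data.frame(bin = hist$bin[cand[keep]],
                    height = sm[cand[keep]],
                    prominence = prom[keep])
  out <- out[order(-out$height, out$bin), , drop = FALSE]
  out$band <- ifelse(out$bin >= 97, "recent",
                     ifelse(out$bin >= 77 & out$bin <= 89,
                            "candidate_3R", "other"))
  rownames(out) <- NULL
  out
}

#' Classify homologue pairs into similarity bands
#'
#' Labels each pair \code{recent} (identity above \code{recent_min}),
#' \code{candidate_3R} (identity within the inclusive
#' `[band_lo, band_hi]` band associated with the ancient teleost
#' duplication), or \code{other}. Every pair receives exactly one label.
#'
#' @param pairs data.frame with \code{pident}, or a numeric vector.
#' @param recent_min,band_lo,band_hi band boundaries in percent.
#' @return character vector of labels (and, for data.frame input, the
#'   input with a \code{band} column).
#' @export
classify_bands <- function(pairs, recent_min = 97, band_lo = 77,
                           band_hi = 89) {
  pid <- if (is.data.frame(pairs)) pairs$pident else pairs
  lab <- ifelse(pid > recent_min, "recent",
                ifelse(pid >= band_lo & pid <= band_hi, "candidate_3R",
                       "other"))
  if (is.data.frame(pairs)) {
    pairs$band <- lab
    pairs
  } else lab
}

#' Side-by-side comparison of identity distributions
#'
#' Reports each histogram's modal bin and detected peak bins in one table;
#' no statistical test is attached (none is standard for this contrast).
#'
#' @param ... named [similarity_histogram()] objects on identical bins.
#' @param window,min_prominence_frac passed to [detect_peaks()].
#' @return data.frame with one row per histogram: \code{name},
#'   \code{total}, \code{modal_bin}, \code{peaks} (comma-separated bins).
#' @export
compare_distributions <- function(..., window = 3L,
                                  min_prominence_frac = 0.05) {
  hs <- list(...)
  if (length(hs) == 1 && is.list(hs[[1]]) &&
      !inherits(hs[[1]], "similarity_histogram")) hs <- hs[[1]]
  if (is.null(names(hs)) || any(!nzchar(names(hs))))
    names(hs) <- paste0("hist", seq_along(hs))
  bins <- lapply(hs, function(h) h$bin)
  if (length(unique(bins)) != 1) stop("histograms must share bins")
  do.call(rbind, lapply(names(hs), function(nm) {
    h <- hs[[nm]]
    pk <- detect_peaks(h, window, min_prominence_frac)
    data.frame(name = nm, total = attr(h, "total"),
               modal_bin = h$bin[which.max(h$count)],
               peaks = paste(sort(pk$bin), collapse = ","),
               stringsAsFactors = FALSE)
  }))
}

#' @export
plot.similarity_histogram <- function(x, ...) {
  graphics::barplot(x$count, names.arg = x$bin, space = 0,
                    xlab = "percent identity (1% bins)", ylab = "pairs",
                    ...)
  invisible(x)
}
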