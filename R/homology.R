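#' Best passing hit per query
#'
#' For every query sequence, the single highest-scoring subject alignment
#' that passes the filters (alignment at least \code{min_aligned} columns
#' long and raw score at least \code{min_score}). Ties are broken by score,
#' then percent identity, then lexicographic subject id. Queries with no
#' passing hit are absent from the result. Within-species searches
#' (\code{seqs_b = NULL}) exclude self-hits.
#'
#' @param seqs_a,seqs_b named character vectors of sequences; leave
#'   \code{seqs_b} as \code{NULL} for a within-set search.
#' @param min_aligned minimum alignment length in columns (the classic
#'   100 bp transcript-homology filter).
#' @param min_score minimum raw alignment score, standing in for a
#'   database-search significance threshold.
#' @param scoring see [align_scoring()].
#' @param band band half-width passed to the aligner (0 = full matrix).
#' @return data.frame with one row per query that has a passing hit:
#'   \code{qid}, \code{sid}, \code{score}, \code{matches},
#'   \code{aligned_columns}, \code{pident}, \code{qcov}, \code{scov}
#'   (single-HSP coverages), plus alignment coordinates.
#' @export
best_hits <- function(seqs_a, seqs_b = NULL, min_aligned = 100L,
                      min_score = 40L, scoring = align_scoring(),
                      band = 32L) {
  seqs_a <- check_sequences(seqs_a, "seqs_a")
  within <- is.null(seqs_b)
  if (!within) seqs_b <- check_sequences(seqs_b, "seqs_b")
  sm <- score_all(seqs_a, seqs_b, scoring = scoring, band = band,
                  self = within)
  subj <- if (within) seqs_a else seqs_b
  select_best(sm, seqs_a, subj, min_aligned, min_score, scoring, band)
}

# best-hit selection from a precomputed score matrix (rows = queries)
select_best <- function(sm, seqs_a, subj, min_aligned, min_score,
                        scoring, band) {
  out <- vector("list", length(seqs_a))
  for (i in seq_along(seqs_a)) {
    sc <- sm[i, ]
    hit <- NULL
    repeat {
      mx <- suppressWarnings(max(sc, na.rm = TRUE))
      if (!is.finite(mx) || mx < min_score) break
      # resolve score ties by identity then id: align all tied candidates
      tied <- which(!is.na(sc) & sc == mx)
      cand <- do.call(rbind, lapply(tied, function(k) {
        al <- align_pair(seqs_a[[i]], subj[[k]], scoring = scoring,
                         band = band)
        al$sid <- colnames(sm)[k]
        al
      }))
      cand <- cand[cand$aligned_columns >= min_aligned &
                   cand$score >= min_score, , drop = FALSE]
      if (nrow(cand) > 0) {
        cand <- cand[order(-cand$score, -cand$pident, cand$sid), ,
                     drop = FALSE]
        hit <- cand[1, , drop = FALSE]
        break
      }
      # every candidate at this score level fails the filters: drop below
      sc[tied] <- NA
    }
    if (!is.null(hit)) {
      hit$qid <- names(seqs_a)[i]
      hit$qcov <- (hit$qend - hit$qstart + 1) / nchar(seqs_a[[i]])
      hit$scov <- (hit$send - hit$sstart + 1) / nchar(subj[[hit$sid]])
      out[[i]] <- hit
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(qid = character(), sid = character(),
                      score = numeric(), matches = integer(),
                      aligned_columns = integer(), pident = numeric(),
                      qcov = numeric(), scov = numeric()))
  rownames(out) <- NULL
  out[, c("qid", "sid", "score", "matches", "aligned_columns", "pident",
          "qcov", "scov", "qstart", "qend", "sstart", "send")]
}

#' Reciprocal best hits
#'
#' A pair (a, b) is reported iff b is a's best passing hit and a is b's
#' best passing hit. For a within-set search the pair is stored once in
#' canonical (lexicographic) order. The output is a partial matching:
#' every id appears in at most one pair.
#'
#' @inheritParams best_hits
#' @return data.frame with columns \code{id_a}, \code{id_b},
#'   \code{relation} (\code{"within_species"} or \code{"between_species"})
#'   and the alignment columns of the a-to-b hit.
#' @export
reciprocal_best_hits <- function(seqs_a, seqs_b = NULL, min_aligned = 100L,
                                 min_score = 40L, scoring = align_scoring(),
                                 band = 32L) {
  within <- is.null(seqs_b)
  seqs_a <- check_sequences(seqs_a, "seqs_a")
  if (!within) seqs_b <- check_sequences(seqs_b, "seqs_b")
  sm <- score_all(seqs_a, seqs_b, scoring = scoring, band = band,
                  self = within)
  subj <- if (within) seqs_a else seqs_b
  fwd <- select_best(sm, seqs_a, subj, min_aligned, min_score, scoring,
                     band)
  rev <- if (within) fwd
         else select_best(t(sm), seqs_b, seqs_a, min_aligned, min_score,
                          scoring, band)
  if (nrow(fwd) == 0)
    return(cbind(data.frame(id_a = character(), id_b = character(),
                            relation = character()), fwd[, -(1:2)]))
  back <- setNames(rev$sid, rev$qid)
  keep <- !is.na(back[fwd$sid]) & back[fwd$sid] == fwd$qid
  pairs <- fwd[keep, , drop = FALSE]
  pairs$id_a <- pairs$qid
  pairs$id_b <- pairs$sid
  if (within) {
    flip <- pairs$id_a > pairs$id_b
    tmp <- pairs$id_a[flip]
    pairs$id_a[flip] <- pairs$id_b[flip]
    pairs$id_b[flip] <- tmp
    pairs <- pairs[!duplicated(paste(pairs$id_a, pairs$id_b)), ,
                   drop = FALSE]
  }
  pairs$relation <- if (within) "within_species" else "between_species"
  rownames(pairs) <- NULL
  pairs[, c("id_a", "id_b", "relation", "score", "matches",
            "aligned_columns", "pident", "qcov", "scov")]
}

# internal: two-sided coverage of a pair from greedy non-overlapping HSPs
pair_coverage <- function(a, b, scoring, band, min_hsp_score = 20L) {
  h <- align_hsps(a, b, scoring = scoring, band = band,
                  min_score = min_hsp_score)
  if (nrow(h) == 0) return(c(qcov = 0, scov = 0))
  c(qcov = sum(h$qend - h$qstart + 1) / nchar(a),
    scov = sum(h$send - h$sstart + 1) / nchar(b))
}

#' Reciprocal best hits with a two-sided coverage requirement
#'
#' [reciprocal_best_hits()] pairs additionally required to have at least
#' \code{min_cov} of \emph{each} sequence covered by non-overlapping local
#' alignments between the two (greedy best-first HSP tiling, so disjoint
#' conserved segments accumulate coverage).
#'
#' @inheritParams best_hits
#' @param min_cov minimum coverage fraction required on both sides.
#' @return As [reciprocal_best_hits()], with \code{qcov}/\code{scov}
#'   replaced by the multi-HSP coverages.
#' @export
rbh_with_coverage <- function(seqs_a, seqs_b = NULL, min_cov = 0.5,
                              min_aligned = 100L, min_score = 40L,
                              scoring = align_scoring(), band = 32L) {
  within <- is.null(seqs_b)
  pairs <- reciprocal_best_hits(seqs_a, seqs_b, min_aligned, min_score,
                                scoring, band)
  if (nrow(pairs) == 0) return(pairs)
  seqs_a <- check_sequences(seqs_a, "seqs_a")
  subj <- if (within) seqs_a else check_sequences(seqs_b, "seqs_b")
  cov <- t(vapply(seq_len(nrow(pairs)), function(k) {
    pair_coverage(seqs_a[[pairs$id_a[k]]], subj[[pairs$id_b[k]]],
                  scoring, band)
  }, numeric(2)))
  pairs$qcov <- cov[, 1]
  pairs$scov <- cov[, 2]
  pairs[pairs$qcov >= min_cov & pairs$scov >= min_cov, , drop = FALSE]
}

#' Collapse near-identical transcripts
#'
#' Single-linkage clustering of transcripts under the relation "aligned at
#' \code{min_identity}\% identity or better over at least \code{min_len}
#' columns"; one representative (the longest member, ties broken by
#' lexicographic id) is kept per cluster. The operation is idempotent.
#'
#' @param transcripts named character vector of sequences.
#' @param min_identity percent identity threshold (default 98).
#' @param min_len minimum alignment length in columns (default 300).
#' @inheritParams best_hits
#' @return list with \code{representatives} (named character vector) and
#'   \code{clusters} (named character vector mapping each transcript id to
#'   its representative id).
#' @export
collapse_redundancy <- function(transcripts, min_identity = 98,
                                min_len = 300L, scoring = align_scoring(),
                                band = 32L) {
  transcripts <- check_sequences(transcripts, "transcripts")
  n <- length(transcripts)
  ids <- names(transcripts)
  edges <- NULL
  if (n > 1) {
    cmb <- utils::combn(n, 2)
    related <- vapply(seq_len(ncol(cmb)), function(k) {
      i <- cmb[1, k]; j <- cmb[2, k]
      # quick reject: best score bounds matches, so short/low-score pairs
      # cannot satisfy the relation
      al <- align_pair(transcripts[[i]], transcripts[[j]],
                       scoring = scoring, band = band)
      al$aligned_columns >= min_len && al$pident >= min_identity
    }, logical(1))
    edges <- cmb[, related, drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges) && ncol(edges) > 0)
    g <- igraph::add_edges(g, as.vector(edges))
  comp <- igraph::components(g)$membership
  reps <- vapply(split(seq_len(n), comp), function(members) {
    lens <- nchar(transcripts[members])
    cand <- members[lens == max(lens)]
    cand[order(ids[cand])][1]
  }, integer(1))
  cluster_map <- setNames(ids[reps[as.character(comp)]], ids)
  list(representatives = transcripts[sort(ids[reps])],
       clusters = cluster_map)
}

#' Filter transcripts by longest open reading frame
#'
#' Retains transcripts whose longest complete ORF (ATG to in-frame stop,
#' inclusive of both codons, scanned in all six frames) is at least
#' \code{min_orf} bases.
#'
#' @param transcripts named character vector of sequences.
#' @param min_orf minimum ORF length in bases (default 300).
#' @return The retained subset of \code{transcripts}.
#' @export
orf_filter <- function(transcripts, min_orf = 300L) {
  transcripts <- check_sequences(transcripts, "transcripts")
  keep <- vapply(transcripts, function(s) longest_orf(s) >= min_orf,
                 logical(1))
  transcripts[keep]
}

#' Length of the longest complete ORF in any of six frames
#' @param seq a nucleotide sequence string.
#' @return Longest ATG-to-stop ORF length in bases (0 if none).
#' @export
longest_orf <- function(seq) {
  seq <- toupper(seq)
  revcomp <- rev_comp(seq)
  best <- 0L
  for (s in c(seq, revcomp)) {
    chars <- strsplit(s, "")[[1]]
    n <- length(chars)
    for (off in 0:2) {
      m <- (n - off) %/% 3
      if (m < 2) next
      codons <- paste0(chars[off + 3 * (seq_len(m) - 1) + 1],
                       chars[off + 3 * (seq_len(m) - 1) + 2],
                       chars[off + 3 * (seq_len(m) - 1) + 3])
      starts <- which(codons == "ATG")
      stops <- which(codons %in% c("TAA", "TAG", "TGA"))
      if (length(starts) == 0 || length(stops) == 0) next
      for (st in starts) {
        nxt <- stops[stops >= st]
        if (length(nxt) == 0) next
        len <- (nxt[1] - st + 1L) * 3L
        if (len > best) best <- len
      }
    }
  }
  best
}

rev_comp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

#' Apply a BED-style interval mask to sequences
#'
#' Masked spans are lower-cased; the aligner treats lower-case bases as
#' unmatchable, so masked repeats cannot contribute to alignments.
#'
#' @param seqs named character vector.
#' @param mask data.frame with columns \code{id}, \code{start}, \code{end}
#'   (0-based half-open).
#' @return The masked sequences.
#' @export
mask_sequences <- function(seqs, mask) {
  stopifnot(all(c("id", "start", "end") %in% names(mask)))
  for (k in seq_len(nrow(mask))) {
    id <- mask$id[k]
    if (!id %in% names(seqs)) next
    s <- seqs[[id]]
    from <- mask$start[k] + 1L
    to <- min(mask$end[k], nchar(s))
    if (from > to) next
    substr(s, from, to) <- tolower(substr(s, from, to))
    seqs[[id]] <- s
  }
  seqs
}
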