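# Independent brute-force oracles and small sequence helpers used across
# the suite. Oracles deliberately avoid the package's selection logic.

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute exactly nsub distinct positions, each to a different base
mutate_seq <- function(seq, nsub, positions = NULL) {
  chars <- strsplit(seq, "")[[1]]
  if (is.null(positions)) positions <- sample(length(chars), nsub)
  for (p in positions) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# per-query argmax over exhaustive full (unbanded) alignments
oracle_best_hits <- function(seqs_a, seqs_b = NULL, min_aligned = 100,
                             min_score = 40) {
  within <- is.null(seqs_b)
  subj <- if (within) seqs_a else seqs_b
  res <- list()
  for (q in names(seqs_a)) {
    best <- NULL
    for (s in names(subj)) {
      if (within && s == q) next
      al <- align_pair(seqs_a[[q]], subj[[s]], band = 0)
      if (al$aligned_columns < min_aligned || al$score < min_score) next
      key <- c(al$score, al$pident)
      if (is.null(best) || al$score > best$score ||
          (al$score == best$score && al$pident > best$pident) ||
          (al$score == best$score && al$pident == best$pident &&
           s < best$sid)) {
        best <- al
        best$sid <- s
      }
    }
    if (!is.null(best)) res[[q]] <- data.frame(qid = q, sid = best$sid,
                                               score = best$score)
  }
  do.call(rbind, c(res, make.row.names = FALSE))
}

# reciprocity oracle built on oracle_best_hits
oracle_rbh <- function(seqs_a, seqs_b, min_aligned = 100,
                       min_score = 40) {
  fwd <- oracle_best_hits(seqs_a, seqs_b, min_aligned, min_score)
  rev <- oracle_best_hits(seqs_b, seqs_a, min_aligned, min_score)
  if (is.null(fwd) || is.null(rev)) return(NULL)
  back <- setNames(rev$sid, rev$qid)
  keep <- !is.na(back[fwd$sid]) & back[fwd$sid] == fwd$qid
  fwd[keep, c("qid", "sid")]
}

# transitive closure of a pairwise relation, as cluster membership ids
oracle_closure <- function(ids, related) {
  parent <- setNames(seq_along(ids), ids)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i < j && related(ids[i], ids[j])) {
        ri <- find(i); rj <- find(j)
        parent[ri] <- rj
      }
    }
  }
  vapply(seq_along(ids), find, numeric(1))
}

# direct re-evaluation of the mean + k*SD rule, cell by cell
oracle_specialized <- function(mat, k = 3) {
  out <- matrix(FALSE, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  for (i in seq_len(nrow(mat))) {
    m <- mean(mat[i, ])
    s <- sd(mat[i, ])
    for (j in seq_len(ncol(mat))) out[i, j] <- mat[i, j] > m + k * s
  }
  out
}

# regex-based longest-ORF oracle (lazy match from every ATG, both strands)
oracle_longest_orf <- function(seq) {
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
  best <- 0L
  for (s in c(seq, rc)) {
    m <- gregexpr("(?=(ATG(?:[ACGT]{3})*?(?:TAA|TAG|TGA)))", s,
                  perl = TRUE)[[1]]
    if (m[1] != -1) {
      lens <- attr(m, "capture.length")[, 1]
      best <- max(best, max(lens))
    }
  }
  best
}

# tiny two-marker genotype table with controlled missingness
toy_genotype_table <- function(n_progeny = 92, missing_per_marker = 0) {
  fmap <- make_marker_map(1, 2, 10)
  parents <- data.frame(marker = fmap$marker,
                        mother = c("101/103", "101/103"),
                        father1 = c("105/107", "105/107"),
                        father2 = c("105/107", "105/107"),
                        stringsAsFactors = FALSE)
  fam <- simulate_half_sib_family(fmap, fmap, parents,
                                  n_progeny = c(ceiling(n_progeny / 2),
                                                floor(n_progeny / 2)),
                                  missing_rate = 0)
  prog <- names(attr(fam, "progeny_father"))
  for (i in seq_len(nrow(fam))) {
    if (missing_per_marker > 0)
      fam[i, prog[seq_len(missing_per_marker)]] <- "-"
  }
  fam
}
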