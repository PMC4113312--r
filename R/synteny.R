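# Conserved synteny: linkage-group x chromosome orthologue matrices,
# fusion/fission/duplication pattern calls, scaffold diagnosis.

#' Point position of a feature
#'
#' The midpoint \code{(start + end) / 2} used to represent a mapped
#' transcript as a single coordinate.
#'
#' @param start,end 0-based half-open coordinates, \code{start <= end}.
#' @return \code{(start + end) / 2} as a real number.
#' @export
point_position <- function(start, end) {
  if (any(start > end)) stop("start > end")
  (start + end) / 2
}

#' Assign transcripts to linkage groups via scaffold anchors
#'
#' A transcript inherits the linkage group of its host scaffold;
#' transcripts on scaffolds without an anchor are excluded (with a
#' warning reporting the count).
#'
#' @param locations data.frame with columns \code{id},
#'   \code{chrom_or_scaffold} (or \code{scaffold}), \code{start},
#'   \code{end}.
#' @param anchors data.frame with columns \code{scaffold}, \code{lg}.
#' @return data.frame \code{id}, \code{scaffold}, \code{lg}, \code{pos}
#'   (point position on the scaffold); attribute \code{n_excluded}.
#' @export
anchor_transcripts <- function(locations, anchors) {
  scol <- if ("chrom_or_scaffold" %in% names(locations))
    "chrom_or_scaffold" else "scaffold"
  lg <- setNames(anchors$lg, anchors$scaffold)[locations[[scol]]]
  excluded <- sum(is.na(lg))
  if (excluded > 0)
    warning(excluded, " transcript(s) on unanchored scaffolds excluded")
  out <- data.frame(id = locations$id[!is.na(lg)],
                    scaffold = locations[[scol]][!is.na(lg)],
                    lg = unname(lg[!is.na(lg)]),
                    pos = point_position(locations$start[!is.na(lg)],
                                         locations$end[!is.na(lg)]),
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- excluded
  out
}

#' Build a linkage-group by chromosome synteny matrix
#'
#' Cross-tabulates orthologue pairs by the focal transcript's linkage
#' group and the comparator orthologue's chromosome. Full counts are kept
#' internally; the sub-\code{display_min} mask applies only to the masked
#' view/export (mirroring the usual "<3 removed for clarity" convention of
#' published tables).
#'
#' @param pairs orthologue pairs, data.frame with \code{id_a} (focal) and
#'   \code{id_b} (comparator), e.g. from [rbh_with_coverage()].
#' @param transcript_lg focal transcript anchoring from
#'   [anchor_transcripts()] (columns \code{id}, \code{lg}).
#' @param comparator_locations data.frame \code{id},
#'   \code{chrom_or_scaffold}, \code{start}, \code{end} for the comparator
#'   species.
#' @param display_min cells below this count are masked in the exported
#'   view.
#' @return A \code{synteny_matrix}: list with \code{counts} (matrix LG x
#'   chromosome), \code{display_min}, \code{n_pairs} (anchored pairs).
#' @export
build_synteny_matrix <- function(pairs, transcript_lg,
                                 comparator_locations, display_min = 3L) {
  lg <- setNames(transcript_lg$lg, transcript_lg$id)[pairs$id_a]
  ccol <- if ("chrom_or_scaffold" %in% names(comparator_locations))
    "chrom_or_scaffold" else "chrom"
  chrom <- setNames(comparator_locations[[ccol]],
                    comparator_locations$id)[pairs$id_b]
  keep <- !is.na(lg) & !is.na(chrom)
  counts <- table(lg = lg[keep], chrom = chrom[keep])
  counts <- unclass(counts)
  m <- structure(list(counts = counts,
                      display_min = as.integer(display_min),
                      n_pairs = sum(keep)),
                 class = "synteny_matrix")
  m
}

#' Masked view of a synteny matrix
#' @param m a \code{synteny_matrix}.
#' @return The count matrix with cells below \code{display_min} set to 0.
#' @export
masked_counts <- function(m) {
  stopifnot(inherits(m, "synteny_matrix"))
  x <- m$counts
  x[x < m$display_min] <- 0L
  x
}

#' @export
print.synteny_matrix <- function(x, ...) {
  cat("synteny_matrix:", nrow(x$counts), "linkage groups x",
      ncol(x$counts), "chromosomes,", x$n_pairs, "anchored pairs\n")
  print(masked_counts(x))
  invisible(x)
}

#' Dominant comparator chromosome(s) per linkage group
#'
#' For each LG row, the chromosomes holding at least \code{frac} of the
#' row mass. Ties for the argmax are all reported.
#'
#' @param m a \code{synteny_matrix}.
#' @param frac row-mass fraction defining dominance.
#' @return named list: LG -> character vector of dominant chromosomes.
#' @export
dominant_chromosomes <- function(m, frac = 0.5) {
  stopifnot(inherits(m, "synteny_matrix"))
  apply(m$counts, 1, function(row) {
    tot <- sum(row)
    if (tot == 0) return(character(0))
    names(row)[row >= frac * tot & row > 0]
  }, simplify = FALSE)
}

# chromosomes holding >= frac of an LG row's mass (the "duplication"
# reading: a post-WGD comparator shows two such chromosomes per LG)
row_major_chroms <- function(counts, lg, frac) {
  row <- counts[lg, ]
  tot <- sum(row)
  if (tot == 0) return(character(0))
  names(row)[row >= frac * tot & row > 0]
}

#' Classify fusion / fission / duplication patterns across comparators
#'
#' Works from two or more synteny matrices sharing the focal LG set:
#' \itemize{
#'   \item Two focal LGs sharing one dominant chromosome (each row holding
#'     at least \code{dominance_frac} of its mass on it) in \emph{all}
#'     comparators indicates a focal-lineage \strong{fission} of one
#'     ancestral chromosome.
#'   \item The same sharing observed in a strict subset of comparators is
#'     called a \strong{lineage-specific fusion} in each comparator where
#'     it is seen.
#'   \item Against a post-WGD comparator, an LG row with exactly two
#'     chromosomes each holding at least \code{duplication_frac} of the
#'     row mass carries a \strong{duplication signature}.
#' }
#'
#' @param matrices named list of \code{synteny_matrix} objects (one per
#'   comparator), sharing the focal LG set. At least two are required for
#'   fusion/fission calls.
#' @param dominance_frac row-mass fraction defining the dominant
#'   chromosome (default 0.5).
#' @param duplication_frac row-mass fraction each of two chromosomes must
#'   hold for a duplication signature (default 0.2).
#' @return list with \code{fissions} (data.frame lg_a, lg_b, chrom),
#'   \code{fusions} (data.frame comparator, chrom, lgs), and
#'   \code{duplication} (data.frame comparator, lg, n_dominant,
#'   chroms).
#' @export
classify_patterns <- function(matrices, dominance_frac = 0.5,
                              duplication_frac = 0.2) {
  if (length(matrices) < 2)
    stop("fusion/fission calls need at least 2 comparators")
  if (is.null(names(matrices)))
    names(matrices) <- paste0("comparator", seq_along(matrices))
  lgsets <- lapply(matrices, function(m) sort(rownames(m$counts)))
  if (length(unique(lgsets)) != 1)
    stop("matrices must share the focal LG set")
  lgs <- lgsets[[1]]
  # per comparator: which LG pairs share a dominant chromosome
  shared <- lapply(matrices, function(m) {
    dom <- lapply(lgs, function(lg)
      row_major_chroms(m$counts, lg, dominance_frac))
    names(dom) <- lgs
    out <- list()
    if (length(lgs) >= 2) {
      cmb <- utils::combn(lgs, 2)
      for (k in seq_len(ncol(cmb))) {
        common <- intersect(dom[[cmb[1, k]]], dom[[cmb[2, k]]])
        if (length(common) > 0)
          out[[paste(cmb[1, k], cmb[2, k], sep = "|")]] <- common
      }
    }
    out
  })
  all_pairs <- unique(unlist(lapply(shared, names)))
  fissions <- list(); fusions <- list()
  for (p in all_pairs) {
    seen_in <- names(shared)[vapply(shared, function(s) p %in% names(s),
                                    logical(1))]
    lg_ab <- strsplit(p, "|", fixed = TRUE)[[1]]
    if (length(seen_in) == length(matrices)) {
      fissions[[p]] <- data.frame(
        lg_a = lg_ab[1], lg_b = lg_ab[2],
        chrom = paste(sort(unique(unlist(lapply(shared[seen_in],
                 function(s) s[[p]])))), collapse = ","),
        stringsAsFactors = FALSE)
    } else {
      for (cmp in seen_in)
        fusions[[paste(cmp, p)]] <- data.frame(
          comparator = cmp,
          chrom = paste(shared[[cmp]][[p]], collapse = ","),
          lgs = sub("\\|", ",", p), stringsAsFactors = FALSE)
    }
  }
  dup <- do.call(rbind, lapply(names(matrices), function(nm) {
    m <- matrices[[nm]]
    do.call(rbind, lapply(lgs, function(lg) {
      ch <- row_major_chroms(m$counts, lg, duplication_frac)
      data.frame(comparator = nm, lg = lg, n_dominant = length(ch),
                 chroms = paste(sort(ch), collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  }))
  dup$duplication_signature <- dup$n_dominant == 2
  empty <- function(...) {
    d <- data.frame(...)
    d[0, , drop = FALSE]
  }
  list(fissions = if (length(fissions)) do.call(rbind, c(fissions,
         make.row.names = FALSE)) else
         empty(lg_a = "", lg_b = "", chrom = ""),
       fusions = if (length(fusions)) do.call(rbind, c(fusions,
         make.row.names = FALSE)) else
         empty(comparator = "", chrom = "", lgs = ""),
       duplication = dup)
}

#' Diagnose a scaffold as consistent, translocated, reorganized or chimeric
#'
#' Works from the scaffold's positionally ordered comparator hits:
#' \itemize{
#'   \item \strong{consistent} if one chromosome holds at least
#'     \code{purity} of the hits in every comparator;
#'   \item otherwise the best single breakpoint splitting the ordered hits
#'     into two maximally chromosome-pure halves is found;
#'     \strong{translocation} if the flanking scaffolds on the linkage
#'     group side-match the two halves' chromosomes;
#'   \item \strong{reorganized_context} if the linkage group's scaffolds
#'     collectively hit at least \code{reorganized_min_chroms} chromosomes
#'     in an interleaved arrangement;
#'   \item \strong{chimera_suspect} otherwise.
#' }
#' The verdict is withheld (\code{NA}) when fewer than \code{min_hits}
#' hits are available in every comparator.
#'
#' @param hits data.frame of the scaffold's mapped orthologue hits:
#'   columns \code{comparator}, \code{pos} (point position on the
#'   scaffold) and \code{chrom} (comparator chromosome).
#' @param flanks data.frame giving the dominant chromosome of the
#'   scaffolds flanking this one on its linkage group, per comparator:
#'   columns \code{comparator}, \code{left}, \code{right} (NA when the
#'   scaffold is terminal).
#' @param lg_chrom_sequence optional character vector: the dominant
#'   chromosomes of the linkage group's scaffolds in map order (one
#'   comparator), used for the reorganized-context test.
#' @param min_hits minimum hits required to issue a verdict.
#' @param purity hit fraction a single chromosome must reach for a
#'   consistent verdict (and each half must reach at the breakpoint).
#' @param reorganized_min_chroms distinct-chromosome count that marks a
#'   reorganized linkage group.
#' @return A \code{scaffold_diagnosis}: list with \code{verdict},
#'   \code{dominant}, \code{breakpoint}, \code{halves}, \code{evidence}.
#' @export
diagnose_scaffold <- function(hits, flanks = NULL,
                              lg_chrom_sequence = NULL, min_hits = 5L,
                              purity = 0.8, reorganized_min_chroms = 4L) {
  stopifnot(all(c("comparator", "pos", "chrom") %in% names(hits)))
  per_cmp <- split(hits, hits$comparator)
  if (all(vapply(per_cmp, nrow, integer(1)) < min_hits))
    return(structure(list(verdict = NA_character_,
                          dominant = NULL, breakpoint = NULL,
                          halves = NULL, evidence = "insufficient hits"),
                     class = "scaffold_diagnosis"))
  per_cmp <- per_cmp[vapply(per_cmp, nrow, integer(1)) >= min_hits]
  dominant <- lapply(per_cmp, function(d) {
    tt <- sort(table(d$chrom), decreasing = TRUE)
    list(chrom = names(tt)[1], frac = tt[[1]] / nrow(d))
  })
  if (all(vapply(dominant, function(x) x$frac >= purity, logical(1))))
    return(structure(list(
      verdict = "consistent",
      dominant = vapply(dominant, `[[`, "", "chrom"),
      breakpoint = NULL, halves = NULL,
      evidence = "single chromosome holds >= purity of hits"),
      class = "scaffold_diagnosis"))
  # breakpoint search in the comparator with the most hits
  ref <- per_cmp[[which.max(vapply(per_cmp, nrow, integer(1)))]]
  ref <- ref[order(ref$pos), ]
  n <- nrow(ref)
  best <- list(score = -Inf)
  for (k in seq_len(n - 1)) {
    left <- ref$chrom[seq_len(k)]
    right <- ref$chrom[(k + 1):n]
    tl <- sort(table(left), decreasing = TRUE)
    tr <- sort(table(right), decreasing = TRUE)
    score <- tl[[1]] + tr[[1]]  # total hits explained by two pure halves
    if (score > best$score && names(tl)[1] != names(tr)[1])
      best <- list(score = score, k = k,
                   left_chrom = names(tl)[1], right_chrom = names(tr)[1],
                   breakpoint = mean(ref$pos[k:(k + 1)]),
                   left_purity = tl[[1]] / k,
                   right_purity = tr[[1]] / (n - k))
  }
  halves <- c(best$left_chrom, best$right_chrom)
  # flank support: each half must be corroborated by the flanking
  # scaffold on its side (trying both scaffold orientations); the linkage
  # group's majority chromosome may stand in for one flank
  flank_support <- FALSE
  if (!is.null(flanks) && is.finite(best$score)) {
    cmp_name <- names(per_cmp)[which.max(vapply(per_cmp, nrow,
                                                integer(1)))]
    fl <- flanks[flanks$comparator == cmp_name, , drop = FALSE]
    lg_dom <- if (!is.null(lg_chrom_sequence) &&
                  length(lg_chrom_sequence) > 0)
      names(sort(table(lg_chrom_sequence), decreasing = TRUE))[1]
    else NA_character_
    if (nrow(fl) == 1) {
      supports <- function(h_left, h_right) {
        left_ok <- isTRUE(fl$left == h_left) ||
          (is.na(fl$left) && isTRUE(lg_dom == h_left))
        right_ok <- isTRUE(fl$right == h_right) ||
          (is.na(fl$right) && isTRUE(lg_dom == h_right))
        left_ok && right_ok
      }
      flank_support <- supports(best$left_chrom, best$right_chrom) ||
        supports(best$right_chrom, best$left_chrom)
    }
  }
  if (flank_support)
    return(structure(list(verdict = "translocation",
                          dominant = vapply(dominant, `[[`, "", "chrom"),
                          breakpoint = best$breakpoint, halves = halves,
                          evidence = "flanking scaffolds match halves"),
                     class = "scaffold_diagnosis"))
  if (!is.null(lg_chrom_sequence)) {
    distinct <- unique(lg_chrom_sequence)
    runs <- rle(lg_chrom_sequence)$lengths
    if (length(distinct) >= reorganized_min_chroms &&
        length(runs) > length(distinct))
      return(structure(list(verdict = "reorganized_context",
                            dominant = vapply(dominant, `[[`, "",
                                              "chrom"),
                            breakpoint = best$breakpoint, halves = halves,
                            evidence = "linkage group hits many interleaved chromosomes"),
                       class = "scaffold_diagnosis"))
  }
  structure(list(verdict = "chimera_suspect",
                 dominant = vapply(dominant, `[[`, "", "chrom"),
                 breakpoint = best$breakpoint, halves = halves,
                 evidence = "split hits without flank support"),
            class = "scaffold_diagnosis")
}

#' @export
print.scaffold_diagnosis <- function(x, ...) {
  cat("scaffold_diagnosis:", x$verdict, "\n")
  if (!is.null(x$halves))
    cat("  halves:", paste(x$halves, collapse = " | "),
        " breakpoint:", x$breakpoint, "\n")
  cat("  evidence:", x$evidence, "\n")
  invisible(x)
}

#' Diagnose every scaffold of a linkage group
#'
#' Convenience wrapper: derives per-scaffold ordered hits, flanking
#' dominant chromosomes and the LG chromosome sequence from an anchored
#' orthologue table, then applies [diagnose_scaffold()] to each scaffold.
#'
#' @param ortho data.frame with columns \code{scaffold}, \code{lg},
#'   \code{pos} (position on scaffold), \code{comparator}, \code{chrom};
#'   one row per mapped orthologue hit.
#' @param anchors data.frame \code{scaffold}, \code{lg}, \code{lg_order}.
#' @inheritParams diagnose_scaffold
#' @return data.frame with one row per (lg, scaffold): verdict, dominant
#'   chromosome, breakpoint, halves.
#' @export
diagnose_lg_scaffolds <- function(ortho, anchors, min_hits = 5L,
                                  purity = 0.8,
                                  reorganized_min_chroms = 4L) {
  anchors <- anchors[order(anchors$lg, anchors$lg_order), ]
  res <- list()
  for (lg in unique(anchors$lg)) {
    sc <- anchors$scaffold[anchors$lg == lg]
    # dominant chromosome per scaffold per comparator
    dom <- lapply(sc, function(s) {
      h <- ortho[ortho$scaffold == s, , drop = FALSE]
      vapply(split(h, h$comparator), function(d)
        names(sort(table(d$chrom), decreasing = TRUE))[1], character(1))
    })
    names(dom) <- sc
    cmps <- unique(ortho$comparator)
    for (i in seq_along(sc)) {
      s <- sc[i]
      h <- ortho[ortho$scaffold == s, c("comparator", "pos", "chrom")]
      flanks <- do.call(rbind, lapply(cmps, function(cm) {
        lf <- if (i > 1) dom[[sc[i - 1]]][cm] else NA_character_
        rt <- if (i < length(sc)) dom[[sc[i + 1]]][cm] else NA_character_
        data.frame(comparator = cm, left = unname(lf), right = unname(rt),
                   stringsAsFactors = FALSE)
      }))
      seq1 <- unname(vapply(dom, function(d)
        if (cmps[1] %in% names(d)) d[[cmps[1]]] else NA_character_,
        character(1)))
      d <- diagnose_scaffold(h, flanks, seq1[!is.na(seq1)], min_hits,
                             purity, reorganized_min_chroms)
      res[[paste(lg, s)]] <- data.frame(
        lg = lg, scaffold = s, verdict = d$verdict,
        halves = paste(d$halves, collapse = "|"),
        breakpoint = if (is.null(d$breakpoint)) NA_real_ else
          d$breakpoint,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
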