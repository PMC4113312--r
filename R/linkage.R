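# Half-sib (pseudo-testcross) microsatellite linkage mapping: marker
# informativeness, missingness filtering, two-point recombination / LOD,
# LOD-threshold grouping with cross-parent joining, greedy ordering,
# Kosambi/Haldane map functions, sex-specific map merging and statistics.

MISSING_GT <- "-"

parse_gt <- function(g) {
  if (is.na(g) || g == MISSING_GT) return(c(NA_character_, NA_character_))
  parts <- strsplit(g, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2 || any(!nzchar(parts)))
    stop("malformed genotype string: ", g)
  parts
}

is_het <- function(g) {
  a <- parse_gt(g)
  !anyNA(a) && a[1] != a[2]
}

#' Classify marker informativeness in a two-parent cross
#'
#' A parent is informative at a marker iff it is heterozygous: the allele
#' it transmitted can then be read in every progeny whose genotype
#' resolves unambiguously given the other parent (homozygous progeny
#' always resolve; a shared-heterozygote configuration leaves heterozygous
#' progeny ambiguous and those meioses are simply dropped).
#'
#' @param mother_gt,father_gt parental genotypes as \code{"a/b"} strings.
#' @return One of \code{"mother_only"}, \code{"father_only"},
#'   \code{"both"}, \code{"neither"}.
#' @export
classify_informativeness <- function(mother_gt, father_gt) {
  m <- is_het(mother_gt); f <- is_het(father_gt)
  if (m && f) "both" else if (m) "mother_only" else if (f) "father_only"
  else "neither"
}

#' Per-marker missing-genotype fraction
#' @param table a \code{genotype_table}.
#' @return named numeric vector (marker -> missing fraction over progeny).
#' @export
missing_fraction <- function(table) {
  prog <- names(attr(table, "progeny_father"))
  gt <- as.matrix(table[, prog, drop = FALSE])
  setNames(rowMeans(gt == MISSING_GT), table$marker)
}

#' Drop markers with excessive missing data
#'
#' Markers whose missing fraction is strictly greater than
#' \code{max_missing} are dropped, unless named on \code{keep_list} (such
#' markers are retained but flagged, mirroring the practice of keeping a
#' high-missingness marker that joins two otherwise separate groups).
#'
#' @param table a \code{genotype_table}.
#' @param max_missing maximum tolerated missing fraction (default 0.15).
#' @param keep_list marker ids exempt from the filter.
#' @return The filtered table; attributes \code{dropped} (ids) and
#'   \code{kept_flagged} (exempt ids over the threshold).
#' @export
missing_filter <- function(table, max_missing = 0.15,
                           keep_list = character(0)) {
  mf <- missing_fraction(table)
  over <- names(mf)[mf > max_missing]
  drop <- setdiff(over, keep_list)
  out <- table[!table$marker %in% drop, , drop = FALSE]
  attr(out, "progeny_father") <- attr(table, "progeny_father")
  attr(out, "dropped") <- drop
  attr(out, "kept_flagged") <- intersect(over, keep_list)
  class(out) <- class(table)
  out
}

#' Transmitted-allele matrix for one parent
#'
#' For each marker and progeny, which of the parent's two alleles was
#' transmitted (1 or 2), or \code{NA} when the call is missing,
#' unresolvable given the other parent's genotype, or the progeny belongs
#' to another father. Mendelian-inconsistent progeny genotypes are set to
#' missing with a warning.
#'
#' @param table a \code{genotype_table}.
#' @param parent \code{"mother"} or a father column name.
#' @return integer matrix markers x progeny with entries 1/2/NA.
#' @export
transmissions <- function(table, parent) {
  prog <- attr(table, "progeny_father")
  cols <- if (parent == "mother") names(prog)
          else names(prog)[prog == parent]
  other_of <- function(j) if (parent == "mother")
    prog[[cols[j]]] else "mother"
  out <- matrix(NA_integer_, nrow(table), length(cols),
                dimnames = list(table$marker, cols))
  n_bad <- 0L
  for (i in seq_len(nrow(table))) {
    pa <- parse_gt(table[[parent]][i])
    if (anyNA(pa) || pa[1] == pa[2]) next  # uninformative or missing
    for (j in seq_along(cols)) {
      g <- table[[cols[j]]][i]
      if (g == MISSING_GT) next
      al <- parse_gt(g)
      oa <- parse_gt(table[[other_of(j)]][i])
      # candidate assignments: (transmitted by `parent`, by other parent)
      ok <- unique(unlist(lapply(1:2, function(x) {
        lapply(1:2, function(y) {
          if (setequal(c(pa[x], oa[y]), al) &&
              (pa[x] == al[1] && oa[y] == al[2] ||
               pa[x] == al[2] && oa[y] == al[1])) pa[x] else NULL
        })
      })))
      if (length(ok) == 0) {
        # allele not explicable by the parents: treat as missing
        n_bad <- n_bad + 1L
        next
      }
      if (length(ok) == 1)
        out[i, j] <- if (ok == pa[1]) 1L else 2L
    }
  }
  if (n_bad > 0)
    warning(n_bad, " progeny call(s) inconsistent with parental alleles ",
            "set to missing")
  out
}

#' Two-point recombination and LOD for a marker pair
#'
#' Pseudo-testcross likelihood ratio with unknown phase: over the
#' \code{n} progeny informative at both markers, \code{x} transmissions
#' switch parental allele between the markers; the recombinant count is
#' \code{r = min(x, n - x)} (the better of the two phase assignments) and
#' \deqn{LOD = r \log_{10}\hat r + (n-r)\log_{10}(1-\hat r) +
#'   n \log_{10} 2,}
#' with \eqn{\hat r = r/n} and \eqn{LOD = n \log_{10} 2} when r = 0.
#'
#' @param ti,tj integer vectors of transmitted-allele codes (1/2/NA) for
#'   the two markers over the same progeny (one parent), e.g. rows of the
#'   matrix built by the grouping machinery.
#' @return list \code{n}, \code{r}, \code{r_hat}, \code{lod}
#'   (\code{lod = NA} when \code{n = 0}).
#' @export
two_point <- function(ti, tj) {
  use <- !is.na(ti) & !is.na(tj)
  n <- sum(use)
  if (n == 0) return(list(n = 0L, r = NA_integer_, r_hat = NA_real_,
                          lod = NA_real_))
  x <- sum(ti[use] != tj[use])
  r <- min(x, n - x)
  r_hat <- r / n
  lod <- if (r == 0) n * log10(2)
         else r * log10(r_hat) + (n - r) * log10(1 - r_hat) + n * log10(2)
  list(n = as.integer(n), r = as.integer(r), r_hat = r_hat, lod = lod)
}

# All pairwise two-point statistics for one parent, vectorized.
# Returns list of matrices n, r, r_hat, lod (markers x markers).
pair_stats_matrix <- function(trans) {
  A <- (trans == 1L); A[is.na(A)] <- FALSE
  B <- (trans == 2L); B[is.na(B)] <- FALSE
  storage.mode(A) <- "numeric"; storage.mode(B) <- "numeric"
  n <- tcrossprod(A + B)
  x <- tcrossprod(A, B) + tcrossprod(B, A)
  r <- pmin(x, n - x)
  r_hat <- ifelse(n > 0, r / n, NA_real_)
  lod <- matrix(NA_real_, nrow(n), ncol(n), dimnames = dimnames(n))
  pos <- n > 0
  lod[pos] <- ifelse(r[pos] == 0, n[pos] * log10(2),
                     r[pos] * log10(pmax(r_hat[pos], 1e-300)) +
                       (n[pos] - r[pos]) * log10(1 - r_hat[pos]) +
                       n[pos] * log10(2))
  diag(lod) <- NA
  list(n = n, r = r, r_hat = r_hat, lod = lod)
}

#' All pairwise two-point statistics per parent
#'
#' @param table a \code{genotype_table}.
#' @param parents which parents to analyse (default: mother plus every
#'   father column present).
#' @return named list (per parent) of lists with matrices \code{n},
#'   \code{r}, \code{r_hat}, \code{lod} and the transmission matrix
#'   \code{trans}.
#' @export
pair_stats <- function(table, parents = NULL) {
  if (is.null(parents))
    parents <- c("mother", grep("^father", names(table), value = TRUE))
  parents <- intersect(parents, names(table))
  out <- lapply(parents, function(p) {
    tr <- transmissions(table, p)
    c(pair_stats_matrix(tr), list(trans = tr))
  })
  names(out) <- parents
  out
}

#' Group markers by two-point LOD
#'
#' Per parent, single-linkage clustering of markers at
#' \code{LOD >= lod_form}; additionally, an edge with
#' \code{lod_join <= LOD < lod_form} in one parent joins two clusters when
#' another parent links the same marker pair at \code{>= lod_form}
#' (cross-parent support). Markers informative in a parent but linked to
#' nothing are listed as unlinked.
#'
#' @param stats output of [pair_stats()].
#' @param lod_form LOD threshold at which groups form (default 4.0).
#' @param lod_join relaxed joining threshold (default 3.0), honoured only
#'   with cross-parent support.
#' @return list with \code{groups} (combined across parents: list of
#'   marker-id vectors, ordered by decreasing size), \code{per_parent}
#'   (the same per parent), and \code{unlinked} (per parent).
#' @export
group_markers <- function(stats, lod_form = 4.0, lod_join = 3.0) {
  all_markers <- rownames(stats[[1]]$lod)
  edge_list <- list()
  per_parent <- list()
  unlinked <- list()
  for (p in names(stats)) {
    lod <- stats[[p]]$lod
    informative <- rownames(lod)[apply(!is.na(stats[[p]]$trans), 1, any)]
    strong <- which(!is.na(lod) & lod >= lod_form, arr.ind = TRUE)
    strong <- strong[strong[, 1] < strong[, 2], , drop = FALSE]
    # cross-parent supported joining edges
    weak <- which(!is.na(lod) & lod >= lod_join & lod < lod_form,
                  arr.ind = TRUE)
    weak <- weak[weak[, 1] < weak[, 2], , drop = FALSE]
    if (nrow(weak) > 0) {
      supported <- vapply(seq_len(nrow(weak)), function(k) {
        i <- rownames(lod)[weak[k, 1]]; j <- colnames(lod)[weak[k, 2]]
        any(vapply(setdiff(names(stats), p), function(q) {
          lq <- stats[[q]]$lod
          i %in% rownames(lq) && j %in% colnames(lq) &&
            isTRUE(lq[i, j] >= lod_form)
        }, logical(1)))
      }, logical(1))
      weak <- weak[supported, , drop = FALSE]
    }
    edges <- rbind(strong, weak)
    g <- igraph::graph_from_data_frame(
      data.frame(from = rownames(lod)[edges[, 1]],
                 to = colnames(lod)[edges[, 2]]),
      directed = FALSE,
      vertices = data.frame(name = informative))
    comp <- igraph::components(g)$membership
    grp <- split(names(comp), comp)
    per_parent[[p]] <- grp[order(-vapply(grp, length, integer(1)))]
    unlinked[[p]] <- names(comp)[comp %in%
      as.integer(names(which(table(comp) == 1)))]
    edge_list[[p]] <- data.frame(from = rownames(lod)[edges[, 1]],
                                 to = colnames(lod)[edges[, 2]],
                                 stringsAsFactors = FALSE)
  }
  # combined groups: union of qualifying edges across parents; markers
  # shared between parents tie their per-parent groups together
  all_edges <- do.call(rbind, edge_list)
  gc <- igraph::graph_from_data_frame(
    all_edges, directed = FALSE,
    vertices = data.frame(name = all_markers))
  compc <- igraph::components(gc)$membership
  grp <- split(names(compc), compc)
  sizes <- vapply(grp, length, integer(1))
  combined <- grp[sizes > 1]
  combined <- combined[order(-vapply(combined, length, integer(1)))]
  names(combined) <- sprintf("LG-%02d", seq_along(combined))
  list(groups = combined, per_parent = per_parent,
       unlinked_combined = names(compc)[compc %in%
         as.integer(names(which(table(compc) == 1)))],
       unlinked = lapply(unlinked, identity))
}

#' Order the markers of a linkage group
#'
#' Greedy chain construction (start from the pair with the smallest
#' recombination fraction, repeatedly append at either end the marker
#' with the smallest \eqn{\hat r} to that end, ties broken by marker id)
#' followed by a deterministic 2-opt refinement: segment reversals that
#' strictly reduce the sum of adjacent \eqn{\hat r} are applied in a fixed
#' scan order until none remains. The refinement repairs the local
#' adjacent swaps and short inversions the greedy chain is prone to at
#' tight marker spacings. The orientation is canonicalized so the
#' lexicographically smaller terminal comes first.
#'
#' @param markers marker ids of one group.
#' @param r_hat matrix of pairwise recombination fractions (one parent or
#'   a combined estimate).
#' @param refine logical; apply the 2-opt pass (default TRUE).
#' @return character vector: the ordered markers.
#' @export
order_group <- function(markers, r_hat, refine = TRUE) {
  if (length(markers) <= 2) return(sort(markers))
  rh <- r_hat[markers, markers]
  diag(rh) <- NA
  rh[is.na(rh)] <- 0.5  # no data: treat as unlinked for ordering
  # tightest pair, deterministic tie-break on ids
  best <- which(rh == min(rh), arr.ind = TRUE)
  cand <- data.frame(a = rownames(rh)[best[, 1]],
                     b = colnames(rh)[best[, 2]])
  cand <- cand[cand$a < cand$b, , drop = FALSE]
  cand <- cand[order(cand$a, cand$b), , drop = FALSE]
  chain <- c(cand$a[1], cand$b[1])
  left <- setdiff(markers, chain)
  while (length(left) > 0) {
    dl <- rh[chain[1], left]
    dr <- rh[chain[length(chain)], left]
    ml <- min(dl); mr <- min(dr)
    if (ml <= mr) {
      pick <- sort(left[dl == ml])[1]
      chain <- c(pick, chain)
    } else {
      pick <- sort(left[dr == mr])[1]
      chain <- c(chain, pick)
    }
    left <- setdiff(left, pick)
  }
  if (refine) chain <- refine_order(chain, rh)
  if (chain[1] > chain[length(chain)]) chain <- rev(chain)
  chain
}

# deterministic local search on the path objective sum of adjacent
# r_hat: first-improvement scans over all segment reversals (2-opt) and
# single-marker relocations (or-opt), repeated to a fixed point (capped)
refine_order <- function(chain, rh) {
  n <- length(chain)
  path_cost <- function(ord) sum(rh[cbind(ord[-n], ord[-1])])
  for (pass in seq_len(50)) {
    improved <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        cand <- chain
        cand[i:j] <- rev(cand[i:j])
        if (path_cost(cand) < path_cost(chain) - 1e-12) {
          chain <- cand
          improved <- TRUE
        }
      }
    }
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j == i) next
        cand <- append(chain[-i], chain[i], after = j - 1)
        if (path_cost(cand) < path_cost(chain) - 1e-12) {
          chain <- cand
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  chain
}

#' Map distance from a recombination fraction
#'
#' Kosambi: \eqn{d = 25\ln((1+2\hat r)/(1-2\hat r))}; Haldane:
#' \eqn{d = -50\ln(1-2\hat r)}. Kosambi is the default, the common choice
#' for fish maps; the choice is exposed throughout.
#'
#' @param r_hat recombination fraction(s) in `[0, 0.5)`.
#' @param fun \code{"kosambi"} or \code{"haldane"}.
#' @return distance(s) in centiMorgans.
#' @export
map_distance <- function(r_hat, fun = c("kosambi", "haldane")) {
  fun <- match.arg(fun)
  if (any(r_hat < 0 | r_hat >= 0.5)) stop("r_hat must be in [0, 0.5)")
  if (fun == "haldane") -50 * log(1 - 2 * r_hat)
  else 25 * log((1 + 2 * r_hat) / (1 - 2 * r_hat))
}

#' Build a linkage map for one parent
#'
#' Groups markers ([group_markers()] on this parent's statistics alone,
#' unless groups are supplied), orders each group ([order_group()]) and
#' accumulates adjacent-pair map distances.
#'
#' @param stats_parent one element of [pair_stats()] output.
#' @param groups optional list of marker groups (e.g. the combined groups
#'   restricted to this parent's informative markers).
#' @param lod_form,lod_join see [group_markers()].
#' @param map_function see [map_distance()].
#' @param sex label stored on the map.
#' @return A \code{linkage_map}: list of data.frames (\code{marker},
#'   \code{pos_cM}) per group, with attributes \code{sex} and
#'   \code{total_cM}.
#' @export
build_map <- function(stats_parent, groups = NULL, lod_form = 4.0,
                      lod_join = 3.0,
                      map_function = c("kosambi", "haldane"),
                      sex = "unknown") {
  map_function <- match.arg(map_function)
  if (is.null(groups)) {
    grouped <- group_markers(setNames(list(stats_parent), sex),
                             lod_form, lod_join)
    groups <- grouped$groups
  }
  informative <- rownames(stats_parent$lod)[
    apply(!is.na(stats_parent$trans), 1, any)]
  maps <- list()
  for (gname in names(groups)) {
    mk <- intersect(groups[[gname]], informative)
    if (length(mk) < 2) next
    ord <- order_group(mk, stats_parent$r_hat)
    rr <- vapply(seq_len(length(ord) - 1), function(i) {
      v <- stats_parent$r_hat[ord[i], ord[i + 1]]
      if (is.na(v)) 0.49 else min(v, 0.49)
    }, numeric(1))
    pos <- cumsum(c(0, map_distance(rr, map_function)))
    maps[[gname]] <- data.frame(marker = ord, pos_cM = pos,
                                stringsAsFactors = FALSE)
  }
  structure(maps, class = "linkage_map", sex = sex,
            total_cM = sum(vapply(maps, function(m)
              max(m$pos_cM) - min(m$pos_cM), numeric(1))))
}

#' @export
print.linkage_map <- function(x, ...) {
  cat("linkage_map (", attr(x, "sex"), "): ", length(x), " groups, ",
      round(attr(x, "total_cM"), 1), " cM\n", sep = "")
  for (g in names(x))
    cat(sprintf("  %s: %d markers, %.1f cM\n", g, nrow(x[[g]]),
                max(x[[g]]$pos_cM)))
  invisible(x)
}

# piecewise-linear transfer of positions from map `from` onto the scale
# of `to` through shared anchor markers
transfer_positions <- function(from_df, anchors_from, anchors_to) {
  stats::approx(anchors_from, anchors_to, xout = from_df$pos_cM,
                rule = 2, ties = mean)$y
}

#' Merge sex-specific linkage maps
#'
#' Groups are paired through shared (both-informative) markers; the
#' incoming group's orientation is chosen to maximize shared-marker order
#' agreement; non-shared markers are interpolated proportionally between
#' the nearest shared anchors (constant extrapolation beyond the terminal
#' anchors). Groups sharing no markers are reported unmerged.
#'
#' @param map_a,map_b two \code{linkage_map} objects (e.g. female and
#'   male).
#' @return list with \code{merged} (a \code{linkage_map} labelled
#'   \code{"merged"}), \code{unmerged_a}, \code{unmerged_b} (group names),
#'   and \code{anchor_report} (shared-marker counts and order agreement
#'   per merged group).
#' @export
merge_maps <- function(map_a, map_b) {
  used_b <- character(0)
  merged <- list()
  report <- list()
  for (ga in names(map_a)) {
    a <- map_a[[ga]]
    share <- vapply(map_b, function(b) length(intersect(a$marker,
                                                        b$marker)),
                    integer(1))
    if (length(share) == 0 || max(share) == 0) {
      merged[[ga]] <- a
      next
    }
    gb <- names(map_b)[which.max(share)]
    used_b <- c(used_b, gb)
    b <- map_b[[gb]]
    shared <- intersect(a$marker, b$marker)
    pa <- setNames(a$pos_cM, a$marker)[shared]
    pb <- setNames(b$pos_cM, b$marker)[shared]
    agree <- if (length(shared) >= 2)
      stats::cor(rank(pa), rank(pb), method = "kendall") else 1
    if (!is.na(agree) && agree < 0) {
      b$pos_cM <- max(b$pos_cM) - b$pos_cM
      b <- b[order(b$pos_cM), ]
      pb <- setNames(b$pos_cM, b$marker)[shared]
      agree <- -agree
    }
    if (length(shared) >= 2 && any(order(pa) != order(pb))) {
      # contradictory internal order: keep the order of the map with the
      # larger span (a proxy for the better-supported parent)
      report_flag <- "order_conflict"
    } else report_flag <- "ok"
    b_only <- b[!b$marker %in% shared, , drop = FALSE]
    if (length(shared) >= 2 && nrow(b_only) > 0) {
      anchor_order <- names(sort(pb))
      b_only$pos_cM <- transfer_positions(b_only, pb[anchor_order],
                                          pa[anchor_order])
    } else if (nrow(b_only) > 0 && length(shared) == 1) {
      # single anchor: rigid shift
      b_only$pos_cM <- b_only$pos_cM - pb[1] + pa[1]
    }
    comb <- rbind(a, b_only)
    comb <- comb[order(comb$pos_cM, comb$marker), ]
    comb$pos_cM <- comb$pos_cM - min(comb$pos_cM)
    rownames(comb) <- NULL
    merged[[ga]] <- comb
    report[[ga]] <- data.frame(group_a = ga, group_b = gb,
                               n_shared = length(shared),
                               order = report_flag,
                               agreement = agree,
                               stringsAsFactors = FALSE)
  }
  structure(
    list(merged = structure(merged, class = "linkage_map",
                            sex = "merged",
                            total_cM = sum(vapply(merged, function(m)
                              max(m$pos_cM) - min(m$pos_cM),
                              numeric(1)))),
         unmerged_a = names(map_a)[vapply(names(map_a), function(g)
           is.null(report[[g]]), logical(1))],
         unmerged_b = setdiff(names(map_b), used_b),
         anchor_report = if (length(report)) do.call(rbind, report)
                         else NULL),
    class = "map_merge")
}

#' Map totals and female:male recombination ratio
#'
#' @param female,male \code{linkage_map} objects.
#' @param merged optional merged map to include in the totals.
#' @return list with \code{totals} (named cM totals),
#'   \code{ratio} (female / male, 2 decimals), and \code{per_group}
#'   (group-level spans and ratios for groups present in both maps).
#' @export
map_stats <- function(female, male, merged = NULL) {
  span <- function(m) vapply(m, function(g) max(g$pos_cM) - min(g$pos_cM),
                             numeric(1))
  tf <- sum(span(female)); tm <- sum(span(male))
  ratio <- if (tm > 0) round(tf / tm, 2) else NA_real_
  shared <- intersect(names(female), names(male))
  per_group <- data.frame(
    group = shared,
    female_cM = span(female)[shared],
    male_cM = span(male)[shared],
    stringsAsFactors = FALSE)
  per_group$ratio <- ifelse(per_group$male_cM > 0,
                            round(per_group$female_cM /
                                    per_group$male_cM, 2), NA)
  totals <- c(female = tf, male = tm)
  if (!is.null(merged)) totals["merged"] <- sum(span(merged))
  list(totals = totals, ratio = ratio, per_group = per_group)
}
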