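# Half-sib (two-father / single mother) microsatellite family simulator.

#' Build a true marker map
#'
#' Evenly spaced markers on each linkage group, the ground truth for
#' linkage-recovery tests.
#'
#' @param n_groups number of linkage groups (chromosomes).
#' @param markers_per_group markers per group.
#' @param spacing_cM distance between adjacent markers in centiMorgans.
#' @return data.frame with columns \code{marker}, \code{lg},
#'   \code{pos_cM}.
#' @export
make_marker_map <- function(n_groups = 25L, markers_per_group = 20L,
                            spacing_cM = 2.7) {
  lg <- rep(sprintf("LG%02d", seq_len(n_groups)), each = markers_per_group)
  data.frame(marker = sprintf("m%s_%02d", rep(sprintf("%02d",
               seq_len(n_groups)), each = markers_per_group),
               rep(seq_len(markers_per_group), n_groups)),
             lg = lg,
             pos_cM = rep((seq_len(markers_per_group) - 1) * spacing_cM,
                          n_groups),
             stringsAsFactors = FALSE)
}

#' Simulate parental microsatellite genotypes
#'
#' Each parent draws its two alleles from a small per-marker allele pool
#' (microsatellite-like multi-allelism); with probability
#' \code{hom_fraction} a parent is homozygous (and hence uninformative) at
#' a marker.
#'
#' @param map a marker map from [make_marker_map()].
#' @param n_fathers number of fathers in the half-sib family.
#' @param n_alleles per-marker allele pool size.
#' @param hom_fraction probability that a parent is homozygous at a marker.
#' @return data.frame with columns \code{marker}, \code{mother},
#'   \code{father1}, ... — genotypes as \code{"a/b"} strings.
#' @export
simulate_parent_genotypes <- function(map, n_fathers = 2L, n_alleles = 4L,
                                      hom_fraction = 0.3) {
  draw <- function() {
    pool <- sample(100:160, n_alleles)
    gts <- vapply(seq_len(n_fathers + 1L), function(p) {
      if (runif(1) < hom_fraction) {
        a <- sample(pool, 1); paste(a, a, sep = "/")
      } else paste(sort(sample(pool, 2)), collapse = "/")
    }, character(1))
    gts
  }
  g <- t(vapply(seq_len(nrow(map)), function(i) draw(),
                character(n_fathers + 1L)))
  out <- data.frame(marker = map$marker, mother = g[, 1],
                    stringsAsFactors = FALSE)
  for (f in seq_len(n_fathers)) out[[paste0("father", f)]] <- g[, f + 1L]
  out
}

split_gt <- function(g) {
  m <- do.call(rbind, strsplit(g, "/", fixed = TRUE))
  if (is.null(m)) m <- matrix(character(0), 0, 2)
  m
}

inv_haldane <- function(d_cM) {
  if (any(d_cM < 0)) stop("negative cM interval")
  0.5 * (1 - exp(-d_cM / 50))
}

# gamete haplotypes for one parent over the markers of one linkage group:
# matrix n_markers x n_meioses of allele-column indices (1 or 2)
meiose_group <- function(pos_cM, n_meioses) {
  if (any(diff(pos_cM) < 0)) stop("negative cM interval")
  n <- length(pos_cM)
  out <- matrix(0L, n, n_meioses)
  out[1, ] <- sample(1:2, n_meioses, replace = TRUE)
  if (n > 1) {
    r <- inv_haldane(diff(pos_cM))
    for (i in 2:n) {
      sw <- runif(n_meioses) < r[i - 1]
      out[i, ] <- ifelse(sw, 3L - out[i - 1, ], out[i - 1, ])
    }
  }
  out
}

#' Simulate a half-sib family genotype table
#'
#' Meioses are simulated without crossover interference (inter-marker
#' recombination probabilities follow the inverse Haldane transform of the
#' cM interval). Female and male meioses can use different maps (e.g. to
#' simulate a female:male recombination-rate ratio). Missing calls are
#' injected completely at random at \code{missing_rate}. Progeny genotypes
#' are reported unphased (alleles sorted), as a genotyping instrument
#' would.
#'
#' @param map_female,map_male marker maps ([make_marker_map()]) giving
#'   sex-specific positions; same markers, same order.
#' @param parents parental genotypes from [simulate_parent_genotypes()].
#' @param n_progeny integer vector, progeny per father (default
#'   \code{c(48, 44)}).
#' @param missing_rate MCAR missingness fraction.
#' @return A \code{genotype_table}: data.frame with marker, mother,
#'   father columns and one column per progeny (named
#'   \code{p<father>_<k>}), missing coded \code{"-"}; attribute
#'   \code{progeny_father} maps progeny column names to father columns.
#' @export
simulate_half_sib_family <- function(map_female, map_male = map_female,
                                     parents, n_progeny = c(48L, 44L),
                                     missing_rate = 0.05) {
  stopifnot(identical(map_female$marker, map_male$marker))
  n_fathers <- length(n_progeny)
  mom <- split_gt(parents$mother)
  dads <- lapply(seq_len(n_fathers),
                 function(f) split_gt(parents[[paste0("father", f)]]))
  nm <- nrow(map_female)
  prog_names <- unlist(lapply(seq_len(n_fathers), function(f)
    sprintf("p%d_%02d", f, seq_len(n_progeny[f]))))
  progeny_father <- setNames(rep(paste0("father", seq_len(n_fathers)),
                                 n_progeny), prog_names)
  gt <- matrix(NA_character_, nm, length(prog_names),
               dimnames = list(parents$marker, prog_names))
  col0 <- 0L
  for (f in seq_len(n_fathers)) {
    cols <- col0 + seq_len(n_progeny[f])
    mat_h <- matrix(0L, nm, n_progeny[f])
    pat_h <- matrix(0L, nm, n_progeny[f])
    for (lg in unique(map_female$lg)) {
      i <- which(map_female$lg == lg)
      mat_h[i, ] <- meiose_group(map_female$pos_cM[i], n_progeny[f])
      pat_h[i, ] <- meiose_group(map_male$pos_cM[i], n_progeny[f])
    }
    for (j in seq_len(n_progeny[f])) {
      ma <- mom[cbind(seq_len(nm), mat_h[, j])]
      pa <- dads[[f]][cbind(seq_len(nm), pat_h[, j])]
      gt[, col0 + j] <- paste(pmin(as.integer(ma), as.integer(pa)),
                              pmax(as.integer(ma), as.integer(pa)),
                              sep = "/")
    }
    col0 <- col0 + n_progeny[f]
  }
  if (missing_rate > 0) {
    miss <- matrix(runif(length(gt)) < missing_rate, nrow(gt))
    gt[miss] <- "-"
  }
  tab <- cbind(data.frame(marker = parents$marker,
                          mother = parents$mother,
                          stringsAsFactors = FALSE),
               parents[, grep("^father", names(parents)), drop = FALSE],
               as.data.frame(gt, stringsAsFactors = FALSE))
  rownames(tab) <- NULL
  attr(tab, "progeny_father") <- progeny_father
  class(tab) <- c("genotype_table", "data.frame")
  tab
}
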