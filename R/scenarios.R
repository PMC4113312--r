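# Packaged parameter-recovery studies: each scenario simulates a study
# condition with known truth, runs the corresponding analysis end to end,
# and returns the measured quantities next to the truth. These back the
# package's validation suite and the reproduction script.

#' Duplication-peak recovery study
#'
#' Simulates an ancient duplicate cohort (one WGD at \code{d_ancient}
#' per-site divergence) and a recent cohort (WGD at \code{d_recent}),
#' pools the transcripts, recovers pairs by within-set reciprocal best
#' hits, and reads the 1%-bin identity histogram.
#'
#' @param seed integer seed.
#' @param n_pairs_ancient,n_pairs_recent duplicate pairs per cohort.
#' @param d_ancient,d_recent per-site divergences (defaults 0.18 / 0.03,
#'   the ancient-teleost-like and recent-duplication-like settings).
#' @param band aligner band half-width.
#' @return list: \code{n_pairs}, \code{modal_bin}, \code{peak_bins},
#'   \code{histogram}, \code{band_counts} (pairs per similarity band),
#'   \code{recovered_ancient} (fraction of ancient truth pairs recovered
#'   as RBHs).
#' @export
scenario_duplication_peaks <- function(seed, n_pairs_ancient = 220L,
                                       n_pairs_recent = 60L,
                                       d_ancient = 0.18,
                                       d_recent = 0.03, band = 16L) {
  gpc <- 20L
  anc <- simulate_ancestral_genome(sim_config(
    seed = seed, n_chromosomes_ancestral =
      as.integer(ceiling(n_pairs_ancient / gpc)),
    genes_per_chromosome = gpc, gene_length_range = c(300L, 600L)))
  old <- apply_wgd(anc$genome, anc$truth, d_ancient, event = "3R")
  rec <- simulate_ancestral_genome(sim_config(
    seed = seed + 1000L, n_chromosomes_ancestral =
      as.integer(ceiling(n_pairs_recent / gpc)),
    genes_per_chromosome = gpc, gene_length_range = c(300L, 600L)))
  rec <- apply_wgd(rec$genome, rec$truth, d_recent, event = "recent")
  rseqs <- setNames(rec$genome$seqs,
                    paste0("r_", names(rec$genome$seqs)))
  seqs <- c(old$genome$seqs, rseqs)
  pairs <- reciprocal_best_hits(seqs, band = band)
  h <- similarity_histogram(pairs)
  pk <- detect_peaks(h)
  anc_ids <- old$genome$genes$gene_id[!grepl("d$",
    old$genome$genes$gene_id)]
  truth_keys <- paste(anc_ids, paste0(anc_ids, "d"))
  got_keys <- paste(pairs$id_a, pairs$id_b)
  bands <- classify_bands(pairs)
  list(n_pairs = nrow(pairs),
       modal_bin = h$bin[which.max(h$count)],
       peak_bins = sort(pk$bin),
       histogram = h,
       band_counts = table(bands$band),
       recovered_ancient = mean(truth_keys %in% got_keys))
}

#' Whole-genome-duplication synteny signature study
#'
#' From one ancestral karyotype, derives a focal (pre-duplication)
#' species and two comparator lineages — one that experienced an extra
#' WGD and one that did not — then builds synteny matrices from
#' coverage-filtered reciprocal best hits and counts dominant comparator
#' chromosomes per focal linkage group.
#'
#' @param seed integer seed.
#' @param n_chromosomes,genes_per_chromosome ancestral karyotype size.
#' @param d_speciation,d_wgd lineage and duplication divergences.
#' @param band aligner band half-width.
#' @param duplication_frac see [classify_patterns()].
#' @return list: \code{n_lg}, \code{wgd_two_dominant} (LG count with
#'   exactly two dominant chromosomes against the duplicated comparator),
#'   \code{flat_one_dominant} (against the unduplicated comparator),
#'   \code{patterns}, \code{matrices}.
#' @export
scenario_wgd_synteny <- function(seed, n_chromosomes = 24L,
                                 genes_per_chromosome = 30L,
                                 d_speciation = 0.05, d_wgd = 0.06,
                                 band = 16L, duplication_frac = 0.2) {
  anc <- simulate_ancestral_genome(sim_config(
    seed = seed, n_chromosomes_ancestral = n_chromosomes,
    genes_per_chromosome = genes_per_chromosome,
    gene_length_range = c(300L, 450L)))
  focal <- anc$genome
  rename <- function(g, sfx) {
    g$genes$gene_id <- paste0(g$genes$gene_id, sfx)
    names(g$seqs) <- paste0(names(g$seqs), sfx)
    g
  }
  cw <- diverge_genes(focal, anc$truth, d_speciation, "speciation")
  cw <- apply_wgd(cw$genome, cw$truth, d_wgd, event = "4R")
  cw$genome <- rename(cw$genome, "_w")
  cf <- diverge_genes(focal, anc$truth, d_speciation, "speciation")
  cf$genome <- rename(cf$genome, "_f")
  ow <- rbh_with_coverage(focal$seqs, cw$genome$seqs, band = band)
  of <- rbh_with_coverage(focal$seqs, cf$genome$seqs, band = band)
  anchors <- data.frame(scaffold = unique(focal$genes$chrom),
                        lg = unique(focal$genes$chrom))
  tlg <- anchor_transcripts(transcript_locations(focal), anchors)
  mw <- build_synteny_matrix(ow, tlg, transcript_locations(cw$genome))
  mf <- build_synteny_matrix(of, tlg, transcript_locations(cf$genome))
  patt <- classify_patterns(list(wgd = mw, flat = mf),
                            duplication_frac = duplication_frac)
  dup <- patt$duplication
  list(n_lg = n_chromosomes,
       wgd_two_dominant = sum(dup$n_dominant == 2 &
                                dup$comparator == "wgd"),
       flat_one_dominant = sum(dup$n_dominant == 1 &
                                 dup$comparator == "flat"),
       patterns = patt,
       matrices = list(wgd = mw, flat = mf))
}

#' Fission / fusion recovery study
#'
#' Injects one focal-lineage fission and one comparator-lineage fusion
#' into a simulated clade of three species and checks that
#' [classify_patterns()] recovers exactly those two events.
#'
#' @param seed integer seed.
#' @param n_chromosomes,genes_per_chromosome ancestral karyotype size.
#' @param d_speciation lineage divergence.
#' @param band aligner band half-width.
#' @return list: \code{fissions}, \code{fusions} (the call tables),
#'   \code{fission_correct}, \code{fusion_correct}, \code{false_calls}.
#' @export
scenario_fission_fusion <- function(seed, n_chromosomes = 8L,
                                    genes_per_chromosome = 12L,
                                    d_speciation = 0.05, band = 16L) {
  anc <- simulate_ancestral_genome(sim_config(
    seed = seed, n_chromosomes_ancestral = n_chromosomes,
    genes_per_chromosome = genes_per_chromosome,
    gene_length_range = c(300L, 450L)))
  fis <- apply_rearrangement(anc$genome, anc$truth,
                             list(type = "fission", chrom = "chr01",
                                  after_gene = genes_per_chromosome %/% 2))
  focal <- fis$genome
  rename <- function(g, sfx) {
    g$genes$gene_id <- paste0(g$genes$gene_id, sfx)
    names(g$seqs) <- paste0(names(g$seqs), sfx)
    g
  }
  c1 <- diverge_genes(anc$genome, anc$truth, d_speciation, "speciation")
  c1 <- apply_rearrangement(c1$genome, c1$truth,
                            list(type = "fusion", chrom_a = "chr02",
                                 chrom_b = "chr03"))
  c1$genome <- rename(c1$genome, "_1")
  c2 <- diverge_genes(anc$genome, anc$truth, d_speciation, "speciation")
  c2$genome <- rename(c2$genome, "_2")
  o1 <- rbh_with_coverage(focal$seqs, c1$genome$seqs, band = band)
  o2 <- rbh_with_coverage(focal$seqs, c2$genome$seqs, band = band)
  anchors <- data.frame(scaffold = unique(focal$genes$chrom),
                        lg = unique(focal$genes$chrom))
  tlg <- anchor_transcripts(transcript_locations(focal), anchors)
  m1 <- build_synteny_matrix(o1, tlg, transcript_locations(c1$genome))
  m2 <- build_synteny_matrix(o2, tlg, transcript_locations(c2$genome))
  patt <- classify_patterns(list(c1 = m1, c2 = m2))
  fission_correct <- nrow(patt$fissions) == 1 &&
    setequal(c(patt$fissions$lg_a, patt$fissions$lg_b),
             c("chr01p", "chr01q"))
  fusion_correct <- nrow(patt$fusions) == 1 &&
    patt$fusions$comparator == "c1" &&
    setequal(strsplit(patt$fusions$lgs, ",")[[1]], c("chr02", "chr03"))
  false_calls <- max(0, nrow(patt$fissions) - 1) +
    max(0, nrow(patt$fusions) - 1)
  list(fissions = patt$fissions, fusions = patt$fusions,
       fission_correct = fission_correct,
       fusion_correct = fusion_correct,
       false_calls = false_calls)
}

#' Chimeric-scaffold diagnosis study
#'
#' Builds a simulated assembly containing one genuine chromosomal
#' translocation whose breakpoint falls in the middle of a scaffold
#' (flanked by scaffolds matching each half) and two injected chimeric
#' scaffolds, then diagnoses every scaffold against an unrearranged
#' comparator lineage.
#'
#' @param seed integer seed.
#' @param band aligner band half-width.
#' @return list: \code{diagnosis} (table for all scaffolds),
#'   \code{translocated_scaffold}, \code{translocation_called},
#'   \code{chimeras_truth}, \code{chimeras_flagged},
#'   \code{false_flags} (single-origin scaffolds not called consistent).
#' @export
scenario_chimera_diagnosis <- function(seed, band = 16L) {
  gpc <- 36L
  anc <- simulate_ancestral_genome(sim_config(
    seed = seed, n_chromosomes_ancestral = 6L,
    genes_per_chromosome = gpc, gene_length_range = c(300L, 420L)))
  # genuine translocation: final 12-gene block of chr02 moves to chr01
  rr <- apply_rearrangement(anc$genome, anc$truth,
                            list(type = "translocation", from = "chr02",
                                 genes = 25:36, to = "chr01"))
  focal <- rr$genome
  moved_ids <- anc$genome$genes$gene_id[anc$genome$genes$chrom ==
    "chr02"][25:36]
  # deterministic cuts on chr01 so one scaffold straddles the breakpoint
  fr <- fragment_into_scaffolds(focal, rr$truth, scaffold_n = 40L,
                                chimera_inject = TRUE, n_chimeras = 2L,
                                cuts = list(chr01 = c(6L, 12L, 18L, 24L,
                                                      30L, 42L)),
                                chimera_exclude_lg = "chr01")
  cmp <- diverge_genes(anc$genome, anc$truth, 0.05, "speciation")
  cmp$genome$genes$gene_id <- paste0(cmp$genome$genes$gene_id, "_c")
  names(cmp$genome$seqs) <- paste0(names(cmp$genome$seqs), "_c")
  ow <- rbh_with_coverage(focal$seqs, cmp$genome$seqs, band = band)
  scf <- fr$scaffolds
  comp_loc <- transcript_locations(cmp$genome)
  ortho <- data.frame(
    scaffold = setNames(scf$scaffold, scf$gene_id)[ow$id_a],
    pos = point_position(setNames(scf$start, scf$gene_id)[ow$id_a],
                         setNames(scf$end, scf$gene_id)[ow$id_a]),
    comparator = "cmp",
    chrom = setNames(comp_loc$chrom_or_scaffold,
                     comp_loc$id)[ow$id_b],
    stringsAsFactors = FALSE)
  ortho$lg <- setNames(fr$anchors$lg, fr$anchors$scaffold)[ortho$scaffold]
  diag <- diagnose_lg_scaffolds(ortho, fr$anchors)
  # ground truth bookkeeping
  origin_mix <- tapply(scf$gene_id %in% moved_ids, scf$scaffold,
                       function(x) any(x) && !all(x))
  straddling <- setdiff(names(origin_mix)[origin_mix],
                        fr$truth$chimeric_scaffolds)
  pure <- setdiff(unique(scf$scaffold),
                  c(straddling, fr$truth$chimeric_scaffolds))
  dg <- setNames(diag$verdict, diag$scaffold)
  list(diagnosis = diag,
       translocated_scaffold = straddling,
       translocation_called = length(straddling) == 1 &&
         identical(unname(dg[straddling]), "translocation"),
       chimeras_truth = fr$truth$chimeric_scaffolds,
       chimeras_flagged = sum(dg[fr$truth$chimeric_scaffolds] ==
                                "chimera_suspect", na.rm = TRUE),
       false_flags = sum(!is.na(dg[pure]) & dg[pure] != "consistent"))
}

#' Linkage-group recovery study
#'
#' Simulates the half-sib mapping design (two fathers, configurable
#' progeny counts), runs the missingness filter, all pairwise two-point
#' statistics and LOD grouping, and reports the recovered group count
#' against the simulated chromosome number.
#'
#' @param seed integer seed.
#' @param n_groups,markers_per_group,spacing_cM true map layout (the
#'   default spacing keeps the genome-wide map length near the
#'   1,289-cM scale typical of an esocid microsatellite map).
#' @param n_progeny progeny per father.
#' @param missing_rate MCAR missingness.
#' @param hom_fraction parental homozygosity rate (drives the mixture of
#'   single- and both-parent informative markers).
#' @param lod_form,lod_join grouping thresholds.
#' @return list: \code{n_groups_true}, \code{n_groups_recovered},
#'   \code{n_unlinked}, \code{groups}.
#' @export
scenario_linkage_groups <- function(seed, n_groups = 25L,
                                    markers_per_group = 20L,
                                    spacing_cM = 2.7,
                                    n_progeny = c(48L, 44L),
                                    missing_rate = 0.05,
                                    hom_fraction = 0.3,
                                    lod_form = 4.0, lod_join = 3.0) {
  set.seed(seed)
  fmap <- make_marker_map(n_groups, markers_per_group, spacing_cM)
  parents <- simulate_parent_genotypes(fmap,
                                       hom_fraction = hom_fraction)
  fam <- simulate_half_sib_family(fmap, fmap, parents,
                                  n_progeny = n_progeny,
                                  missing_rate = missing_rate)
  fam <- missing_filter(fam)
  st <- suppressWarnings(pair_stats(fam))
  gr <- group_markers(st, lod_form, lod_join)
  list(n_groups_true = n_groups,
       n_groups_recovered = length(gr$groups),
       n_unlinked = length(gr$unlinked_combined),
       groups = gr$groups)
}

#' Linkage map order and length recovery study
#'
#' At a larger progeny count, checks per-group marker order against the
#' simulated order (up to reversal), the total map length against the
#' simulated truth, and — when \code{female_scale != 1} — recovery of the
#' female:male recombination-rate ratio.
#'
#' @inheritParams scenario_linkage_groups
#' @param female_scale factor applied to the female map's cM positions.
#' @param map_function see [map_distance()].
#' @return list: \code{order_recovered}, \code{n_groups_ordered},
#'   \code{order_recovered_correct_groups} / \code{n_correct_groups}
#'   (the same restricted to groups drawn from a single true chromosome,
#'   i.e. ordering accuracy uncontaminated by chance between-group
#'   joins), \code{adjacent_agreement} (fraction of truth-adjacent marker
#'   pairs adjacent and ordered consistently in the estimate),
#'   \code{map_total_cM}, \code{truth_total_cM}, \code{length_rel_error},
#'   \code{ratio} (NA unless \code{female_scale != 1}).
#' @export
scenario_linkage_map <- function(seed, n_groups = 25L,
                                 markers_per_group = 20L,
                                 spacing_cM = 2.7,
                                 n_progeny = c(250L, 250L),
                                 missing_rate = 0.05,
                                 female_scale = 1,
                                 map_function = "kosambi") {
  set.seed(seed)
  fmap <- make_marker_map(n_groups, markers_per_group, spacing_cM)
  fmap_f <- fmap
  fmap_f$pos_cM <- fmap$pos_cM * female_scale
  parents <- simulate_parent_genotypes(fmap, hom_fraction = 0)
  fam <- simulate_half_sib_family(fmap_f, fmap, parents,
                                  n_progeny = n_progeny,
                                  missing_rate = missing_rate)
  st <- suppressWarnings(pair_stats(fam))
  # sex-specific maps are built from each parent's own linkage groups
  # (build_map groups on the parent's statistics when none are given)
  mp <- build_map(st$mother, map_function = map_function,
                  sex = "female")
  ok <- 0L; agree_num <- 0L; agree_den <- 0L
  ok_correct <- 0L; n_correct <- 0L
  true_sets <- split(fmap$marker, fmap$lg)
  for (g in names(mp)) {
    mk <- mp[[g]]$marker
    tr <- fmap[fmap$marker %in% mk, ]
    tr <- tr[order(tr$pos_cM), ]
    recovered <- identical(mk, tr$marker) || identical(mk, rev(tr$marker))
    if (recovered) ok <- ok + 1L
    # groups whose markers all come from one true chromosome measure
    # ordering alone, uncontaminated by chance between-group joins
    if (any(vapply(true_sets, function(s) all(mk %in% s), logical(1)))) {
      n_correct <- n_correct + 1L
      if (recovered) ok_correct <- ok_correct + 1L
    }
    est_rank <- match(tr$marker, mk)
    d <- diff(est_rank)
    agree_num <- agree_num + max(sum(d == 1), sum(d == -1))
    agree_den <- agree_den + length(d)
  }
  truth_total <- sum(tapply(fmap_f$pos_cM, fmap_f$lg, max)) *
    ifelse(female_scale != 1, 1, 1)
  total <- attr(mp, "total_cM")
  ratio <- NA_real_
  if (female_scale != 1) {
    m1 <- build_map(st$father1, map_function = map_function,
                    sex = "male")
    m2 <- build_map(st$father2, map_function = map_function,
                    sex = "male")
    mmale <- merge_maps(m1, m2)$merged
    # rate comparison is made over groups drawn from a single true
    # chromosome: a chance between-chromosome join would otherwise add a
    # near-0.5 junction interval (> 100 cM) to the other parent's map
    clean <- names(mp)[vapply(names(mp), function(g)
      any(vapply(true_sets, function(s) all(mp[[g]]$marker %in% s),
                 logical(1))), logical(1))]
    clean <- intersect(clean, names(mmale))
    keep <- function(m, gs) structure(m[gs], class = "linkage_map",
                                      sex = attr(m, "sex"))
    ratio <- map_stats(keep(mp, clean), keep(mmale, clean))$ratio
  }
  list(order_recovered = ok, n_groups_ordered = length(mp),
       order_recovered_correct_groups = ok_correct,
       n_correct_groups = n_correct,
       adjacent_agreement = agree_num / agree_den,
       map_total_cM = total, truth_total_cM = truth_total,
       length_rel_error = (total - truth_total) / truth_total,
       ratio = ratio)
}
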