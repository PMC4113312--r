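# End-to-end pipeline orchestration and printed-arithmetic verification.

#' Default pipeline configuration
#'
#' Stage parameters default to the analysis settings used throughout the
#' package: 100-column minimum alignments, 50% two-sided RBH coverage,
#' 98%/300 bp redundancy collapse, 1% identity bins with the 77-89 band
#' and >97 recent cutoff, LOD 4.0 formation / 3.0 joining, 15% missingness
#' filter and the 3-SD specialization rule.
#'
#' @param seed integer seed for the simulation stages.
#' @param outdir output directory for stage artifacts.
#' @return nested configuration list.
#' @export
default_run_config <- function(seed = 1L, outdir = tempfile("esoxrun")) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    simulate = list(n_chromosomes = 6L, genes_per_chromosome = 8L,
                    gene_length_range = c(300L, 500L),
                    divergence_speciation = 0.05,
                    divergence_wgd = 0.06,
                    n_markers_per_group = 6L, marker_spacing_cM = 8,
                    n_progeny = c(48L, 44L), missing_rate = 0.05,
                    n_transcripts_expression = 200L, n_tissues = 13L,
                    n_specialized_per_tissue = 5L),
    homology = list(min_aligned = 100L, min_score = 40L, min_cov = 0.5,
                    band = 32L),
    dupprofile = list(window = 3L, min_prominence_frac = 0.05,
                      recent_min = 97, band_lo = 77, band_hi = 89),
    synteny = list(display_min = 3L, dominance_frac = 0.5,
                   duplication_frac = 0.2),
    linkage = list(lod_form = 4.0, lod_join = 3.0, max_missing = 0.15,
                   map_function = "kosambi"),
    expression = list(k = 3)
  )
}

config_hash <- function(config) {
  config$outdir <- NULL  # output location is not analytic configuration
  s <- paste(deparse(config), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 997)) %% .Machine$integer.max)
}

check_config <- function(config, template = default_run_config()) {
  bad <- setdiff(names(config), names(template))
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (nm in names(config)) {
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]]))) {
      badk <- setdiff(names(config[[nm]]), names(template[[nm]]))
      if (length(badk) > 0)
        stop("unknown config key(s) in ", nm, ": ",
             paste(badk, collapse = ", "))
    }
  }
  invisible(TRUE)
}

merge_config <- function(config) {
  template <- default_run_config(seed = config$seed %||% 1L,
                                 outdir = config$outdir %||%
                                   tempfile("esoxrun"))
  check_config(config, template)
  for (nm in names(config)) {
    if (is.list(template[[nm]]) && is.list(config[[nm]])) {
      for (k in names(config[[nm]]))
        template[[nm]][[k]] <- config[[nm]][[k]]
    } else template[[nm]] <- config[[nm]]
  }
  template
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full simulated-study pipeline
#'
#' Simulates a focal (pre-duplication) genome plus two comparator
#' lineages (one with an extra WGD, one without), a half-sib mapping
#' family, and a tissue expression panel; then runs homologue detection,
#' the duplication profile, synteny classification, linkage mapping and
#' expression specialization, writing each stage's tables under
#' \code{config$outdir} with provenance headers.
#'
#' @param config a (possibly partial) configuration; see
#'   [default_run_config()]. Unknown keys are rejected before any stage
#'   runs.
#' @return list of stage summaries (also serialized to
#'   \code{summary.json} in the output directory).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- merge_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  prov <- c(paste("tool: esoxsynt", as.character(
              utils::packageVersion("esoxsynt"))),
            paste("config_hash:", config_hash(cfg)),
            paste("seed:", cfg$seed))
  out <- function(...) file.path(cfg$outdir, paste0(...))
  sim <- cfg$simulate
  set.seed(cfg$seed)

  ## stage 1: simulate -----------------------------------------------
  anc <- simulate_ancestral_genome(sim_config(
    seed = cfg$seed, n_chromosomes_ancestral = sim$n_chromosomes,
    genes_per_chromosome = sim$genes_per_chromosome,
    gene_length_range = sim$gene_length_range))
  focal <- anc$genome; focal_truth <- anc$truth
  cmp_wgd <- diverge_genes(focal, focal_truth,
                           sim$divergence_speciation, "speciation")
  cmp_wgd <- apply_wgd(cmp_wgd$genome, cmp_wgd$truth,
                       sim$divergence_wgd, event = "4R")
  cmp_flat <- diverge_genes(focal, focal_truth,
                            sim$divergence_speciation, "speciation")
  # comparator gene ids must not collide with focal ids
  rename_genome <- function(g, suffix) {
    g$genes$gene_id <- paste0(g$genes$gene_id, suffix)
    names(g$seqs) <- paste0(names(g$seqs), suffix)
    g
  }
  cmp_wgd$genome <- rename_genome(cmp_wgd$genome, "_w")
  cmp_flat$genome <- rename_genome(cmp_flat$genome, "_f")
  write_fasta(focal$seqs, out("focal.fa"))
  write_fasta(cmp_wgd$genome$seqs, out("comparator_wgd.fa"))
  write_fasta(cmp_flat$genome$seqs, out("comparator_flat.fa"))
  write_tsv(transcript_locations(focal), out("focal_locations.tsv"), prov)
  # marker map + family
  fmap <- make_marker_map(sim$n_chromosomes, sim$n_markers_per_group,
                          sim$marker_spacing_cM)
  parents <- simulate_parent_genotypes(fmap)
  fam <- simulate_half_sib_family(fmap, fmap, parents,
                                  n_progeny = sim$n_progeny,
                                  missing_rate = sim$missing_rate)
  write_genotype_table(fam, out("genotypes.tsv"))
  expr <- simulate_expression(sim$n_transcripts_expression,
                              sim$n_tissues,
                              sim$n_specialized_per_tissue)
  write_tsv(data.frame(transcript = rownames(expr$counts),
                       expr$counts), out("counts.tsv"), prov)

  ## stage 2: homology ------------------------------------------------
  hom <- cfg$homology
  paralogues <- reciprocal_best_hits(focal$seqs,
                                     min_aligned = hom$min_aligned,
                                     min_score = hom$min_score,
                                     band = hom$band)
  ortho_wgd <- rbh_with_coverage(focal$seqs, cmp_wgd$genome$seqs,
                                 min_cov = hom$min_cov,
                                 min_aligned = hom$min_aligned,
                                 min_score = hom$min_score,
                                 band = hom$band)
  ortho_flat <- rbh_with_coverage(focal$seqs, cmp_flat$genome$seqs,
                                  min_cov = hom$min_cov,
                                  min_aligned = hom$min_aligned,
                                  min_score = hom$min_score,
                                  band = hom$band)
  write_tsv(paralogues, out("paralogue_pairs.tsv"), prov)
  write_tsv(ortho_wgd, out("orthologue_pairs_wgd.tsv"), prov)

  ## stage 3: duplication profile --------------------------------------
  dp <- cfg$dupprofile
  hist_orth <- similarity_histogram(ortho_wgd)
  peaks_orth <- detect_peaks(hist_orth, dp$window,
                             dp$min_prominence_frac)
  write_tsv(hist_orth, out("orthologue_identity_histogram.tsv"), prov)

  ## stage 4: synteny ---------------------------------------------------
  sy <- cfg$synteny
  # focal chromosomes double as anchored linkage groups here
  anchors <- data.frame(scaffold = unique(focal$genes$chrom),
                        lg = unique(focal$genes$chrom))
  tlg <- anchor_transcripts(transcript_locations(focal), anchors)
  m_wgd <- build_synteny_matrix(ortho_wgd, tlg,
                                transcript_locations(cmp_wgd$genome),
                                sy$display_min)
  m_flat <- build_synteny_matrix(ortho_flat, tlg,
                                 transcript_locations(cmp_flat$genome),
                                 sy$display_min)
  patt <- classify_patterns(list(wgd = m_wgd, flat = m_flat),
                            sy$dominance_frac, sy$duplication_frac)
  write_tsv(as.data.frame(masked_counts(m_wgd)),
            out("synteny_matrix_wgd_masked.tsv"), prov)
  write_tsv(patt$duplication, out("synteny_duplication_calls.tsv"), prov)

  ## stage 5: linkage ---------------------------------------------------
  lk <- cfg$linkage
  fam_f <- missing_filter(fam, lk$max_missing)
  st <- pair_stats(fam_f)
  grp <- group_markers(st, lk$lod_form, lk$lod_join)
  map_female <- build_map(st$mother, grp$groups, lk$lod_form,
                          lk$lod_join, lk$map_function, sex = "female")
  map_m1 <- build_map(st$father1, grp$groups, lk$lod_form, lk$lod_join,
                      lk$map_function, sex = "male")
  map_m2 <- build_map(st$father2, grp$groups, lk$lod_form, lk$lod_join,
                      lk$map_function, sex = "male")
  map_male <- merge_maps(map_m1, map_m2)$merged
  attr(map_male, "sex") <- "male"
  merged <- merge_maps(map_female, map_male)
  mstats <- map_stats(map_female, map_male, merged$merged)
  write_mapchart(merged$merged, out("merged_map.txt"))

  ## stage 6: expression ------------------------------------------------
  fp <- fpkm(expr$counts, expr$lengths)
  spec <- specialized_calls(fp, k = cfg$expression$k)
  write_tsv(spec$per_tissue, out("specialized_per_tissue.tsv"), prov)

  summary <- list(
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    n_focal_transcripts = length(focal$seqs),
    n_paralogue_pairs = nrow(paralogues),
    n_orthologue_pairs_wgd = nrow(ortho_wgd),
    orthologue_peaks = peaks_orth$bin,
    n_linkage_groups = length(grp$groups),
    wgd_two_dominant_rows = sum(patt$duplication$duplication_signature[
      patt$duplication$comparator == "wgd"]),
    map_totals = as.list(mstats$totals),
    female_male_ratio = mstats$ratio,
    specialized_counts = setNames(spec$per_tissue$n_specialized,
                                  spec$per_tissue$tissue))
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(summary)
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Recompute a panel of published derived quantities
#'
#' Reads the shipped table of printed input constants (assembly sizes,
#' marker screening counts, map spans) and recomputes each derived
#' quantity from its inputs, comparing with the reported value at the
#' reported precision (half-up rounding).
#'
#' @return data.frame with columns \code{quantity}, \code{computed},
#'   \code{reported}, \code{pass}.
#' @export
worked_examples <- function() {
  path <- system.file("extdata", "reported_values.tsv",
                      package = "esoxsynt")
  tab <- read_tsv(path)
  compute <- function(op, a, b, c_) {
    switch(op,
           divide_int = round_half_up(a / b, 0),
           pct_1dp = round_half_up(100 * a / b, 1),
           pct_int = round_half_up(100 * a / b, 0),
           sum = a + b,
           sum_minus = a - b - c_,
           ratio_2dp = round_half_up(a / b, 2),
           stop("unknown op: ", op))
  }
  tab$computed <- vapply(seq_len(nrow(tab)), function(i)
    compute(tab$op[i], tab$input_a[i], tab$input_b[i], tab$input_c[i]),
    numeric(1))
  tab$pass <- tab$computed == tab$reported
  tab[, c("quantity", "input_a", "input_b", "input_c", "computed",
          "reported", "pass")]
}
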