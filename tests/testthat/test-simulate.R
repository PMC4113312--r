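test_that("ancestral genome respects configured counts and determinism", {
  cfg <- sim_config(seed = 31, n_chromosomes_ancestral = 24,
                    genes_per_chromosome = 10)
  g <- simulate_ancestral_genome(cfg)
  expect_equal(nrow(g$genome$genes), 240)
  expect_equal(length(unique(g$genome$genes$chrom)), 24)
  expect_equal(length(g$genome$seqs), 240)
  # non-overlapping genes per chromosome
  by_chr <- split(g$genome$genes, g$genome$genes$chrom)
  for (d in by_chr) {
    d <- d[order(d$start), ]
    expect_true(all(d$start[-1] >= head(d$end, -1)))
  }
  # byte-identical FASTA under the same seed
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(simulate_ancestral_genome(cfg)$genome$seqs, f1)
  write_fasta(simulate_ancestral_genome(cfg)$genome$seqs, f2)
  expect_identical(readLines(f1), readLines(f2))

  one <- simulate_ancestral_genome(sim_config(
    seed = 1, n_chromosomes_ancestral = 1, genes_per_chromosome = 1,
    gene_length_range = c(300, 300)))
  expect_equal(nchar(one$genome$seqs[[1]]), 300)
  expect_error(simulate_ancestral_genome(cfg, chromosome_length = 1000),
               "exceeds")
})

test_that("config validation rejects out-of-range fractions", {
  expect_error(sim_config(missing_rate = 1.2), "fraction")
  expect_error(sim_config(n_chromosomes_ancestral = 0), ">= 1")
})

test_that("WGD doubles the genome and fixes pair identity exactly", {
  cfg <- sim_config(seed = 32, n_chromosomes_ancestral = 3,
                    genes_per_chromosome = 5)
  g <- simulate_ancestral_genome(cfg)
  w <- apply_wgd(g$genome, g$truth, 0.18, event = "3R")
  expect_equal(nrow(w$genome$genes), 30)
  expect_equal(length(unique(w$genome$genes$chrom)), 6)
  for (id in g$genome$genes$gene_id) {
    s1 <- strsplit(w$genome$seqs[[id]], "")[[1]]
    s2 <- strsplit(w$genome$seqs[[paste0(id, "d")]], "")[[1]]
    L <- length(s1)
    expect_equal(sum(s1 != s2), round(0.18 * L))
  }
  # d = 0: identical copies
  w0 <- apply_wgd(g$genome, g$truth, 0, event = "recent")
  id <- g$genome$genes$gene_id[1]
  expect_identical(w0$genome$seqs[[id]], w0$genome$seqs[[paste0(id, "d")]])
  # two successive rounds: four copies per ancestral gene
  w2 <- apply_wgd(w$genome, w$truth, 0.06, event = "4R")
  anc <- w2$truth$ancestry
  expect_equal(nrow(w2$genome$genes), 60)
  expect_true(all(table(anc$ancestor_id) == 4))
  expect_setequal(unique(anc$event), c("none", "3R", "4R"))
  # loss removes duplicate copies only
  wl <- apply_wgd(g$genome, g$truth, 0.1, event = "4R",
                  loss_fraction = 0.4)
  expect_equal(nrow(wl$genome$genes), 30 - round(0.4 * 15))
})

test_that("rearrangements conserve gene content", {
  cfg <- sim_config(seed = 33, n_chromosomes_ancestral = 3,
                    genes_per_chromosome = 8)
  g <- simulate_ancestral_genome(cfg)
  ids <- sort(g$genome$genes$gene_id)

  fis <- apply_rearrangement(g$genome, g$truth,
                             list(type = "fission", chrom = "chr01",
                                  after_gene = 4))
  expect_equal(length(unique(fis$genome$genes$chrom)), 4)
  got <- split(fis$genome$genes$gene_id, fis$genome$genes$chrom)
  expect_setequal(c(got$chr01p, got$chr01q),
                  g$genome$genes$gene_id[g$genome$genes$chrom == "chr01"])
  expect_equal(length(got$chr01p), 4)
  expect_error(apply_rearrangement(g$genome, g$truth,
                                   list(type = "fission", chrom = "chr01",
                                        after_gene = 4.5)),
               "between genes")

  fus <- apply_rearrangement(g$genome, g$truth,
                             list(type = "fusion", chrom_a = "chr02",
                                  chrom_b = "chr03"))
  expect_equal(length(unique(fus$genome$genes$chrom)), 2)
  expect_equal(sum(fus$genome$genes$chrom == "chr02+chr03"), 16)

  tra <- apply_rearrangement(g$genome, g$truth,
                             list(type = "translocation", from = "chr01",
                                  genes = 6:8, to = "chr02"))
  expect_equal(sum(tra$genome$genes$chrom == "chr01"), 5)
  expect_equal(sum(tra$genome$genes$chrom == "chr02"), 11)
  expect_setequal(sort(tra$genome$genes$gene_id), ids)
})

test_that("scaffold fragmentation conserves genes and flags chimeras", {
  cfg <- sim_config(seed = 34, n_chromosomes_ancestral = 4,
                    genes_per_chromosome = 10)
  g <- simulate_ancestral_genome(cfg)
  fr <- fragment_into_scaffolds(g$genome, g$truth, scaffold_n = 12)
  expect_equal(length(unique(fr$scaffolds$scaffold)), 12)
  expect_setequal(fr$scaffolds$gene_id, g$genome$genes$gene_id)
  expect_length(fr$truth$chimeric_scaffolds, 0)
  # without injection every scaffold is single-origin
  origin <- setNames(g$genome$genes$chrom, g$genome$genes$gene_id)
  per_scf <- tapply(origin[fr$scaffolds$gene_id], fr$scaffolds$scaffold,
                    function(x) length(unique(x)))
  expect_true(all(per_scf == 1))

  frc <- fragment_into_scaffolds(g$genome, g$truth, scaffold_n = 12,
                                 chimera_inject = TRUE, n_chimeras = 2)
  expect_equal(length(frc$truth$chimeric_scaffolds), 2)
  expect_equal(length(unique(frc$scaffolds$scaffold)), 12)
  expect_setequal(frc$scaffolds$gene_id, g$genome$genes$gene_id)
  per_scf <- tapply(origin[frc$scaffolds$gene_id], frc$scaffolds$scaffold,
                    function(x) length(unique(x)))
  expect_true(all(per_scf[frc$truth$chimeric_scaffolds] == 2))
})

test_that("meiosis follows the inverse Haldane recombination model", {
  set.seed(35)
  fmap0 <- data.frame(marker = c("A", "B"), lg = "LG1", pos_cM = c(5, 5))
  parents <- data.frame(marker = c("A", "B"), mother = "101/103",
                        father1 = "105/105", stringsAsFactors = FALSE)
  fam0 <- simulate_half_sib_family(fmap0, fmap0, parents,
                                   n_progeny = 1000, missing_rate = 0)
  st0 <- pair_stats(fam0, "mother")
  expect_equal(st0$mother$r["A", "B"], 0)

  fmap10 <- data.frame(marker = c("A", "B"), lg = "LG1",
                       pos_cM = c(0, 10))
  fam10 <- simulate_half_sib_family(fmap10, fmap10, parents,
                                    n_progeny = 10000, missing_rate = 0)
  st10 <- pair_stats(fam10, "mother")
  r_expected <- 0.5 * (1 - exp(-0.2))
  expect_lt(abs(st10$mother$r_hat["A", "B"] - r_expected), 0.01)

  expect_false(any(as.matrix(fam10[, names(attr(fam10,
    "progeny_father"))]) == "-"))
  expect_error(simulate_half_sib_family(
    data.frame(marker = c("A", "B"), lg = "LG1", pos_cM = c(10, 0)),
    parents = parents, n_progeny = 10), "negative cM")
})

test_that("expression generator plants recoverable specializations", {
  set.seed(36)
  e0 <- simulate_expression(50, 13, n_specialized_per_tissue = 0)
  expect_equal(nrow(e0$truth), 0)
  expect_true(all(rowSums(e0$counts) > 0))

  e1 <- simulate_expression(130, 13, n_specialized_per_tissue = 2,
                            boost = 100)
  fp <- fpkm(e1$counts, e1$lengths)
  calls <- specialized_calls(fp)
  planted <- paste(e1$truth$transcript, e1$truth$tissue)
  found <- paste(calls$pairs$transcript, calls$pairs$tissue)
  expect_true(all(planted %in% found))

  expect_error(simulate_expression(10, 13, n_specialized_per_tissue = 2),
               "exceeds")
})

test_that("genotype tables round-trip through the TSV format", {
  set.seed(37)
  fmap <- make_marker_map(2, 4, 10)
  parents <- simulate_parent_genotypes(fmap)
  fam <- simulate_half_sib_family(fmap, fmap, parents,
                                  n_progeny = c(6, 5),
                                  missing_rate = 0.1)
  path <- tempfile(fileext = ".tsv")
  write_genotype_table(fam, path)
  back <- read_genotype_table(path)
  expect_equal(as.data.frame(back), as.data.frame(fam),
               ignore_attr = TRUE)
  expect_equal(attr(back, "progeny_father"),
               attr(fam, "progeny_father"))
})
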