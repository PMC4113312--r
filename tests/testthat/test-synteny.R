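make_matrix <- function(cells, lgs, chroms) {
  # cells: data.frame(lg, chrom, n) expanded into a synteny_matrix
  pairs <- do.call(rbind, lapply(seq_len(nrow(cells)), function(k) {
    n <- cells$n[k]
    data.frame(id_a = sprintf("%s_%s_%d", cells$lg[k], cells$chrom[k],
                              seq_len(n)),
               id_b = sprintf("x_%s_%s_%d", cells$lg[k], cells$chrom[k],
                              seq_len(n)))
  }))
  tlg <- data.frame(id = pairs$id_a, lg = sub("_.*", "", pairs$id_a))
  comp <- data.frame(id = pairs$id_b,
                     chrom_or_scaffold = sub("^x_[^_]+_([^_]+)_.*", "\\1",
                                             pairs$id_b),
                     start = 0, end = 100)
  m <- build_synteny_matrix(pairs, tlg, comp)
  # pad to the full lg/chrom universe
  full <- matrix(0L, length(lgs), length(chroms),
                 dimnames = list(lgs, chroms))
  full[rownames(m$counts), colnames(m$counts)] <- m$counts
  m$counts <- full
  m
}

test_that("point position is the midpoint", {
  expect_equal(point_position(100, 300), 200)
  expect_equal(point_position(0, 0), 0)
  expect_equal(point_position(5, 6), 5.5)
  expect_error(point_position(10, 5), "start > end")
})

test_that("transcripts inherit linkage groups through anchors", {
  loc <- data.frame(id = c("t1", "t2", "t3"),
                    chrom_or_scaffold = c("s1", "s1", "s9"),
                    start = c(0, 100, 0), end = c(50, 200, 80))
  anchors <- data.frame(scaffold = "s1", lg = "LG-03")
  expect_warning(res <- anchor_transcripts(loc, anchors), "unanchored")
  expect_equal(res$lg, c("LG-03", "LG-03"))
  expect_equal(attr(res, "n_excluded"), 1)
})

test_that("synteny matrix keeps full counts and masks only the export", {
  m <- make_matrix(data.frame(lg = c("LG1", "LG1"),
                              chrom = c("chrA", "chrB"), n = c(5, 2)),
                   "LG1", c("chrA", "chrB"))
  expect_equal(m$counts["LG1", "chrA"], 5)
  expect_equal(m$counts["LG1", "chrB"], 2)     # retained internally
  expect_equal(masked_counts(m)["LG1", "chrB"], 0)  # masked for display
  expect_equal(dominant_chromosomes(m)$LG1, "chrA")
})

test_that("dominance ties report all tied chromosomes", {
  m <- make_matrix(data.frame(lg = c("LG1", "LG1"),
                              chrom = c("chrA", "chrB"), n = c(4, 4)),
                   "LG1", c("chrA", "chrB"))
  expect_setequal(dominant_chromosomes(m)$LG1, c("chrA", "chrB"))
})

test_that("classify_patterns separates focal fissions from
           comparator-specific fusions", {
  lgs <- c("LG-09", "LG-25", "LG-01", "LG-02")
  base <- data.frame(lg = c("LG-01", "LG-02"),
                     chrom = c("c1", "c2"), n = c(10, 10))
  # LG-09 and LG-25 share chrIX in all three comparators -> fission
  fis <- data.frame(lg = c("LG-09", "LG-25"), chrom = "chrIX",
                    n = c(12, 9))
  m1 <- make_matrix(rbind(base, fis), lgs, c("c1", "c2", "chrIX"))
  m2 <- make_matrix(rbind(base, fis), lgs, c("c1", "c2", "chrIX"))
  m3 <- make_matrix(rbind(base, fis), lgs, c("c1", "c2", "chrIX"))
  patt <- classify_patterns(list(a = m1, b = m2, c = m3))
  expect_equal(nrow(patt$fissions), 1)
  expect_setequal(c(patt$fissions$lg_a, patt$fissions$lg_b),
                  c("LG-09", "LG-25"))
  expect_equal(nrow(patt$fusions), 0)

  # chrI absorbs LG-01 and LG-02 in comparator 1 only -> fusion there
  fus1 <- data.frame(lg = c("LG-01", "LG-02", "LG-09", "LG-25"),
                     chrom = c("chrI", "chrI", "c3", "c4"),
                     n = c(10, 10, 10, 10))
  flat <- data.frame(lg = c("LG-01", "LG-02", "LG-09", "LG-25"),
                     chrom = c("c1", "c2", "c3", "c4"),
                     n = c(10, 10, 10, 10))
  chr_all <- c("chrI", "c1", "c2", "c3", "c4")
  n1 <- make_matrix(fus1, lgs, chr_all)
  n2 <- make_matrix(flat, lgs, chr_all)
  patt2 <- classify_patterns(list(a = n1, b = n2))
  expect_equal(patt2$fusions$comparator, "a")
  expect_setequal(strsplit(patt2$fusions$lgs, ",")[[1]],
                  c("LG-01", "LG-02"))
  expect_equal(nrow(patt2$fissions), 0)

  expect_error(classify_patterns(list(a = m1)), "at least 2")
})

test_that("scaffold diagnosis distinguishes consistent, translocated and
           chimeric scaffolds", {
  # all hits on one chromosome -> consistent
  h1 <- data.frame(comparator = "g", pos = seq(100, 1000, 100),
                   chrom = "chrV")
  d1 <- diagnose_scaffold(h1)
  expect_equal(d1$verdict, "consistent")

  # scaffold-9-like: first half chrV, second half chrVI, flanks agree
  h2 <- data.frame(comparator = "g", pos = seq(100, 1200, 100),
                   chrom = rep(c("chrV", "chrVI"), each = 6))
  fl2 <- data.frame(comparator = "g", left = "chrV", right = "chrVI")
  d2 <- diagnose_scaffold(h2, flanks = fl2)
  expect_equal(d2$verdict, "translocation")
  expect_equal(d2$halves, c("chrV", "chrVI"))
  expect_true(d2$breakpoint > 600 && d2$breakpoint < 700)

  # same split but flanks contradict the distal half -> chimera suspect
  fl3 <- data.frame(comparator = "g", left = "chrV", right = "chrV")
  d3 <- diagnose_scaffold(h2, flanks = fl3,
                          lg_chrom_sequence = rep("chrV", 6))
  expect_equal(d3$verdict, "chimera_suspect")

  # interleaved many-chromosome linkage group -> reorganized context
  d4 <- diagnose_scaffold(h2, flanks = fl3,
                          lg_chrom_sequence = rep(c("chrV", "chrW",
                                                    "chrX", "chrY"), 3))
  expect_equal(d4$verdict, "reorganized_context")

  # too few hits -> verdict withheld
  h5 <- data.frame(comparator = "g", pos = c(1, 2), chrom = "chrV")
  expect_true(is.na(diagnose_scaffold(h5)$verdict))
})

test_that("matrix totals equal the anchored pair count", {
  set.seed(51)
  m <- make_matrix(data.frame(lg = c("LG1", "LG2", "LG2"),
                              chrom = c("cA", "cA", "cB"),
                              n = c(7, 4, 6)),
                   c("LG1", "LG2"), c("cA", "cB"))
  expect_equal(sum(m$counts), 17)
  expect_equal(m$n_pairs, 17)
})
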