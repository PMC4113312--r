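test_that("best_hits enforces the alignment-length and score filters", {
  set.seed(21)
  core <- rand_seq(90)
  q <- c(q1 = core)
  s <- c(s1 = paste0(rand_seq(40), core, rand_seq(40)))
  # only a 90-column alignment is available -> absent at min_aligned = 100
  expect_equal(nrow(best_hits(q, s, min_aligned = 100, band = 0)), 0)
  expect_equal(best_hits(q, s, min_aligned = 80, band = 0)$sid, "s1")

  q2 <- c(q1 = rand_seq(200))
  s2 <- c(s1 = q2[[1]])
  bh <- best_hits(q2, s2)
  expect_equal(bh$sid, "s1")
  expect_equal(bh$pident, 100)
})

test_that("best_hits equals the exhaustive argmax oracle", {
  set.seed(22)
  bases <- lapply(1:10, function(i) rand_seq(150))
  subj <- setNames(vapply(bases, identity, ""), sprintf("s%02d", 1:10))
  qry <- setNames(vapply(bases, function(b) mutate_seq(b, sample(5:30, 1)),
                         ""), sprintf("q%02d", 1:10))
  mine <- best_hits(qry, subj, band = 0)
  oracle <- oracle_best_hits(qry, subj)
  expect_equal(mine[order(mine$qid), c("qid", "sid", "score")],
               oracle[order(oracle$qid), ], ignore_attr = TRUE)
})

test_that("reciprocity is required: a->b best but b->c best gives no pair
           for a", {
  set.seed(23)
  seg_ab <- rand_seq(120)
  seg_bc <- rand_seq(200)
  trio <- c(a = seg_ab,
            b = paste0(seg_ab, seg_bc),
            c = seg_bc)
  # within-set: a's best is b, but b's best is c (longer shared segment)
  rb <- reciprocal_best_hits(trio, band = 0)
  expect_false("a" %in% c(rb$id_a, rb$id_b))
  expect_equal(nrow(rb), 1)
  expect_equal(rb$id_a, "b")
  expect_equal(rb$id_b, "c")
  expect_equal(rb$relation, "within_species")
})

test_that("RBH equals the brute-force reciprocity oracle and is a
           partial matching", {
  set.seed(24)
  bases <- lapply(1:15, function(i) rand_seq(140))
  A <- setNames(vapply(bases, function(b) mutate_seq(b, sample(0:25, 1)),
                       ""), sprintf("a%02d", 1:15))
  B <- setNames(vapply(bases, function(b) mutate_seq(b, sample(0:25, 1)),
                       ""), sprintf("b%02d", 1:15))
  mine <- reciprocal_best_hits(A, B, band = 0)
  oracle <- oracle_rbh(A, B)
  expect_equal(mine[order(mine$id_a), c("id_a", "id_b")],
               setNames(oracle[order(oracle$qid), ], c("id_a", "id_b")),
               ignore_attr = TRUE)
  expect_false(anyDuplicated(mine$id_a) > 0)
  expect_false(anyDuplicated(mine$id_b) > 0)
})

test_that("coverage filter keeps full-length pairs, drops one-sided
           matches, and accumulates disjoint segments", {
  set.seed(25)
  full <- rand_seq(600)
  r1 <- rbh_with_coverage(c(q = full), c(s = full), band = 0)
  expect_equal(nrow(r1), 1)
  expect_equal(r1$qcov, 1)
  expect_equal(r1$scov, 1)

  # subject matches only ~40% of the query -> dropped at min_cov = 0.5
  part <- substr(full, 1, 240)
  r2 <- rbh_with_coverage(c(q = full), c(s = part), band = 0)
  expect_equal(nrow(r2), 0)

  # two disjoint 300 bp conserved segments in 1000 bp sequences: 60%
  # two-sided coverage via greedy non-overlapping HSP selection
  s1 <- rand_seq(300); s2 <- rand_seq(300)
  qa <- paste0(s1, rand_seq(400), s2)
  sb <- paste0(s1, rand_seq(400), s2)
  r3 <- rbh_with_coverage(c(q = qa), c(s = sb), band = 0)
  expect_equal(nrow(r3), 1)
  expect_gte(r3$qcov, 0.6)
  expect_gte(r3$scov, 0.6)
})

test_that("redundancy collapse matches the transitive-closure oracle and
           is idempotent", {
  set.seed(26)
  # duplicates collapse, sub-threshold pairs survive
  t1 <- rand_seq(400)
  two <- c(a = t1, b = t1)
  cr <- collapse_redundancy(two)
  expect_equal(length(cr$representatives), 1)

  t2 <- rand_seq(1000)
  t3 <- mutate_seq(t2, 30)  # 97% identity over 1000 nt: below threshold
  cr2 <- collapse_redundancy(c(a = t2, b = t3))
  expect_equal(length(cr2$representatives), 2)

  # 20 transcripts in known chained clusters
  seeds <- lapply(1:5, function(i) rand_seq(500))
  tx <- list()
  for (i in seq_along(seeds)) {
    tx[[sprintf("c%d_1", i)]] <- seeds[[i]]
    tx[[sprintf("c%d_2", i)]] <- mutate_seq(seeds[[i]], 5)
    tx[[sprintf("c%d_3", i)]] <- mutate_seq(seeds[[i]], 8)
    tx[[sprintf("c%d_4", i)]] <- rand_seq(500)
  }
  tx <- unlist(tx)
  cr3 <- collapse_redundancy(tx)
  related <- function(i, j) {
    al <- align_pair(tx[[i]], tx[[j]], band = 0)
    al$aligned_columns >= 300 && al$pident >= 98
  }
  truth <- oracle_closure(names(tx), related)
  expect_equal(length(cr3$representatives), length(unique(truth)))
  # same partition: cluster labels agree up to renaming
  expect_equal(as.integer(factor(cr3$clusters[names(tx)])),
               as.integer(factor(truth)), ignore_attr = TRUE)
  # idempotence
  cr4 <- collapse_redundancy(cr3$representatives)
  expect_equal(cr4$representatives, cr3$representatives)
})

test_that("ORF filter applies the 300 bp start-to-stop rule in six
           frames", {
  set.seed(27)
  codons <- c("GCT", "GGA", "TCA", "CTG", "AAC", "TGC", "GAC", "ATT")
  body <- paste(sample(codons, 98, replace = TRUE), collapse = "")
  orf300 <- paste0("ATG", body, "TAA")  # exactly 300 bp
  expect_equal(nchar(orf300), 300)
  expect_equal(longest_orf(orf300), 300)
  expect_named(orf_filter(c(x = orf300)), "x")

  polyT <- paste(rep("T", 500), collapse = "")
  expect_equal(length(orf_filter(c(x = polyT))), 0)

  for (i in 1:10) {
    s <- rand_seq(2000)
    expect_equal(longest_orf(s), oracle_longest_orf(s))
  }
})
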