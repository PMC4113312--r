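test_that("histogram bins identities by floor with a closed top bin", {
  h <- similarity_histogram(c(82.3, 82.9, 94.5))
  expect_equal(h$count[h$bin == 82], 2)
  expect_equal(h$count[h$bin == 94], 1)
  expect_equal(sum(h$count), 3)
  expect_equal(attr(h, "total"), 3)

  h0 <- similarity_histogram(numeric(0))
  expect_true(all(h0$count == 0))
  expect_equal(attr(h0, "total"), 0)

  h100 <- similarity_histogram(c(100, 99.5))
  expect_equal(h100$count[h100$bin == 99], 2)

  expect_error(similarity_histogram(c(50, 101)), "outside")
  expect_error(similarity_histogram(c(-1)), "outside")
})

test_that("histogram is conserved and order-invariant", {
  set.seed(41)
  ids <- runif(1000, 0, 100)
  h1 <- similarity_histogram(ids)
  h2 <- similarity_histogram(sample(ids))
  expect_equal(sum(h1$count), 1000)
  expect_equal(h1, h2)
})

test_that("peak detection finds isolated and two-component maxima", {
  counts <- rep(2L, 100)
  counts[83] <- 40L  # bin 82
  h <- structure(data.frame(bin = 0:99, count = counts),
                 total = sum(counts),
                 class = c("similarity_histogram", "data.frame"))
  pk <- detect_peaks(h)
  expect_equal(pk$bin, 82)

  flat <- structure(data.frame(bin = 0:99, count = rep(5L, 100)),
                    total = 500L,
                    class = c("similarity_histogram", "data.frame"))
  expect_equal(nrow(detect_peaks(flat)), 0)

  two <- similarity_histogram(c(rep(82.4, 100), rep(98.2, 100)))
  pk2 <- detect_peaks(two)
  expect_setequal(pk2$bin, c(82, 98))

  expect_error(detect_peaks(h, window = 2), "odd")
})

test_that("band classification partitions every pair exactly once", {
  expect_equal(classify_bands(85), "candidate_3R")
  expect_equal(classify_bands(98), "recent")
  expect_equal(classify_bands(92), "other")
  expect_equal(classify_bands(77), "candidate_3R")
  expect_equal(classify_bands(89), "candidate_3R")
  expect_equal(classify_bands(97), "other")  # recent requires > 97
  set.seed(42)
  lab <- classify_bands(runif(500, 0, 100))
  expect_true(all(lab %in% c("recent", "candidate_3R", "other")))
  expect_length(lab, 500)
})

test_that("distribution comparison reports modal bins side by side", {
  h82 <- similarity_histogram(c(rep(82.5, 30), rep(70.5, 5)))
  h89 <- similarity_histogram(c(rep(89.5, 30), rep(70.5, 5)))
  cmp <- compare_distributions(a = h82, b = h89)
  expect_equal(cmp$modal_bin, c(82, 89))
  cmp2 <- compare_distributions(a = h82, b = h82)
  expect_equal(cmp2$modal_bin[1], cmp2$modal_bin[2])
  h_bad <- h82[1:50, ]
  class(h_bad) <- class(h82)
  expect_error(compare_distributions(a = h82, b = h_bad), "share bins")
})

test_that("simulated pre- and post-WGD cohorts land in the right bands", {
  cfg <- sim_config(seed = 43, n_chromosomes_ancestral = 2,
                    genes_per_chromosome = 10,
                    gene_length_range = c(300, 400))
  g <- simulate_ancestral_genome(cfg)
  w3 <- apply_wgd(g$genome, g$truth, 0.18, "3R")
  p3 <- reciprocal_best_hits(w3$genome$seqs, band = 16)
  w4 <- apply_wgd(g$genome, g$truth, 0.06, "4R")
  p4 <- reciprocal_best_hits(w4$genome$seqs, band = 16)
  cmp <- compare_distributions(pre = similarity_histogram(p3),
                               post = similarity_histogram(p4))
  expect_equal(cmp$modal_bin, c(82, 94))
})
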