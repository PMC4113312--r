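test_that("FPKM follows its formula", {
  counts <- matrix(c(10, 0), 2, 1,
                   dimnames = list(c("t1", "t2"), "brain"))
  fp <- fpkm(counts, lengths = c(1000, 500), totals = 1e6)
  expect_equal(fp["t1", "brain"], 10)
  expect_equal(fp["t2", "brain"], 0)
  expect_error(fpkm(counts, c(1000, 0), 1e6), "length")
  expect_error(fpkm(counts, c(1000, 500), 0), "total")

  set.seed(71)
  cm <- matrix(rpois(50 * 13, 40), 50, 13,
               dimnames = list(sprintf("t%02d", 1:50),
                               sprintf("ti%02d", 1:13)))
  lens <- sample(300:2000, 50)
  tot <- colSums(cm)
  fp2 <- fpkm(cm, lens)
  for (k in sample(length(fp2), 25)) {
    i <- (k - 1) %% 50 + 1
    j <- (k - 1) %/% 50 + 1
    expect_equal(unname(fp2[i, j]),
                 unname(cm[i, j] * 1e9 / (lens[i] * tot[j])))
  }
})

test_that("FPKM is invariant to scaling a tissue's depth", {
  set.seed(72)
  cm <- matrix(rpois(20 * 4, 50), 20, 4)
  lens <- sample(500:1500, 20)
  tot <- colSums(cm)
  fp1 <- fpkm(cm, lens, tot)
  cm2 <- cm
  cm2[, 2] <- cm[, 2] * 7
  fp2 <- fpkm(cm2, lens, tot * c(1, 7, 1, 1))
  expect_equal(fp1, fp2)
})

test_that("the 3-SD specialization rule behaves on canonical rows", {
  # constant row: SD 0, nothing flagged
  m1 <- matrix(5, 1, 13, dimnames = list("t", sprintf("ti%02d", 1:13)))
  expect_equal(nrow(specialized_calls(m1)$pairs), 0)

  # twelve 1.0s and one 100.0: mean 8.615, sample SD 27.46 -> only the
  # 100.0 tissue exceeds mean + 3 SD (~91.0)
  v <- c(rep(1, 12), 100)
  m2 <- matrix(v, 1, 13, byrow = TRUE,
               dimnames = list("t", sprintf("ti%02d", 1:13)))
  calls <- specialized_calls(m2)
  expect_equal(calls$pairs$tissue, "ti13")
  expect_equal(mean(v) + 3 * sd(v), 90.99, tolerance = 1e-3)

  expect_error(specialized_calls(matrix(1, 2, 1)), "single tissue")
})

test_that("specialization calls equal the brute-force oracle and satisfy
           the defining inequality", {
  set.seed(73)
  for (rep in 1:3) {
    m <- matrix(exp(rnorm(40 * 13, 3, 1)), 40, 13,
                dimnames = list(sprintf("t%02d", 1:40),
                                sprintf("ti%02d", 1:13)))
    calls <- specialized_calls(m)
    expect_equal(calls$calls, oracle_specialized(m))
    idx <- which(calls$calls, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1]
      expect_gt(m[idx[k, 1], idx[k, 2]],
                mean(m[i, ]) + 3 * sd(m[i, ]))
    }
  }
  # population-SD variant flags at least as many cells
  m <- matrix(exp(rnorm(40 * 13, 3, 1)), 40, 13)
  expect_gte(sum(specialized_calls(m, sd_denom = "n")$calls),
             sum(specialized_calls(m, sd_denom = "n-1")$calls))
})

test_that("per-tissue complexity ranking counts specialized transcripts", {
  set.seed(74)
  e <- simulate_expression(260, 13, n_specialized_per_tissue = 4)
  fp <- fpkm(e$counts, e$lengths)
  calls <- specialized_calls(fp)
  expect_setequal(calls$per_tissue$tissue, colnames(e$counts))
  expect_true(all(diff(calls$per_tissue$n_specialized) <= 0))
  expect_gte(min(calls$per_tissue$n_specialized), 1)
})

test_that("top tables rank by FPKM with deterministic ties", {
  m <- matrix(c(5, 5, 1), 3, 1,
              dimnames = list(c("tb", "ta", "tc"), "brain"))
  top <- top_expressed(m, per_tissue_n = 10)
  expect_equal(top$transcript, c("ta", "tb", "tc"))  # ties by id
  expect_equal(nrow(top), 3)
  top2 <- top_expressed(m, per_tissue_n = 2)
  expect_equal(top2$transcript, c("ta", "tb"))
})
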