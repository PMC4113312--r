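test_that("informativeness follows the heterozygosity rule", {
  expect_equal(classify_informativeness("101/103", "101/101"),
               "mother_only")
  expect_equal(classify_informativeness("101/103", "105/107"), "both")
  expect_equal(classify_informativeness("101/101", "101/101"), "neither")
  expect_equal(classify_informativeness("101/101", "101/103"),
               "father_only")
  expect_error(classify_informativeness("101", "101/103"), "malformed")
})

test_that("missing filter drops strictly above the threshold, honours
           the keep list, and is order-independent", {
  # 14/92 = 15.2% missing -> dropped; 13/92 = 14.1% -> kept
  t14 <- toy_genotype_table(92, missing_per_marker = 14)
  f14 <- missing_filter(t14)
  expect_equal(nrow(f14), 0)
  expect_length(attr(f14, "dropped"), 2)

  t13 <- toy_genotype_table(92, missing_per_marker = 13)
  expect_equal(nrow(missing_filter(t13)), 2)

  keep <- missing_filter(t14, keep_list = t14$marker[1])
  expect_equal(keep$marker, t14$marker[1])
  expect_equal(attr(keep, "kept_flagged"), t14$marker[1])

  # order independence over markers
  rev_tab <- t14[2:1, ]
  attr(rev_tab, "progeny_father") <- attr(t14, "progeny_father")
  class(rev_tab) <- class(t14)
  expect_setequal(attr(missing_filter(rev_tab), "dropped"),
                  attr(f14, "dropped"))
})

test_that("two-point LOD matches its closed form", {
  # n = 20, r = 0
  tp0 <- two_point(rep(1L, 20), rep(1L, 20))
  expect_equal(tp0$lod, 20 * log10(2), tolerance = 1e-10)
  expect_equal(round(tp0$lod, 2), 6.02)
  # n = 20, r = 10 -> LOD 0
  tp10 <- two_point(c(rep(1L, 10), rep(2L, 10)), rep(1L, 20))
  expect_equal(tp10$lod, 0)
  expect_equal(tp10$r_hat, 0.5)
  # n = 100, r = 20: direct evaluation of the likelihood-ratio formula
  ti <- rep(1L, 100)
  tj <- c(rep(2L, 20), rep(1L, 80))
  tp20 <- two_point(ti, tj)
  expect_equal(tp20$r, 20L)
  lod_direct <- 20 * log10(0.2) + 80 * log10(0.8) + 100 * log10(2)
  expect_equal(tp20$lod, lod_direct)
  expect_equal(round(tp20$lod, 2), 8.37)
  # missing transmissions excluded from n
  tpm <- two_point(c(1L, NA, 1L, 2L), c(1L, 1L, NA, 2L))
  expect_equal(tpm$n, 2L)
  # phase maximization: complementary codings give the same r
  expect_equal(two_point(ti, 3L - tj)$r, 20L)
})

test_that("LOD is decreasing in r and zero at r = n/2", {
  n <- 60
  lods <- vapply(0:(n / 2), function(r) {
    two_point(c(rep(2L, r), rep(1L, n - r)), rep(1L, n))$lod
  }, numeric(1))
  expect_true(all(diff(lods) < 1e-12))
  expect_equal(lods[length(lods)], 0)
})

test_that("vectorized pair statistics agree with two_point", {
  set.seed(61)
  fmap <- make_marker_map(2, 5, 8)
  parents <- simulate_parent_genotypes(fmap, hom_fraction = 0.2)
  fam <- simulate_half_sib_family(fmap, fmap, parents,
                                  n_progeny = c(30, 30),
                                  missing_rate = 0.1)
  st <- suppressWarnings(pair_stats(fam))
  tr <- st$mother$trans
  for (i in 1:5) {
    for (j in (i + 1):min(i + 3, 10)) {
      tp <- two_point(tr[i, ], tr[j, ])
      if (tp$n > 0) {
        expect_equal(st$mother$n[i, j], tp$n)
        expect_equal(st$mother$r[i, j], tp$r)
        expect_equal(st$mother$lod[i, j], tp$lod)
      }
    }
  }
})

test_that("grouping is transitive and honours cross-parent joining", {
  mk <- c("A", "B", "C")
  mkmat <- function(vals) {
    m <- matrix(vals, 3, 3, dimnames = list(mk, mk))
    diag(m) <- NA
    m
  }
  trans_all <- matrix(1L, 3, 2, dimnames = list(mk, c("p1", "p2")))
  # LODs {AB: 5, BC: 5, AC: 0.1} -> one group of three by transitivity
  lod1 <- mkmat(c(NA, 5, 0.1, 5, NA, 5, 0.1, 5, NA))
  g1 <- group_markers(list(mother = list(lod = lod1, trans = trans_all)))
  expect_length(g1$groups, 1)
  expect_setequal(g1$groups[[1]], mk)

  # bridge at 3.4 in one parent joins only with >= 4.0 support elsewhere
  lod_weak <- mkmat(c(NA, 3.4, NA, 3.4, NA, NA, NA, NA, NA))
  lod_none <- mkmat(rep(NA_real_, 9))
  lod_supp <- mkmat(c(NA, 4.2, NA, 4.2, NA, NA, NA, NA, NA))
  g_un <- group_markers(list(mother = list(lod = lod_weak,
                                           trans = trans_all),
                             father1 = list(lod = lod_none,
                                            trans = trans_all)))
  expect_length(g_un$groups, 0)  # 3.4 alone does not form a group
  g_sup <- group_markers(list(mother = list(lod = lod_weak,
                                            trans = trans_all),
                              father1 = list(lod = lod_supp,
                                             trans = trans_all)))
  expect_true(any(vapply(g_sup$groups, function(g)
    setequal(g, c("A", "B")), logical(1))))
})

test_that("ordering recovers the chain and canonicalizes orientation", {
  mk <- c("A", "B", "C")
  rh <- matrix(c(NA, 0.05, 0.10, 0.05, NA, 0.05, 0.10, 0.05, NA),
               3, 3, dimnames = list(mk, mk))
  expect_equal(order_group(mk, rh), c("A", "B", "C"))
  expect_equal(order_group(c("B", "A"), rh), c("A", "B"))

  set.seed(62)
  fmap <- make_marker_map(1, 8, 12)
  parents <- simulate_parent_genotypes(fmap, hom_fraction = 0)
  fam <- simulate_half_sib_family(fmap, fmap, parents,
                                  n_progeny = c(250, 250),
                                  missing_rate = 0)
  st <- pair_stats(fam, "mother")
  ord <- order_group(fmap$marker, st$mother$r_hat)
  expect_true(identical(ord, fmap$marker) ||
                identical(ord, rev(fmap$marker)))
})

test_that("map functions match their closed forms", {
  expect_equal(round(map_distance(0.1, "haldane"), 2), 11.16)
  expect_equal(round(map_distance(0.1, "kosambi"), 2), 10.14)
  expect_equal(map_distance(0, "haldane"), 0)
  expect_equal(map_distance(0, "kosambi"), 0)
  expect_error(map_distance(0.5), "r_hat")
})

test_that("map merging anchors on shared markers and reports
           unmergeable groups", {
  g1 <- data.frame(marker = c("A", "B", "C"), pos_cM = c(0, 10, 20))
  map_a <- structure(list(LG1 = g1), class = "linkage_map",
                     sex = "female", total_cM = 20)
  map_b <- structure(list(LG1 = g1), class = "linkage_map",
                     sex = "male", total_cM = 20)
  mm <- merge_maps(map_a, map_b)
  expect_equal(mm$merged$LG1, g1, ignore_attr = TRUE)

  g2 <- data.frame(marker = c("X", "Y"), pos_cM = c(0, 15))
  map_c <- structure(list(LG9 = g2), class = "linkage_map",
                     sex = "male", total_cM = 15)
  mm2 <- merge_maps(map_a, map_c)
  expect_equal(mm2$unmerged_b, "LG9")

  # male-only markers interpolate between shared anchors
  gb <- data.frame(marker = c("A", "M", "B"), pos_cM = c(0, 5, 10))
  map_d <- structure(list(LG1 = gb), class = "linkage_map",
                     sex = "male", total_cM = 10)
  mm3 <- merge_maps(map_a, map_d)
  merged <- mm3$merged$LG1
  expect_equal(merged$pos_cM[merged$marker == "M"], 5)
  expect_setequal(merged$marker, c("A", "B", "C", "M"))
})

test_that("map statistics reproduce the sex-ratio arithmetic", {
  f <- structure(list(LG1 = data.frame(marker = c("A", "B"),
                                       pos_cM = c(0, 1245.4))),
                 class = "linkage_map", sex = "female")
  m <- structure(list(LG1 = data.frame(marker = c("A", "B"),
                                       pos_cM = c(0, 1166.0))),
                 class = "linkage_map", sex = "male")
  st <- map_stats(f, m)
  expect_equal(st$ratio, 1.07)
  expect_equal(map_stats(f, f)$ratio, 1)
})

test_that("Mendelian-inconsistent progeny calls are warned and dropped", {
  fmap <- make_marker_map(1, 1, 0)
  parents <- data.frame(marker = fmap$marker, mother = "101/103",
                        father1 = "105/107", stringsAsFactors = FALSE)
  fam <- simulate_half_sib_family(fmap, fmap, parents, n_progeny = 4,
                                  missing_rate = 0)
  prog <- names(attr(fam, "progeny_father"))
  fam[1, prog[1]] <- "199/199"  # impossible genotype
  expect_warning(tr <- transmissions(fam, "mother"),
                 "inconsistent")
  expect_true(is.na(tr[1, prog[1]]))
})
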