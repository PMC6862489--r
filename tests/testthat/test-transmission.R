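test_that("the d60/gal double heterozygote sheds lethal gametes and keeps 75% fertility", {
  map <- d60_gal_map()
  f1 <- phased_genotype(map, c(D60 = "D60", Gal = "Gal"),
                             c(D60 = "d60", Gal = "gal"))
  gd <- gamete_frequencies(f1, map, rule = study_rule())
  expect_freqs_equal(gd, c("D60:Gal" = 1/3, "D60:gal" = 1/3, "d60:Gal" = 1/3))
  expect_identical(attr(gd, "fertility"), 0.75)
})

test_that("without lethality two unlinked heterozygous loci give four gametes at 1/4", {
  map <- d60_gal_map()
  f1 <- phased_genotype(map, c(D60 = "D60", Gal = "Gal"),
                             c(D60 = "d60", Gal = "gal"))
  gd <- gamete_frequencies(f1, map)
  expect_equal(sort(gd$freq), rep(0.25, 4))
  expect_identical(attr(gd, "fertility"), 1)
})

test_that("complete GW2-D60 linkage leaves three surviving gamete types at 1/3", {
  # hand enumeration: 8 phase-consistent haplotypes, r(GW2,D60)=0 collapses to
  # {GW2.d60}xGal/gal and {gw2.D60}xGal/gal at 1/4 each; GW2.d60.gal is lethal
  map <- study_map(r = 0)
  parent <- phased_genotype(map, c(GW2 = "GW2", D60 = "d60", Gal = "Gal"),
                                 c(GW2 = "gw2", D60 = "D60", Gal = "gal"))
  gd <- gamete_frequencies(parent, map, rule = study_rule())
  expect_freqs_equal(gd, c("GW2:d60:Gal" = 1/3, "gw2:D60:Gal" = 1/3,
                           "gw2:D60:gal" = 1/3))
  expect_identical(attr(gd, "fertility"), 0.75)
})

test_that("illegal alleles are rejected as invalid genotypes", {
  map <- d60_gal_map()
  expect_error(phased_genotype(map, c(D60 = "XX", Gal = "Gal"),
                                    c(D60 = "d60", Gal = "gal")),
               class = "seglethal_invalid_genotype")
})

test_that("selfing the F1-type survivor distribution yields 6:2:1 culm classes", {
  map <- d60_gal_map()
  f1 <- phased_genotype(map, c(D60 = "D60", Gal = "Gal"),
                             c(D60 = "d60", Gal = "gal"))
  gd <- gamete_frequencies(f1, map, rule = study_rule())
  zd <- zygote_distribution(gd, gd)
  expect_equal(sum(zd$freq), 1, tolerance = 1e-12)
  p <- expected_class_probabilities(zd, culm_classifier())
  expect_equal(p$prob[p$class == "long_culm"], 6/9, tolerance = 1e-12)
  expect_equal(p$prob[p$class == "partially_sterile"], 2/9, tolerance = 1e-12)
  expect_equal(p$prob[p$class == "semidwarf"], 1/9, tolerance = 1e-12)
})

test_that("two fixed homozygous parents give a single F1 genotype", {
  map <- study_map()
  gd_f <- gamete_frequencies(founder_koshihikari(map), map)
  gd_m <- gamete_frequencies(founder_inochinoichi(map), map)
  zd <- zygote_distribution(gd_f, gd_m)
  expect_equal(nrow(zd), 1L)
  expect_equal(zd$freq, 1)
})

test_that("mismatched locus sets are incompatible gametes", {
  map2 <- d60_gal_map()
  map3 <- study_map()
  gd2 <- gamete_frequencies(phased_genotype(map2, c(D60 = "D60", Gal = "Gal"),
                                                  c(D60 = "d60", Gal = "gal")),
                            map2)
  gd3 <- gamete_frequencies(founder_koshihikari(map3), map3)
  expect_error(zygote_distribution(gd2, gd3),
               class = "seglethal_incompatible_gametes")
})

test_that("carrier frequency is 5/9 under complete linkage, 6/36 and 2/36 under independence", {
  g0 <- expected_class_probabilities(resolve_design(design_bc1f2(r = 0)),
                                     grain_classifier(mode = "complete"))
  expect_equal(g0$prob[g0$class == "large"], 5/9, tolerance = 1e-12)
  expect_equal(g0$prob[g0$class == "small"], 4/9, tolerance = 1e-12)

  jt <- expected_class_probabilities(
    resolve_design(design_bc4f2(r = 0.5)),
    joint_classifier(grain_classifier(), culm_classifier()))
  p <- stats::setNames(jt$prob, jt$class)
  expect_equal(p[["large:long_culm"]], 6/36, tolerance = 1e-12)
  expect_equal(p[["large:partially_sterile"]], 2/36, tolerance = 1e-12)
})

test_that("a fixed line classifies to a degenerate class distribution", {
  zd <- resolve_design(cross_design(
    founders = list(K = founder_koshihikari()),
    steps = list(step_self("S1", "K", n = 1L)),
    map = study_map(), rule = study_rule()))
  p <- expected_class_probabilities(zd, culm_classifier())
  expect_equal(sort(p$prob, decreasing = TRUE), c(1, 0, 0))
})

test_that("classify follows the culm and grain rules", {
  expect_identical(classify(list(D60 = "d60/d60", Gal = "Gal/Gal"),
                            culm_classifier()), "semidwarf")
  expect_identical(classify(list(D60 = "d60/D60", Gal = "Gal/gal"),
                            culm_classifier()), "partially_sterile")
  expect_identical(classify(list(D60 = "d60/D60", Gal = "Gal/Gal"),
                            culm_classifier()), "long_culm")
  expect_identical(classify(list(GW2 = "GW2/gw2"), grain_classifier()),
                   "medium")
  expect_identical(classify(list(GW2 = "GW2/GW2"), grain_classifier()),
                   "large")
  expect_error(classify(list(GW2 = "GW2/gw2"), culm_classifier()),
               class = "seglethal_classification")
})

test_that("gamete and zygote distributions sum to one for random phased parents", {
  set.seed(42)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    map <- random_map(k, linked = sample(1:k, 1))
    par1 <- random_parent(map)
    par2 <- random_parent(map)
    gd1 <- gamete_frequencies(par1, map)
    gd2 <- gamete_frequencies(par2, map)
    expect_equal(sum(gd1$freq), 1, tolerance = 1e-12)
    zd <- zygote_distribution(gd1, gd2)
    expect_equal(sum(zd$freq), 1, tolerance = 1e-12)
  }
})

test_that("with no lethality and r = 0.5 a two-locus F2 segregates 9:3:3:1", {
  map <- linkage_map(list(locus("A", c("A", "a")), locus("B", c("B", "b"))),
                     groups = list(g = c("A", "B")), r = list(g = 0.5))
  f1 <- phased_genotype(map, c(A = "A", B = "B"), c(A = "a", B = "b"))
  gd <- gamete_frequencies(f1, map)
  zd <- zygote_distribution(gd, gd)
  geno <- zygote_genotypes(zd)
  dom_a <- grepl("A", geno$A, fixed = TRUE)
  dom_b <- grepl("B", geno$B, fixed = TRUE)
  p <- c(sum(geno$freq[dom_a & dom_b]), sum(geno$freq[dom_a & !dom_b]),
         sum(geno$freq[!dom_a & dom_b]), sum(geno$freq[!dom_a & !dom_b]))
  expect_equal(p, c(9, 3, 3, 1) / 16, tolerance = 1e-12)
})

test_that("culm-class probabilities are invariant to the GW2-D60 recombination fraction", {
  for (r in c(0, 0.1, 0.176, 0.3, 0.5)) {
    p <- expected_class_probabilities(resolve_design(design_bc1f2(r = r)),
                                      culm_classifier())
    expect_equal(stats::setNames(p$prob, p$class),
                 c(semidwarf = 1/9, partially_sterile = 2/9, long_culm = 6/9),
                 tolerance = 1e-12)
  }
})

test_that("P(gw2gw2 | semidwarf) increases strictly with r and vanishes at r = 0", {
  cond_small <- function(r) {
    jt <- expected_class_probabilities(
      resolve_design(design_bc4f2(r = r)),
      joint_classifier(grain_classifier(), culm_classifier()))
    p <- stats::setNames(jt$prob, jt$class)
    p[["small:semidwarf"]] / sum(p[grep(":semidwarf", names(p), fixed = TRUE)])
  }
  rs <- c(0, 0.05, 0.176, 0.3, 0.4, 0.5)
  vals <- vapply(rs, cond_small, numeric(1))
  expect_equal(vals[1], 0, tolerance = 1e-12)
  expect_true(all(diff(vals) > 0))
  expect_equal(vals, rs^2, tolerance = 1e-12)  # conditional law is Binom(2, r)
})
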