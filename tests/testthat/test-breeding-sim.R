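loci_of <- function(pop) map_locus_names(attr(pop, "map"))

test_that("a large simulated d60-scheme F2 fits the 6:2:1 culm expectation", {
  pop <- simulate_population(design_d60_f2(n = 10000L), seed = 3)
  lab <- classify(pop[loci_of(pop)], culm_classifier())
  obs <- c(semidwarf = sum(lab == "semidwarf"),
           partially_sterile = sum(lab == "partially_sterile"),
           long_culm = sum(lab == "long_culm"))
  res <- fit_vs_model(obs, design_d60_f2(), culm_classifier())
  expect_gt(res$p, 0.01)
})

test_that("one offspring of two fixed homozygous parents is the unique F1", {
  d <- cross_design(
    founders = list(K = founder_koshihikari(), I = founder_inochinoichi()),
    steps = list(step_cross("F1", "K", "I", n = 1L)),
    map = study_map(), rule = study_rule())
  pop <- simulate_population(d, seed = 5)
  expect_equal(nrow(pop), 1L)
  expect_setequal(c(pop$hap1, pop$hap2),
                  c("GW2:D60:gal", "gw2:D60:gal"))
})

test_that("simulation is reproducible per seed and written byte-identically", {
  p1 <- simulate_population(design_grain_f2(n = 50L), seed = 9)
  p2 <- simulate_population(design_grain_f2(n = 50L), seed = 9)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  p3 <- simulate_population(design_grain_f2(n = 50L), seed = 10)
  expect_false(identical(p1$hap1, p3$hap1))

  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_population(sample_phenotypes(p1, seed = 9), f1)
  write_population(sample_phenotypes(p2, seed = 9), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(file.exists(paste0(f1, ".provenance.txt")))
})

test_that("simulated F1-type individuals carry fertility 0.75 as a genotype property", {
  d <- design_d60_f2(n = 400L)
  pops <- simulate_population(d, seed = 2, all = TRUE)
  expect_equal(unique(pops$F1$fertility), 0.75)
  f2 <- pops$F2
  lab <- classify(f2[loci_of(f2)], culm_classifier())
  expect_true(all(f2$fertility[lab == "partially_sterile"] == 0.75))
  expect_true(all(f2$fertility[lab != "partially_sterile"] == 1))
})

test_that("with lethality disabled single-locus F2 ratios are Mendelian 1:2:1", {
  pop <- simulate_population(design_grain_f2(n = 8000L), rule = NULL, seed = 13)
  counts <- table(pop$GW2)
  tab <- class_count_table(names(counts), as.integer(counts),
                           ratio = c(1, 2, 1)[match(names(counts),
                             c("GW2/GW2", "GW2/gw2", "gw2/gw2"))])
  expect_gt(chi_square_gof(tab)$p, 0.01)
})

test_that("an unsatisfiable selection predicate fails naming the step", {
  d <- design_grain_f2(n = 30L)
  d$steps <- c(d$steps, list(step_select("pick_dwarf", "F2",
                                         genotype_predicate(c(D60 = "d60/d60")))))
  expect_error(simulate_population(d, seed = 1), "pick_dwarf",
               class = "seglethal_selection_failure")
})

test_that("genotype selection steps propagate the selected parent", {
  d <- design_grain_f2(n = 200L)
  d$steps <- c(d$steps,
               list(step_select("large_grain", "F2",
                                genotype_predicate(c(GW2 = "GW2/GW2"))),
                    step_self("F3", "large_grain", n = 50L)))
  pop <- simulate_population(d, seed = 21)
  expect_true(all(pop$GW2 == "GW2/GW2"))   # selfing a fixed homozygote
})

test_that("a marker at the anchor position matches the trait genotype exactly", {
  pop <- simulate_population(design_grain_f2(n = 300L), seed = 4)
  mk <- data.frame(marker = "at_anchor", chromosome = "chr2", pos_mb = 8.1)
  pop <- attach_markers(pop, mk, anchor = "GW2", seed = 6)
  code <- c("GW2/GW2" = "D", "GW2/gw2" = "H", "gw2/gw2" = "R")
  expect_identical(pop$at_anchor, unname(code[pop$GW2]))
})

test_that("marker-trait recombination matches the Haldane distance at 20 cM", {
  pop <- simulate_population(design_grain_f2(n = 4000L), seed = 8)
  mk <- data.frame(marker = "M20", chromosome = "chr2", pos_mb = 8.1 + 5)
  pop <- attach_markers(pop, mk, anchor = "GW2", cm_per_mb = 4, seed = 9)
  rec <- pop[pop$GW2 == "gw2/gw2", "M20", drop = FALSE]
  est <- marker_trait_recombination(rec)
  expect_lt(abs(est$value - 100 * haldane_r(20)), 3)
})

test_that("double recombinants across flanking markers occur at the product rate", {
  pop <- simulate_population(design_grain_f2(n = 20000L), seed = 15)
  mk <- data.frame(marker = c("ML", "MR"), chromosome = "chr2",
                   pos_mb = c(8.1 - 2.5, 8.1 + 2.5))
  pop <- attach_markers(pop, mk, anchor = "GW2", seed = 16)
  # score per gamete via the recessive-class trick on both homozygote classes
  r1 <- haldane_r(10)
  hom <- pop$GW2 %in% c("gw2/gw2", "GW2/GW2")
  sub <- pop[hom, ]
  expected_code <- ifelse(sub$GW2 == "gw2/gw2", "R", "D")
  n_rec_l <- ifelse(sub$ML == "H", 1L, ifelse(sub$ML == expected_code, 0L, 2L))
  n_rec_r <- ifelse(sub$MR == "H", 1L, ifelse(sub$MR == expected_code, 0L, 2L))
  # fraction of individuals recombinant on both sides vs product of margins
  p_l <- mean(n_rec_l) / 2; p_r <- mean(n_rec_r) / 2
  p_both <- (sum(pmin(n_rec_l, n_rec_r))) / (2 * nrow(sub))
  expect_lt(abs(p_l - r1), 0.01)
  expect_lt(abs(p_both - p_l * p_r), 0.01)
})

test_that("markers off the anchor chromosome are rejected", {
  pop <- simulate_population(design_grain_f2(n = 10L), seed = 1)
  mk <- data.frame(marker = "off", chromosome = "chr3", pos_mb = 1)
  expect_error(attach_markers(pop, mk, anchor = "GW2", seed = 1),
               class = "seglethal_placement")
})

test_that("zero trait noise returns exact class means; noise accuracy matches theory", {
  pop <- simulate_population(design_grain_f2(n = 2000L), seed = 17)
  m0 <- phenotype_model(grain_sd = 1e-12, culm_sd = 1e-12)
  p0 <- sample_phenotypes(pop, m0, seed = 18)
  expect_equal(unname(m0$grain_means[p0$grain_class]), p0$grain_area,
               tolerance = 1e-6)

  model <- phenotype_model()
  pd <- sample_phenotypes(pop, model, seed = 19)
  recovered <- mean(c("small", "medium", "large")[
    findInterval(pd$grain_area, c(21.0, 23.3)) + 1L] == pd$grain_class)
  # closed-form Gaussian overlap: class-weighted probability of landing in
  # the own-class interval given means 20.0/22.0/24.6 and sd 0.8
  sd <- model$grain_sd
  p_small <- stats::pnorm(21.0, 20.0, sd)
  p_med <- stats::pnorm(23.3, 22.0, sd) - stats::pnorm(21.0, 22.0, sd)
  p_large <- 1 - stats::pnorm(23.3, 24.6, sd)
  theory <- sum(c(p_small, p_med, p_large) *
                  prop.table(table(factor(pd$grain_class,
                                          c("small", "medium", "large")))))
  expect_lt(abs(recovered - theory), 0.03)
})

test_that("simulated grain areas classify to counts fitting 1:2:1 in most seeds", {
  ok <- 0L
  for (s in 1:30) {
    pop <- simulate_population(design_grain_f2(n = 200L), seed = 100 + s)
    pd <- sample_phenotypes(pop, seed = 200 + s)
    tab <- classify_counts(pd$grain_area, grain_threshold_rule(),
                           ratio = c(1, 2, 1))
    if (chi_square_gof(tab)$p > 0.01) ok <- ok + 1L
  }
  expect_gte(ok, 27L)
})
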