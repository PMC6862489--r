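#' Phenotype model for simulated populations
#'
#' Class means and Gaussian noise for the two measured traits. Grain-area
#' anchors follow the marker-diagnosed class means of the mapping material
#' (small/recurrent 20.0 mm^2, donor-homozygous large 24.6 mm^2, heterozygote
#' intermediate at 22.0 mm^2 under incomplete dominance); culm-length means
#' follow the semidwarf (44-54 cm) and long-culm (54-74 cm) class ranges of
#' the combined-scheme BC4F2.
#'
#' @param grain_means named numeric: mean grain area (mm^2) per grain class;
#'   must be ordered small < medium < large.
#' @param grain_sd within-class standard deviation (mm^2).
#' @param culm_means named numeric: mean culm length (cm) for semidwarf and
#'   long-culm classes (partially sterile plants are long-culm in stature).
#' @param culm_sd within-class standard deviation (cm).
#' @param fertility_threshold individuals with gamete survival below this are
#'   labelled partially sterile (the default 1 flags the 0.75-fertility
#'   F1-type genotype).
#' @return A \code{"phenotype_model"}.
#' @examples
#' phenotype_model()
#' @export
phenotype_model <- function(grain_means = c(small = 20.0, medium = 22.0,
                                            large = 24.6),
                            grain_sd = 0.8,
                            culm_means = c(semidwarf = 49, long_culm = 64),
                            culm_sd = 3,
                            fertility_threshold = 1) {
  if (!(grain_means[["small"]] < grain_means[["medium"]] &&
        grain_means[["medium"]] < grain_means[["large"]]))
    abort("grain means must be ordered small < medium < large",
          "seglethal_invalid_model")
  if (!(culm_means[["semidwarf"]] < culm_means[["long_culm"]]))
    abort("semidwarf mean culm length must be below the long-culm mean",
          "seglethal_invalid_model")
  if (grain_sd <= 0 || culm_sd <= 0)
    abort("trait standard deviations must be positive",
          "seglethal_invalid_model")
  structure(list(grain_means = grain_means, grain_sd = grain_sd,
                 culm_means = culm_means, culm_sd = culm_sd,
                 fertility_threshold = fertility_threshold),
            class = "phenotype_model")
}

step_seed <- function(seed, i)
  as.integer(((as.numeric(seed) %% 1e9) * 1009 + i * 7919) %% 2147483629)

pop_genotypes <- function(pop, map) {
  loci <- map_locus_names(map)
  a1 <- do.call(rbind, strsplit(pop$hap1, ":", fixed = TRUE))
  a2 <- do.call(rbind, strsplit(pop$hap2, ":", fixed = TRUE))
  cols <- list()
  for (j in seq_along(loci)) {
    ord <- map$loci[[loci[j]]]$alleles
    donor_first <- match(a1[, j], ord) <= match(a2[, j], ord)
    cols[[loci[j]]] <- paste(ifelse(donor_first, a1[, j], a2[, j]),
                             ifelse(donor_first, a2[, j], a1[, j]), sep = "/")
  }
  as.data.frame(cols, stringsAsFactors = FALSE)
}

genotype_fertility <- function(pop, map, rule) {
  key <- paste(pop$hap1, pop$hap2, sep = "|")
  uk <- unique(key)
  fert <- vapply(uk, function(k) {
    hp <- strsplit(k, "|", fixed = TRUE)[[1]]
    h1 <- strsplit(hp[1], ":", fixed = TRUE)[[1]]
    h2 <- strsplit(hp[2], ":", fixed = TRUE)[[1]]
    nm <- map_locus_names(map)
    names(h1) <- nm; names(h2) <- nm
    attr(gamete_frequencies(phased_genotype(map, h1, h2), map, rule), "fertility")
  }, numeric(1))
  unname(fert[match(key, uk)])
}

#' Simulate a breeding-scheme population
#'
#' Samples finite populations through the steps of a cross design under the
#' transmission model: each offspring receives one surviving gamete drawn from
#' each parent's gamete distribution (multinomial over the exact surviving
#' frequencies). Cross and self steps use the first individual of the parent
#' population (after a selection step, the first individual satisfying the
#' predicate). Each step draws from its own seeded RNG stream derived from
#' \code{seed}, so adding later steps never perturbs earlier draws.
#'
#' @param design a \code{\link{cross_design}} (step sizes come from the
#'   steps' \code{n}).
#' @param map,rule overrides for the design's own map and lethality rule.
#' @param seed integer seed; runs are reproducible per seed.
#' @param all return all populations (named list) instead of only the final.
#' @return A \code{"sim_population"} data frame: \code{id}, \code{generation},
#'   \code{hap1}, \code{hap2}, one genotype column per locus, and
#'   \code{fertility} (the individual's own gamete survival fraction).
#'   Attributes: \code{map}, \code{rule}, \code{seed}.
#' @examples
#' pop <- simulate_population(design_d60_f2(n = 200L), seed = 1)
#' table(classify(pop[map_locus_names(attr(pop, "map"))], culm_classifier()))
#' @export
simulate_population <- function(design, map = NULL, rule = NULL, seed,
                                all = FALSE) {
  map <- if (is.null(map)) design$map else map
  rule <- if (is.null(rule)) design$rule else rule
  nm <- map_locus_names(map)
  mk_pop <- function(h1, h2, gen) {
    pop <- data.frame(id = paste0(gen, "_", seq_along(h1)), generation = gen,
                      hap1 = h1, hap2 = h2, stringsAsFactors = FALSE)
    pop <- cbind(pop, pop_genotypes(pop, map))
    pop$fertility <- genotype_fertility(pop, map, rule)
    pop
  }
  pops <- lapply(names(design$founders), function(f) {
    g <- design$founders[[f]]
    k <- c(paste(g$hap1[nm], collapse = ":"), paste(g$hap2[nm], collapse = ":"))
    mk_pop(min(k), max(k), f)
  })
  names(pops) <- names(design$founders)

  draw_gamete <- function(parent_row, sex, n) {
    h1 <- strsplit(parent_row$hap1, ":", fixed = TRUE)[[1]]
    h2 <- strsplit(parent_row$hap2, ":", fixed = TRUE)[[1]]
    names(h1) <- nm; names(h2) <- nm
    gd <- gamete_frequencies(phased_genotype(map, h1, h2), map, rule, sex)
    keys <- hap_key(gd, nm)
    keys[sample.int(length(keys), n, replace = TRUE, prob = gd$freq)]
  }

  for (i in seq_along(design$steps)) {
    s <- design$steps[[i]]
    set.seed(step_seed(seed, i))
    pops[[s$name]] <- switch(
      s$op,
      cross = {
        fem <- pops[[s$parents[1]]][1, ]
        mal <- pops[[s$parents[2]]][1, ]
        mk_pop(draw_gamete(fem, "female", s$n),
               draw_gamete(mal, "male", s$n), s$name)
      },
      self = {
        par <- pops[[s$parents[1]]][1, ]
        mk_pop(draw_gamete(par, "female", s$n),
               draw_gamete(par, "male", s$n), s$name)
      },
      select = {
        parent <- pops[[s$parents[1]]]
        keep <- s$where(parent[nm])
        if (!any(keep))
          abort(sprintf(
            "selection step '%s' is unsatisfiable in population '%s'",
            s$name, s$parents[1]), "seglethal_selection_failure")
        sub <- parent[keep, , drop = FALSE]
        sub$generation <- s$name
        rownames(sub) <- NULL
        sub
      },
      abort(sprintf("unknown step op '%s'", s$op), "seglethal_invalid_design"))
  }
  res <- if (all) pops else pops[[length(pops)]]
  wrap <- function(p) structure(p, map = map, rule = rule, seed = seed,
                                class = c("sim_population", "data.frame"))
  if (all) lapply(res, wrap) else wrap(res)
}

#' Attach marker genotypes to a simulated population
#'
#' Simulates marker alleles on each individual's two haplotypes, conditional
#' on the haplotype's allele at an anchor trait locus, by walking a
#' no-interference crossover chain outward from the anchor along the
#' chromosome (physical Mb spacing converted to cM with \code{cm_per_mb},
#' then to recombination fractions with the Haldane map function). Marker
#' alleles are therefore jointly consistent with the anchored haplotype: a
#' marker at the anchor position always matches the anchor, and
#' double-recombinant frequencies are products of single-interval
#' frequencies.
#'
#' This treats each haplotype as an intact gamete of an F1 fully heterozygous
#' in coupling (all donor alleles on one parental strand), which holds for F2
#' populations such as the mapping design; it is an approximation for later
#' backcross generations.
#'
#' @param population a \code{"sim_population"}.
#' @param markers data frame with columns \code{marker}, \code{chromosome},
#'   \code{pos_mb}.
#' @param anchor name of the trait locus (must carry chromosome and position
#'   in the population's map).
#' @param cm_per_mb physical-to-genetic conversion (default 4 cM/Mb, a rice
#'   chromosome-2 order of magnitude; deliberately coarse).
#' @param seed seed for the marker crossover draws.
#' @return The population with one extra column per marker holding codes
#'   \code{"D"} (donor homozygote), \code{"H"}, \code{"R"} (recurrent
#'   homozygote), plus attribute \code{marker_info}.
#' @examples
#' pop <- simulate_population(design_grain_f2(n = 50L), seed = 1)
#' mk <- data.frame(marker = "RM3390", chromosome = "chr2", pos_mb = 7.7)
#' pop <- attach_markers(pop, mk, anchor = "GW2", seed = 2)
#' @export
attach_markers <- function(population, markers, anchor, cm_per_mb = 4, seed) {
  map <- attr(population, "map")
  loc <- map$loci[[anchor]]
  if (is.null(loc) || is.na(loc$pos_mb) || is.na(loc$chromosome))
    abort("anchor locus must have a chromosome and Mb position",
          "seglethal_placement")
  if (any(markers$chromosome != loc$chromosome))
    abort("marker placed off the anchor's chromosome", "seglethal_placement")
  n <- nrow(population)
  donor_allele <- loc$alleles[1]
  anchor_idx <- match(anchor, map_locus_names(map))
  origin <- function(haps)
    vapply(strsplit(haps, ":", fixed = TRUE), `[`, "", anchor_idx) ==
      donor_allele

  set.seed(step_seed(seed, 0L))
  o1_anchor <- origin(population$hap1)
  o2_anchor <- origin(population$hap2)
  ord <- order(markers$pos_mb)
  markers <- markers[ord, , drop = FALSE]
  res <- matrix(NA, n, nrow(markers),
                dimnames = list(NULL, markers$marker))
  for (side in c("left", "right")) {
    idx <- if (side == "left")
      rev(which(markers$pos_mb < loc$pos_mb))
    else which(markers$pos_mb >= loc$pos_mb)
    o1 <- o1_anchor; o2 <- o2_anchor
    prev <- loc$pos_mb
    for (j in idx) {
      r <- haldane_r(cm_per_mb * abs(markers$pos_mb[j] - prev))
      o1 <- xor(o1, stats::runif(n) < r)
      o2 <- xor(o2, stats::runif(n) < r)
      res[, j] <- ifelse(o1 & o2, "D", ifelse(!o1 & !o2, "R", "H"))
      prev <- markers$pos_mb[j]
    }
  }
  for (m in colnames(res)) population[[m]] <- res[, m]
  attr(population, "marker_info") <- markers
  population
}

#' Sample grain-area and culm-length phenotypes
#'
#' Adds class labels derived from the genotype (grain class from the
#' \code{GW2} genotype, culm class from \code{D60}/\code{Gal}) and draws the
#' continuous traits as class mean + Gaussian noise. Fertility is a genotype
#' property (already held by the population); individuals below the model's
#' fertility threshold are flagged partially sterile.
#'
#' @param population a \code{"sim_population"}.
#' @param model a \code{\link{phenotype_model}}.
#' @param seed seed for the trait noise.
#' @return The population with columns \code{grain_class}, \code{culm_class},
#'   \code{grain_area}, \code{culm_length}, \code{partially_sterile}.
#' @examples
#' pop <- simulate_population(design_grain_f2(n = 100L), seed = 1)
#' pop <- sample_phenotypes(pop, seed = 2)
#' @export
sample_phenotypes <- function(population, model = phenotype_model(), seed) {
  set.seed(step_seed(seed, 1L))
  geno <- population[map_locus_names(attr(population, "map"))]
  n <- nrow(population)
  grain <- classify(geno, grain_classifier())
  culm <- classify(geno, culm_classifier())
  population$grain_class <- grain
  population$culm_class <- culm
  population$grain_area <- unname(model$grain_means[grain]) +
    stats::rnorm(n, 0, model$grain_sd)
  stature <- ifelse(culm == "semidwarf", "semidwarf", "long_culm")
  population$culm_length <- unname(model$culm_means[stature]) +
    stats::rnorm(n, 0, model$culm_sd)
  population$partially_sterile <-
    population$fertility < model$fertility_threshold
  population
}

#' Write a simulated population with a provenance sidecar
#'
#' Writes the population as CSV and a plain-text sidecar
#' (\code{<path>.provenance.txt}) recording the simulation seed, population
#' size, generation label and package version, so outputs are auditable
#' without external tooling.
#'
#' @param population a \code{"sim_population"}.
#' @param path output CSV path.
#' @param extra named character vector of additional provenance fields
#'   (e.g. a design-file checksum).
#' @return \code{path}, invisibly.
#' @export
write_population <- function(population, path, extra = NULL) {
  utils::write.csv(as.data.frame(population), path, row.names = FALSE,
                   quote = FALSE)
  prov <- c(seed = as.character(attr(population, "seed")),
            n = as.character(nrow(population)),
            generation = population$generation[1],
            package_version = as.character(utils::packageVersion("seglethal")),
            extra)
  writeLines(paste(names(prov), prov, sep = ": "),
             paste0(path, ".provenance.txt"))
  invisible(path)
}
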