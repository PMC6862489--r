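#' Cross designs
#'
#' A machine-readable breeding scheme: named founder genotypes plus an ordered
#' list of steps (cross, self, select). Designs can be resolved analytically to
#' exact genotype distributions (\code{\link{resolve_design}}) or sampled as
#' finite populations (\code{\link{simulate_population}}).
#'
#' @param founders named list of \code{\link{phased_genotype}} objects.
#' @param steps list of steps from \code{step_cross}, \code{step_self},
#'   \code{step_select}.
#' @param map the \code{\link{linkage_map}} shared by all founders.
#' @param rule a \code{\link{lethality_rule}} or NULL.
#' @return An object of class \code{"cross_design"}.
#' @seealso \code{\link{design_bc1f2}} for the built-in study schemes.
#' @export
cross_design <- function(founders, steps, map, rule = NULL) {
  refs <- names(founders)
  for (s in steps) {
    for (p in s$parents)
      if (!p %in% refs)
        abort(sprintf("step '%s' references unknown population '%s'",
                      s$name, p), "seglethal_invalid_design")
    refs <- c(refs, s$name)
  }
  if (anyDuplicated(refs))
    abort("population names must be unique", "seglethal_invalid_design")
  structure(list(founders = founders, steps = steps, map = map, rule = rule),
            class = "cross_design")
}

#' @rdname cross_design
#' @param name name of the population the step produces.
#' @param female,male,parent names of parent populations.
#' @param n population size used by the simulator (ignored analytically).
#' @export
step_cross <- function(name, female, male, n = 100L)
  list(name = name, op = "cross", parents = c(female, male), n = as.integer(n))

#' @rdname cross_design
#' @export
step_self <- function(name, parent, n = 100L)
  list(name = name, op = "self", parents = parent, n = as.integer(n))

#' @rdname cross_design
#' @param where predicate: a function taking a data frame of per-locus
#'   genotype strings (one row per genotype class or individual) and returning
#'   a logical vector.
#' @export
step_select <- function(name, parent, where)
  list(name = name, op = "select", parents = parent, where = where)

#' Mixture gamete distribution of a population
#'
#' @param zd a \code{"zygote_dist"} population.
#' @param map,rule,sex forwarded to \code{\link{gamete_frequencies}}.
#' @return A \code{"gamete_dist"}; its \code{fertility} attribute is the
#'   frequency-weighted mean fertility of the population's genotypes.
#' @keywords internal
population_gametes <- function(zd, map, rule, sex) {
  loci <- attr(zd, "loci")
  tabs <- vector("list", nrow(zd))
  fert <- 0
  for (i in seq_len(nrow(zd))) {
    h1 <- strsplit(zd$hap1[i], ":", fixed = TRUE)[[1]]
    h2 <- strsplit(zd$hap2[i], ":", fixed = TRUE)[[1]]
    names(h1) <- loci; names(h2) <- loci
    gd <- gamete_frequencies(phased_genotype(map, h1, h2), map, rule, sex)
    fert <- fert + zd$freq[i] * attr(gd, "fertility")
    gd$freq <- gd$freq * zd$freq[i]
    tabs[[i]] <- as.data.frame(gd)
  }
  out <- do.call(rbind, tabs)
  out <- stats::aggregate(freq ~ ., data = out, FUN = sum)
  out <- out[, c(loci, "freq")]
  structure(out, fertility = fert, map = map,
            class = c("gamete_dist", "data.frame"))
}

founder_zygote <- function(g, map) {
  nm <- map_locus_names(map)
  k1 <- paste(g$hap1[nm], collapse = ":")
  k2 <- paste(g$hap2[nm], collapse = ":")
  structure(data.frame(hap1 = min(k1, k2), hap2 = max(k1, k2), freq = 1,
                       stringsAsFactors = FALSE),
            map = map, loci = nm, class = c("zygote_dist", "data.frame"))
}

#' Resolve a cross design to exact genotype distributions
#'
#' Walks the design's steps analytically. Crosses and selfs propagate exact
#' surviving-gamete distributions (each parental genotype contributes gametes
#' in proportion to its population frequency); selection steps condition the
#' distribution on the predicate and renormalise.
#'
#' @param design a \code{\link{cross_design}}.
#' @param map,rule overrides for the design's own map and lethality rule.
#' @param all if TRUE return the named list of all population distributions,
#'   otherwise only the final one.
#' @return A \code{"zygote_dist"} (or a named list of them).
#' @examples
#' zd <- resolve_design(design_d60_f2())
#' expected_class_probabilities(zd, culm_classifier())
#' @export
resolve_design <- function(design, map = NULL, rule = NULL, all = FALSE) {
  map <- if (is.null(map)) design$map else map
  rule <- if (is.null(rule)) design$rule else rule
  pops <- lapply(design$founders, founder_zygote, map = map)
  for (s in design$steps) {
    pops[[s$name]] <- switch(
      s$op,
      cross = zygote_distribution(
        population_gametes(pops[[s$parents[1]]], map, rule, "female"),
        population_gametes(pops[[s$parents[2]]], map, rule, "male")),
      self = zygote_distribution(
        population_gametes(pops[[s$parents[1]]], map, rule, "female"),
        population_gametes(pops[[s$parents[1]]], map, rule, "male")),
      select = {
        zd <- pops[[s$parents[1]]]
        keep <- s$where(zygote_genotypes(zd))
        if (!any(keep))
          abort(sprintf("selection step '%s' matches no genotype", s$name),
                "seglethal_selection_failure")
        sub <- zd[keep, , drop = FALSE]
        sub$freq <- sub$freq / sum(sub$freq)
        structure(sub, map = map, loci = attr(zd, "loci"),
                  class = c("zygote_dist", "data.frame"))
      },
      abort(sprintf("unknown step op '%s'", s$op), "seglethal_invalid_design"))
  }
  if (all) pops else pops[[length(pops)]]
}

# ---- built-in study system: GW2 (grain size), D60 (semidwarfing), Gal ------

#' The GW2/d60/Gal study system
#'
#' Convenience builders for the three-locus system of the large-grain locus
#' \code{GW2} and the semidwarfing locus \code{D60} on chromosome 2 (linked,
#' default r = 0.176) plus the gametic lethal locus \code{Gal}, unlinked to
#' both by default. Donor alleles are \code{GW2} (Inochinoichi), \code{d60}
#' and \code{Gal} (the Hokuriku 100-derived semidwarf donor). The study rule
#' kills gametes of either sex carrying both \code{d60} and \code{gal}.
#'
#' @param r recombination fraction between \code{GW2} and \code{D60}.
#' @param gal_linked place \code{Gal} on chromosome 2 distal to \code{D60}
#'   with recombination fraction \code{r_d60_gal} (the default keeps it
#'   unlinked, which the observed 6:2:1 culm segregation requires).
#' @param r_d60_gal used only when \code{gal_linked} is TRUE.
#' @return \code{study_map}: a \code{\link{linkage_map}}; \code{study_rule}:
#'   a \code{\link{lethality_rule}}; founder helpers: phased genotypes.
#' @examples
#' study_map(r = 0.2)
#' founder_koshihikari()
#' @export
study_map <- function(r = 0.176, gal_linked = FALSE, r_d60_gal = 0.25) {
  loci <- list(locus("GW2", c("GW2", "gw2"), "chr2", 8.1),
               locus("D60", c("d60", "D60"), "chr2"),
               locus("Gal", c("Gal", "gal")))
  if (gal_linked)
    linkage_map(loci, groups = list(chr2 = c("GW2", "D60", "Gal")),
                r = list(chr2 = c(r, r_d60_gal)))
  else
    linkage_map(loci, groups = list(chr2 = c("GW2", "D60"), gal = "Gal"),
                r = list(chr2 = r, gal = numeric(0)))
}

#' @rdname study_map
#' @export
study_rule <- function() lethality_rule(list(c(D60 = "d60", Gal = "gal")))

hom <- function(map, gw2, d60, gal) {
  h <- c(GW2 = gw2, D60 = d60, Gal = gal)
  phased_genotype(map, h, h)
}

#' @rdname study_map
#' @param map linkage map the founder is defined over.
#' @export
founder_koshihikari <- function(map = study_map())
  hom(map, "gw2", "D60", "gal")

#' @rdname study_map
#' @export
founder_koshihikari_d60 <- function(map = study_map())
  hom(map, "gw2", "d60", "Gal")

#' @rdname study_map
#' @export
founder_inochinoichi <- function(map = study_map())
  hom(map, "GW2", "D60", "gal")

#' @rdname study_map
#' @details \code{founder_gw2_d60_donor} is the large-grain semidwarf
#'   segregant used as the non-recurrent parent of the combined-scheme
#'   backcrosses: homozygous \code{GW2 d60 Gal}, carrying the recombinant
#'   \code{GW2}-\code{d60} coupling haplotype.
#' @export
founder_gw2_d60_donor <- function(map = study_map())
  hom(map, "GW2", "d60", "Gal")

#' @rdname study_map
#' @details \code{study_f1_d60} is the F1 of Koshihikari d60 x Inochinoichi:
#'   \code{GW2.D60.gal / gw2.d60.Gal}, i.e. the partially sterile
#'   \code{D60d60 Galgal} type with 75% gamete survival under the study rule.
#' @export
study_f1_d60 <- function(map = study_map()) {
  phased_genotype(map, c(GW2 = "GW2", D60 = "D60", Gal = "gal"),
                       c(GW2 = "gw2", D60 = "d60", Gal = "Gal"))
}

#' Built-in study cross designs
#'
#' \describe{
#'   \item{\code{design_d60_f2}}{Koshihikari d60 x Inochinoichi, F1 selfed:
#'     the F2 whose culm classes segregate 6 long : 2 partially sterile :
#'     1 semidwarf under gamete lethality.}
#'   \item{\code{design_grain_f2}}{Koshihikari x Inochinoichi, F1 selfed: only
#'     \code{GW2} segregates (1:2:1 grain classes, no lethality expressed).}
#'   \item{\code{design_bc1f2}, \code{design_bc4f2}}{Koshihikari crossed to a
#'     homozygous \code{GW2 d60 Gal} donor line, F1 selfed. The F1 carries the
#'     donor alleles in coupling, so the semidwarf class is depleted of
#'     \code{gw2} in proportion to r. The two generations share this genetic
#'     structure and differ only in label and default population size (112 for
#'     BC1F2, 157 for BC4F2, the study's totals).}
#' }
#'
#' @param r recombination fraction between \code{GW2} and \code{D60}.
#' @param n final population size for the simulator.
#' @return A \code{\link{cross_design}}.
#' @examples
#' expected_class_probabilities(resolve_design(design_bc1f2()),
#'                              culm_classifier())
#' @export
design_bc1f2 <- function(r = 0.176, n = 112L) {
  map <- study_map(r)
  cross_design(
    founders = list(Koshihikari = founder_koshihikari(map),
                    donor = founder_gw2_d60_donor(map)),
    steps = list(step_cross("BC1F1", "Koshihikari", "donor", n = 1L),
                 step_self("BC1F2", "BC1F1", n = n)),
    map = map, rule = study_rule())
}

#' @rdname design_bc1f2
#' @export
design_bc4f2 <- function(r = 0.176, n = 157L) {
  map <- study_map(r)
  cross_design(
    founders = list(Koshihikari = founder_koshihikari(map),
                    donor = founder_gw2_d60_donor(map)),
    steps = list(step_cross("BC4F1", "Koshihikari", "donor", n = 1L),
                 step_self("BC4F2", "BC4F1", n = n)),
    map = map, rule = study_rule())
}

#' @rdname design_bc1f2
#' @export
design_d60_f2 <- function(r = 0.176, n = 112L) {
  map <- study_map(r)
  cross_design(
    founders = list(Koshihikari_d60 = founder_koshihikari_d60(map),
                    Inochinoichi = founder_inochinoichi(map)),
    steps = list(step_cross("F1", "Koshihikari_d60", "Inochinoichi", n = 1L),
                 step_self("F2", "F1", n = n)),
    map = map, rule = study_rule())
}

#' @rdname design_bc1f2
#' @details \code{design_d60_background_f2} is the BC2F2/BC3F2 structure of
#'   the combined scheme where Koshihikari d60 is the recurrent parent: the F1
#'   is homozygous \code{d60 Gal}, no lethal gamete class exists, and the
#'   grain locus segregates in an undistorted 1:2:1.
#' @export
design_d60_background_f2 <- function(r = 0.176, n = 94L) {
  map <- study_map(r)
  cross_design(
    founders = list(Koshihikari_d60 = founder_koshihikari_d60(map),
                    donor = founder_gw2_d60_donor(map)),
    steps = list(step_cross("F1", "Koshihikari_d60", "donor", n = 1L),
                 step_self("F2", "F1", n = n)),
    map = map, rule = study_rule())
}

#' @rdname design_bc1f2
#' @export
design_grain_f2 <- function(r = 0.176, n = 186L) {
  map <- study_map(r)
  cross_design(
    founders = list(Koshihikari = founder_koshihikari(map),
                    Inochinoichi = founder_inochinoichi(map)),
    steps = list(step_cross("F1", "Koshihikari", "Inochinoichi", n = 1L),
                 step_self("F2", "F1", n = n)),
    map = map, rule = study_rule())
}
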