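#' @keywords internal
abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "seglethal_error")))
}

#' Define a biallelic locus
#'
#' A locus carries exactly two alleles, given in (donor, recurrent) order:
#' the donor allele is the one introgressed from the non-recurrent parent
#' (e.g. the Inochinoichi \code{GW2} allele), the recurrent allele the one
#' carried by the recurrent backcross parent (e.g. Koshihikari \code{gw2}).
#'
#' @param name locus identifier, unique within a map.
#' @param alleles character(2), donor allele first.
#' @param chromosome chromosome identifier (optional).
#' @param pos_mb physical position in Mb from the chromosome end (optional).
#' @return An object of class \code{"locus"}.
#' @examples
#' locus("GW2", c("GW2", "gw2"), chromosome = "chr2", pos_mb = 8.1)
#' @export
locus <- function(name, alleles, chromosome = NA_character_, pos_mb = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length(alleles) != 2L || anyDuplicated(alleles))
    abort(sprintf("locus '%s' must have exactly two distinct alleles", name),
          "seglethal_invalid_locus")
  structure(list(name = name, alleles = as.character(alleles),
                 chromosome = chromosome, pos_mb = pos_mb),
            class = "locus")
}

#' Build a linkage map
#'
#' Loci are partitioned into linkage groups; within a group the order is fixed
#' and each adjacent pair has a recombination fraction r in [0, 0.5]. Loci in
#' different groups assort independently (equivalent to r = 0.5 between them).
#'
#' @param loci list of \code{\link{locus}} objects.
#' @param groups named list of character vectors giving the ordered locus names
#'   of each group. Defaults to one group per locus (all unlinked).
#' @param r named list parallel to \code{groups}: numeric vector of adjacent
#'   recombination fractions, length one less than the group size.
#' @return An object of class \code{"linkage_map"}.
#' @examples
#' m <- linkage_map(
#'   list(locus("GW2", c("GW2", "gw2")), locus("D60", c("d60", "D60")),
#'        locus("Gal", c("Gal", "gal"))),
#'   groups = list(chr2 = c("GW2", "D60"), galgrp = "Gal"),
#'   r = list(chr2 = 0.176, galgrp = numeric(0)))
#' @export
linkage_map <- function(loci, groups = NULL, r = NULL) {
  names(loci) <- vapply(loci, `[[`, "", "name")
  if (anyDuplicated(names(loci)))
    abort("locus names must be unique within a map", "seglethal_invalid_locus")
  if (is.null(groups)) {
    groups <- as.list(names(loci))
    names(groups) <- names(loci)
    r <- lapply(groups, function(g) numeric(0))
  }
  if (!setequal(unlist(groups), names(loci)) ||
      length(unlist(groups)) != length(loci))
    abort("groups must partition the map's loci", "seglethal_invalid_map")
  for (g in names(groups)) {
    k <- length(groups[[g]])
    rg <- if (is.null(r[[g]])) numeric(0) else r[[g]]
    if (length(rg) != k - 1L)
      abort(sprintf("group '%s' needs %d recombination fraction(s)", g, k - 1L),
            "seglethal_invalid_map")
    if (k > 1L && any(rg < 0 | rg > 0.5))
      abort("recombination fractions must lie in [0, 0.5]",
            "seglethal_invalid_map")
  }
  structure(list(loci = loci, groups = groups, r = r[names(groups)]),
            class = "linkage_map")
}

#' Ordered locus names of a linkage map
#' @param map a \code{\link{linkage_map}}.
#' @return Character vector of locus names in map order (group by group).
#' @export
map_locus_names <- function(map) unlist(map$groups, use.names = FALSE)

#' @export
print.linkage_map <- function(x, ...) {
  cat("Linkage map:", length(x$loci), "loci in", length(x$groups), "group(s)\n")
  for (g in names(x$groups)) {
    loci <- x$groups[[g]]
    line <- loci[1]
    if (length(loci) > 1)
      for (i in seq_along(x$r[[g]]))
        line <- paste0(line, " -(r=", format(x$r[[g]][i]), ")- ", loci[i + 1])
    cat(" ", g, ":", line, "\n")
  }
  invisible(x)
}

#' Phased multilocus genotype
#'
#' An individual's two haplotypes over all loci of a map. Phase matters:
#' \code{GW2.d60.Gal / gw2.D60.gal} (coupling of the donor alleles) produces
#' different gamete frequencies than the repulsion arrangement.
#'
#' @param map a \code{\link{linkage_map}}.
#' @param hap1,hap2 named character vectors, one allele per locus of the map.
#' @return An object of class \code{"phased_genotype"}.
#' @examples
#' m <- study_map()
#' f1 <- phased_genotype(m, c(GW2 = "GW2", D60 = "d60", Gal = "Gal"),
#'                          c(GW2 = "gw2", D60 = "D60", Gal = "gal"))
#' @export
phased_genotype <- function(map, hap1, hap2) {
  nm <- map_locus_names(map)
  for (h in list(hap1, hap2)) {
    if (!setequal(names(h), nm))
      abort("haplotypes must cover exactly the map's loci",
            "seglethal_invalid_genotype")
    for (loc in nm)
      if (!h[[loc]] %in% map$loci[[loc]]$alleles)
        abort(sprintf("allele '%s' is not legal for locus '%s'", h[[loc]], loc),
              "seglethal_invalid_genotype")
  }
  structure(list(hap1 = hap1[nm], hap2 = hap2[nm], map = map),
            class = "phased_genotype")
}

#' @export
print.phased_genotype <- function(x, ...) {
  cat(paste(x$hap1, collapse = "."), "/", paste(x$hap2, collapse = "."), "\n")
  invisible(x)
}

#' Gamete lethality rule
#'
#' Declares allele combinations that render a gamete inviable. A gamete dies
#' if, for any combination, it carries every listed allele. The default study
#' rule kills gametes carrying both \code{d60} and \code{gal} in both sexes,
#' which reduces pollen and seed fertility of the double heterozygote to 75%.
#'
#' @param combos list of named character vectors (locus name -> lethal allele);
#'   each combination must name at least two distinct loci.
#' @param sex which gametic sex the rule applies to.
#' @return An object of class \code{"lethality_rule"}.
#' @examples
#' lethality_rule(list(c(D60 = "d60", Gal = "gal")))
#' @export
lethality_rule <- function(combos, sex = c("both", "male", "female")) {
  sex <- match.arg(sex)
  for (cb in combos) {
    if (is.null(names(cb)) || anyDuplicated(names(cb)) || length(cb) < 2L)
      abort("each lethal combination must name >= 2 distinct loci",
            "seglethal_invalid_rule")
  }
  structure(list(combos = combos, sex = sex), class = "lethality_rule")
}
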