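#' Phenotype classifiers
#'
#' A classifier maps a multilocus genotype to a phenotype class label.
#' \code{culm_classifier} implements the culm-type rule of the d60/gal system:
#' semidwarf iff homozygous \code{d60d60}; partially sterile iff
#' \code{D60d60 Galgal} (the F1-type genotype, whose gametes are 25% lethal);
#' long culm otherwise. \code{grain_classifier} implements the grain-size rule
#' of the incompletely dominant large-grain locus: large iff \code{GW2GW2},
#' medium iff heterozygous, small iff \code{gw2gw2}; in \code{"complete"}
#' dominance mode carriers are pooled into \code{"large"}.
#'
#' @param d60_locus,gal_locus,gw2_locus locus names used by the rule.
#' @param d60_allele,gal_allele,large_allele the relevant allele symbols.
#' @param mode dominance mode for the grain rule.
#' @return An object of class \code{"phenotype_classifier"}: a list with
#'   \code{name}, \code{loci}, \code{labels} and a vectorised \code{fun} taking
#'   a data frame of per-locus genotype strings.
#' @examples
#' cl <- culm_classifier()
#' gr <- grain_classifier()
#' @name classifiers
NULL

new_classifier <- function(name, loci, labels, fun) {
  structure(list(name = name, loci = loci, labels = labels, fun = fun),
            class = "phenotype_classifier")
}

#' @rdname classifiers
#' @export
culm_classifier <- function(d60_locus = "D60", gal_locus = "Gal",
                            d60_allele = "d60", gal_allele = "gal") {
  new_classifier(
    "culm", c(d60_locus, gal_locus),
    c("semidwarf", "partially_sterile", "long_culm"),
    function(geno) {
      d <- count_allele(geno[[d60_locus]], d60_allele)
      g <- count_allele(geno[[gal_locus]], gal_allele)
      # F1 type D60d60 Galgal (het at both) sheds 25% lethal gametes
      ifelse(d == 2L, "semidwarf",
             ifelse(d == 1L & g == 1L, "partially_sterile", "long_culm"))
    })
}

#' @rdname classifiers
#' @export
grain_classifier <- function(mode = c("incomplete", "complete"),
                             gw2_locus = "GW2", large_allele = "GW2") {
  mode <- match.arg(mode)
  labels <- if (mode == "incomplete") c("large", "medium", "small")
            else c("large", "small")
  new_classifier(
    "grain", gw2_locus, labels,
    function(geno) {
      n <- count_allele(geno[[gw2_locus]], large_allele)
      if (mode == "incomplete")
        c("small", "medium", "large")[n + 1L]
      else
        ifelse(n > 0L, "large", "small")
    })
}

#' @rdname classifiers
#' @param a,b classifiers to combine into joint (interaction) classes.
#' @export
joint_classifier <- function(a, b) {
  labels <- as.vector(outer(a$labels, b$labels, paste, sep = ":"))
  new_classifier(
    paste(a$name, b$name, sep = ":"), union(a$loci, b$loci), labels,
    function(geno) paste(a$fun(geno), b$fun(geno), sep = ":"))
}

count_allele <- function(geno_str, allele) {
  parts <- strsplit(geno_str, "/", fixed = TRUE)
  vapply(parts, function(p) sum(p == allele), 0L)
}

#' Classify genotypes into phenotype classes
#'
#' @param genotype a named list or one-row data frame of per-locus genotype
#'   strings (\code{"GW2/gw2"} style), or a \code{"zygote_dist"} (all rows
#'   classified at once).
#' @param classifier a \code{"phenotype_classifier"}.
#' @return Character vector of class labels.
#' @examples
#' classify(list(D60 = "d60/d60", Gal = "Gal/Gal"), culm_classifier())
#' @export
classify <- function(genotype, classifier) {
  if (inherits(genotype, "zygote_dist")) genotype <- zygote_genotypes(genotype)
  if (!is.data.frame(genotype))
    genotype <- as.data.frame(genotype, stringsAsFactors = FALSE)
  missing <- setdiff(classifier$loci, names(genotype))
  if (length(missing))
    abort(sprintf("genotype does not cover classifier locus/loci: %s",
                  paste(missing, collapse = ", ")),
          "seglethal_classification")
  lab <- classifier$fun(genotype)
  if (anyNA(lab))
    abort("classifier is not total over the supplied genotypes",
          "seglethal_classification")
  lab
}

#' Expected phenotype-class probabilities of a cross
#'
#' Resolves a cross design (or an already-resolved zygote distribution) to its
#' final genotype distribution and aggregates it into phenotype-class
#' probabilities. Joint classes (e.g. culm x grain) are obtained with
#' \code{\link{joint_classifier}}.
#'
#' @param x a \code{\link{cross_design}} or a \code{"zygote_dist"}.
#' @param classifier a \code{"phenotype_classifier"}.
#' @param map,rule forwarded to \code{\link{resolve_design}} when \code{x} is
#'   a design.
#' @return Data frame with columns \code{class} (every classifier label, in
#'   label order) and \code{prob}, summing to 1.
#' @examples
#' zd <- resolve_design(design_bc1f2())
#' expected_class_probabilities(zd, culm_classifier())  # 1/9, 2/9, 6/9
#' @export
expected_class_probabilities <- function(x, classifier, map = NULL, rule = NULL) {
  zd <- if (inherits(x, "zygote_dist")) x else resolve_design(x, map, rule)
  lab <- classify(zd, classifier)
  p <- vapply(classifier$labels,
              function(l) sum(zd$freq[lab == l]), numeric(1))
  extra <- setdiff(unique(lab), classifier$labels)
  if (length(extra))
    abort("classifier produced labels outside its declared label set",
          "seglethal_classification")
  data.frame(class = classifier$labels, prob = unname(p),
             stringsAsFactors = FALSE)
}
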