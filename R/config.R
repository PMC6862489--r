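#' Read a cross design from a YAML configuration file
#'
#' The configuration mirrors the package's objects: a \code{loci} list
#' (name, alleles in donor-first order, optional chromosome and pos_mb),
#' \code{groups}/\code{r} for the linkage map, an optional \code{lethal}
#' block (sex plus a list of allele combinations), \code{founders} given as
#' two haplotypes each, and ordered \code{steps} (\code{cross}, \code{self},
#' \code{select}; population sizes under the key \code{size}, since a bare
#' \code{n} is a YAML 1.1 boolean). Selection predicates are expressed as a
#' named genotype
#' pattern, e.g. \code{where: \{GW2: "GW2/GW2", D60: "d60/d60"\}}.
#'
#' @param path YAML file path.
#' @return A \code{\link{cross_design}} carrying its map and lethality rule.
#' @examples
#' cfg <- system.file("extdata", "bc1f2_design.yaml", package = "seglethal")
#' d <- read_design(cfg)
#' resolve_design(d)
#' @export
read_design <- function(path) {
  if (!file.exists(path))
    abort(sprintf("design file '%s' not found", path), "seglethal_config")
  cfg <- yaml::read_yaml(path)
  for (field in c("loci", "founders", "steps"))
    if (is.null(cfg[[field]]))
      abort(sprintf("design file lacks required field '%s'", field),
            "seglethal_config")
  loci <- lapply(cfg$loci, function(l)
    locus(l$name, unlist(l$alleles),
          chromosome = if (is.null(l$chromosome)) NA_character_ else l$chromosome,
          pos_mb = if (is.null(l$pos_mb)) NA_real_ else l$pos_mb))
  groups <- if (is.null(cfg$groups)) NULL else lapply(cfg$groups, unlist)
  r <- if (is.null(cfg$r)) NULL else
    lapply(cfg$r, function(x) as.numeric(unlist(x)))
  map <- linkage_map(loci, groups = groups, r = r)
  rule <- NULL
  if (!is.null(cfg$lethal)) {
    combos <- lapply(cfg$lethal$combos, unlist)
    sex <- if (is.null(cfg$lethal$sex)) "both" else cfg$lethal$sex
    rule <- lethality_rule(combos, sex = sex)
  }
  founders <- lapply(cfg$founders, function(f)
    phased_genotype(map, unlist(f$hap1), unlist(f$hap2)))
  steps <- lapply(cfg$steps, function(s) {
    # the key is called 'size' because bare 'n' is a YAML 1.1 boolean
    n <- if (is.null(s$size)) 100L else as.integer(s$size)
    switch(s$op,
      cross = step_cross(s$name, s$female, s$male, n = n),
      self = step_self(s$name, s$parent, n = n),
      select = {
        pattern <- unlist(s$where)
        step_select(s$name, s$parent, genotype_predicate(pattern))
      },
      abort(sprintf("unknown step op '%s' in design file", s$op),
            "seglethal_config"))
  })
  cross_design(founders, steps, map, rule)
}

#' Selection predicate from a genotype pattern
#'
#' @param pattern named character vector, locus name -> required genotype
#'   string (donor-first, e.g. \code{"GW2/GW2"}).
#' @return A predicate function over a per-locus genotype data frame,
#'   suitable for \code{\link{step_select}}.
#' @examples
#' p <- genotype_predicate(c(D60 = "d60/d60"))
#' @export
genotype_predicate <- function(pattern) {
  force(pattern)
  function(geno) {
    keep <- rep(TRUE, nrow(geno))
    for (loc in names(pattern)) {
      if (is.null(geno[[loc]]))
        abort(sprintf("selection pattern names unknown locus '%s'", loc),
              "seglethal_config")
      keep <- keep & geno[[loc]] == pattern[[loc]]
    }
    keep
  }
}
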