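#' Surviving-gamete haplotype distribution of a phased parent
#'
#' Enumerates the gamete haplotypes a parent produces under independent
#' assortment between linkage groups and, within a group, crossovers between
#' adjacent loci with the map's recombination fractions (no interference).
#' Haplotypes matching a lethality rule are removed; the remainder is
#' renormalised, and the pre-lethality surviving fraction is reported as the
#' parent's fertility.
#'
#' @param parent a \code{\link{phased_genotype}}.
#' @param map a \code{\link{linkage_map}}; defaults to the parent's own map.
#' @param rule a \code{\link{lethality_rule}} or NULL for no lethality.
#' @param sex the gametic sex being produced; the rule is applied only when its
#'   \code{sex} field is \code{"both"} or equals this value.
#' @return A \code{"gamete_dist"}: a data frame with one allele column per
#'   locus plus \code{freq} (summing to 1), with attributes \code{fertility}
#'   (surviving fraction before renormalisation) and \code{map}.
#' @examples
#' gd <- gamete_frequencies(study_f1_d60(), rule = study_rule())
#' attr(gd, "fertility")  # 0.75 for the D60d60 Galgal heterozygote
#' @export
gamete_frequencies <- function(parent, map = parent$map, rule = NULL,
                               sex = c("both", "female", "male")) {
  sex <- match.arg(sex)
  if (!inherits(parent, "phased_genotype"))
    abort("parent must be a phased_genotype", "seglethal_invalid_genotype")
  nm <- map_locus_names(map)
  if (!setequal(names(parent$hap1), nm))
    abort("parent is not defined over the map's loci",
          "seglethal_invalid_genotype")
  for (loc in nm)
    for (a in c(parent$hap1[[loc]], parent$hap2[[loc]]))
      if (!a %in% map$loci[[loc]]$alleles)
        abort(sprintf("allele '%s' is not legal for locus '%s'", a, loc),
              "seglethal_invalid_genotype")

  # per linkage group: enumerate the strand-of-origin assignment of each locus
  group_tab <- lapply(names(map$groups), function(g) {
    loci <- map$groups[[g]]
    k <- length(loci)
    src <- as.matrix(expand.grid(rep(list(1:2), k)))
    pr <- rep(0.5, nrow(src))
    if (k > 1L) {
      rg <- map$r[[g]]
      for (i in seq_len(k - 1L)) {
        same <- src[, i] == src[, i + 1L]
        pr <- pr * ifelse(same, 1 - rg[i], rg[i])
      }
    }
    al <- matrix("", nrow(src), k, dimnames = list(NULL, loci))
    for (j in seq_len(k)) {
      both <- c(parent$hap1[[loci[j]]], parent$hap2[[loci[j]]])
      al[, j] <- both[src[, j]]
    }
    df <- as.data.frame(al, stringsAsFactors = FALSE)
    df$freq <- pr
    df
  })

  # independent assortment between groups: cross join
  out <- Reduce(function(a, b) {
    ia <- rep(seq_len(nrow(a)), times = nrow(b))
    ib <- rep(seq_len(nrow(b)), each = nrow(a))
    cbind(a[ia, setdiff(names(a), "freq"), drop = FALSE],
          b[ib, setdiff(names(b), "freq"), drop = FALSE],
          freq = a$freq[ia] * b$freq[ib])
  }, group_tab)
  out <- out[, c(nm, "freq")]
  out <- stats::aggregate(freq ~ ., data = out, FUN = sum)
  out <- out[out$freq > 0, c(nm, "freq")]  # drop structural zeros (r = 0)

  fertility <- 1
  if (!is.null(rule) && (rule$sex == "both" || rule$sex == sex)) {
    lethal <- rep(FALSE, nrow(out))
    for (cb in rule$combos) {
      loc_in <- intersect(names(cb), nm)
      if (length(loc_in) < length(cb)) next   # combo loci absent from this map
      hit <- rep(TRUE, nrow(out))
      for (loc in names(cb)) hit <- hit & out[[loc]] == cb[[loc]]
      lethal <- lethal | hit
    }
    fertility <- 1 - sum(out$freq[lethal])
    out <- out[!lethal, , drop = FALSE]
    if (fertility <= 0)
      abort("lethality rule removes all gametes", "seglethal_invalid_rule")
    out$freq <- out$freq / fertility
  }
  rownames(out) <- NULL
  structure(out, fertility = fertility, map = map,
            class = c("gamete_dist", "data.frame"))
}

hap_key <- function(df, loci) {
  do.call(paste, c(unname(as.list(df[, loci, drop = FALSE])), sep = ":"))
}

#' Zygote genotype distribution from two gamete pools
#'
#' Forms the outer product of female and male surviving-gamete frequencies and
#' aggregates the result into unordered phased genotypes (reciprocal
#' heterozygotes are pooled: parental origin of a haplotype is not tracked).
#'
#' @param female,male \code{"gamete_dist"} objects over the same locus set.
#' @return A \code{"zygote_dist"}: data frame with columns \code{hap1},
#'   \code{hap2} (colon-separated allele strings, lexicographically ordered
#'   pair) and \code{freq} summing to 1; attribute \code{map}.
#' @examples
#' gd <- gamete_frequencies(study_f1_d60(), rule = study_rule())
#' zd <- zygote_distribution(gd, gd)  # selfed F1 under gamete lethality
#' @export
zygote_distribution <- function(female, male) {
  loci_f <- setdiff(names(female), "freq")
  loci_m <- setdiff(names(male), "freq")
  if (!identical(loci_f, loci_m))
    abort("female and male gamete distributions cover different locus sets",
          "seglethal_incompatible_gametes")
  kf <- hap_key(female, loci_f)
  km <- hap_key(male, loci_m)
  i <- rep(seq_along(kf), times = length(km))
  j <- rep(seq_along(km), each = length(kf))
  h1 <- pmin(kf[i], km[j])
  h2 <- pmax(kf[i], km[j])
  fr <- female$freq[i] * male$freq[j]
  key <- paste(h1, h2, sep = "|")
  agg <- rowsum(fr, key)
  parts <- strsplit(rownames(agg), "|", fixed = TRUE)
  out <- data.frame(hap1 = vapply(parts, `[`, "", 1L),
                    hap2 = vapply(parts, `[`, "", 2L),
                    freq = as.numeric(agg), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out[order(out$hap1, out$hap2), ],
            map = attr(female, "map"), loci = loci_f,
            class = c("zygote_dist", "data.frame"))
}

#' Per-locus genotypes of a zygote distribution
#'
#' Expands the haplotype-pair representation into one unordered genotype
#' string per locus, donor allele written first (\code{"GW2/gw2"}).
#'
#' @param zd a \code{"zygote_dist"}.
#' @return Data frame with one genotype column per locus plus \code{freq}.
#' @export
zygote_genotypes <- function(zd) {
  loci <- attr(zd, "loci")
  map <- attr(zd, "map")
  a1 <- do.call(rbind, strsplit(zd$hap1, ":", fixed = TRUE))
  a2 <- do.call(rbind, strsplit(zd$hap2, ":", fixed = TRUE))
  cols <- list()
  for (j in seq_along(loci)) {
    ord <- map$loci[[loci[j]]]$alleles  # donor allele first
    g1 <- a1[, j]; g2 <- a2[, j]
    donor_first <- match(g1, ord) <= match(g2, ord)
    cols[[loci[j]]] <- paste(ifelse(donor_first, g1, g2),
                             ifelse(donor_first, g2, g1), sep = "/")
  }
  cols$freq <- zd$freq
  as.data.frame(cols, stringsAsFactors = FALSE)
}
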