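`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force oracle for surviving-gamete distributions.
# Enumerates, per linkage group, the starting parental strand and every
# per-interval crossover indicator vector, builds each gamete haplotype
# cumulatively, and multiplies probabilities; groups are combined by
# exhaustive cartesian product. Lethality is applied by direct string
# matching. Written deliberately apart from the package's strand-assignment
# algorithm.
oracle_gametes <- function(parent, map, rule = NULL) {
  per_group <- lapply(names(map$groups), function(g) {
    loci <- map$groups[[g]]
    k <- length(loci)
    rg <- map$r[[g]]
    combos <- expand.grid(rep(list(0:1), k - 1L + 1L))  # start strand + xovers
    haps <- character(0)
    probs <- numeric(0)
    for (i in seq_len(nrow(combos))) {
      strand <- combos[i, 1] + 1L
      p <- 0.5
      al <- character(k)
      for (j in seq_len(k)) {
        if (j > 1L) {
          xo <- combos[i, j]
          p <- p * if (xo == 1) rg[j - 1L] else 1 - rg[j - 1L]
          if (xo == 1) strand <- 3L - strand
        }
        al[j] <- if (strand == 1L) parent$hap1[[loci[j]]]
                 else parent$hap2[[loci[j]]]
      }
      haps <- c(haps, paste(al, collapse = ":"))
      probs <- c(probs, p)
    }
    list(loci = loci, haps = haps, probs = probs)
  })
  haps <- per_group[[1]]$haps
  probs <- per_group[[1]]$probs
  loci <- per_group[[1]]$loci
  for (grp in per_group[-1]) {
    haps <- as.vector(outer(haps, grp$haps, paste, sep = ":"))
    probs <- as.vector(outer(probs, grp$probs, `*`))
    loci <- c(loci, grp$loci)
  }
  freq <- tapply(probs, haps, sum)
  if (!is.null(rule)) {
    allele_lists <- strsplit(names(freq), ":", fixed = TRUE)
    lethal <- vapply(allele_lists, function(al) {
      names(al) <- loci
      any(vapply(rule$combos, function(cb)
        all(al[names(cb)] == cb), logical(1)))
    }, logical(1))
    fert <- 1 - sum(freq[lethal])
    freq <- freq[!lethal] / fert
  } else fert <- 1
  # return in the package's map order for direct comparison
  ord <- map_locus_names(map)
  reorder_key <- vapply(strsplit(names(freq), ":", fixed = TRUE), function(al) {
    names(al) <- loci
    paste(al[ord], collapse = ":")
  }, "")
  list(freq = stats::setNames(as.numeric(freq), reorder_key), fertility = fert)
}

# keyed frequencies of a package gamete_dist, for comparison with the oracle
gd_freqs <- function(gd) {
  loci <- setdiff(names(gd), "freq")
  stats::setNames(gd$freq, do.call(paste, c(gd[loci], sep = ":")))
}

# random k-locus map: first group holds `linked` loci, the rest unlinked
random_map <- function(k, linked = k) {
  loci <- lapply(seq_len(k), function(i)
    locus(paste0("L", i), c(paste0("A", i), paste0("a", i))))
  groups <- list(g1 = paste0("L", seq_len(linked)))
  if (linked < k)
    for (i in seq(linked + 1L, k)) groups[[paste0("g", i)]] <- paste0("L", i)
  r <- lapply(groups, function(g) stats::runif(max(length(g) - 1L, 0L), 0, 0.5))
  linkage_map(loci, groups = groups, r = r)
}

random_parent <- function(map) {
  nm <- map_locus_names(map)
  pick <- function() vapply(nm, function(l)
    sample(map$loci[[l]]$alleles, 1L), "")
  phased_genotype(map, pick(), pick())
}

# two-locus D60/Gal map for the minimal lethality examples
d60_gal_map <- function() {
  linkage_map(list(locus("D60", c("d60", "D60")), locus("Gal", c("Gal", "gal"))))
}

expect_freqs_equal <- function(gd, expected, tol = 1e-12) {
  got <- gd_freqs(gd)
  expect_setequal(names(got), names(expected))
  expect_equal(got[names(expected)], expected, tolerance = tol)
}
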