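new_recomb_estimate <- function(r_hat, estimator, n_gametes,
                                support = NULL, flags = character(0)) {
  structure(list(r_hat = r_hat, value = 100 * r_hat, estimator = estimator,
                 n_gametes = n_gametes, support = support, flags = flags),
            class = "recomb_estimate")
}

#' @export
print.recomb_estimate <- function(x, ...) {
  cat(sprintf("Recombination value = %.1f (r = %.4f, %s, %d gametes)\n",
              x$value, x$r_hat, x$estimator, x$n_gametes))
  if (!is.null(x$support))
    cat(sprintf("  1-unit support interval: [%.4f, %.4f]\n",
                x$support[1], x$support[2]))
  for (f in x$flags) cat("  flag:", f, "\n")
  invisible(x)
}

#' Recessive-class counting estimator of the recombination fraction
#'
#' For a class in which every individual contributes two independently
#' scoreable gametes (the d60d60 semidwarf class of the backcross F2s, or the
#' recessive grain class of a mapping F2), each heterozygote carries one
#' recombinant gamete and each recurrent-type homozygote two:
#' \deqn{\hat r = (n_{het} + 2 n_{rec}) / (2N).}
#' Selecting on the recessive class removes the lethality distortion, so
#' within it this is the conditional maximum-likelihood estimate.
#'
#' @param n_donor_homo,n_het,n_other_homo class counts (donor homozygous,
#'   heterozygous, opposite homozygous).
#' @return A \code{"recomb_estimate"}; \code{value} is 100 x r. Estimates
#'   above 50 are returned as-is but flagged with a phase warning.
#' @examples
#' counting_estimator(11, 6, 0)  # recombination value 17.6
#' @export
counting_estimator <- function(n_donor_homo, n_het, n_other_homo) {
  N <- n_donor_homo + n_het + n_other_homo
  if (N == 0) abort("empty class: no individuals to score",
                    "seglethal_empty_class")
  r_hat <- (n_het + 2 * n_other_homo) / (2 * N)
  flags <- character(0)
  if (r_hat > 0.5) {
    flags <- "estimate outside [0, 0.5]: check linkage phase"
    warning("counting estimate exceeds 0.5; loci may be in repulsion phase",
            call. = FALSE)
  }
  new_recomb_estimate(r_hat, "counting", 2L * N, flags = flags)
}

#' Maximum-likelihood recombination estimate from class counts
#'
#' Maximises the multinomial log-likelihood of observed class counts whose
#' expected probabilities are a function of r alone. The optimum is located on
#' a coarse grid, refined on a 1e-4 grid around the bracketing interval, then
#' polished with \code{stats::optimize}; ties break toward smaller r. A 1-unit
#' log-likelihood support interval is reported.
#'
#' @param observed named or unnamed vector of class counts.
#' @param prob_fun function of r returning class probabilities aligned with
#'   \code{observed}; typically built from a cross design, e.g.
#'   \code{\link{semidwarf_class_probs}} or \code{\link{design_class_probs}}.
#' @param lower,upper search range for r.
#' @return A \code{"recomb_estimate"} with support interval; flagged
#'   non-identifiable (with a warning) when the likelihood is flat.
#' @examples
#' ml_estimator(c(11, 6, 0), semidwarf_class_probs)  # r_hat 0.176
#' @export
ml_estimator <- function(observed, prob_fun, lower = 0, upper = 0.5) {
  if (sum(observed) == 0)
    abort("empty class: no individuals to score", "seglethal_empty_class")
  ll <- function(r) {
    p <- prob_fun(r)
    if (length(p) != length(observed))
      abort("prob_fun must return one probability per observed class",
            "seglethal_invalid_table")
    keep <- observed > 0
    if (any(p[keep] <= 0)) return(-Inf)
    sum(observed[keep] * log(p[keep]))
  }
  coarse <- seq(lower, upper, by = 5e-3)
  lc <- vapply(coarse, ll, numeric(1))
  if (all(!is.finite(lc)) || max(lc) - min(lc[is.finite(lc)]) < 1e-9) {
    warning("likelihood is flat in r: classes are uninformative", call. = FALSE)
    return(new_recomb_estimate(lower, "ML", 2L * sum(observed),
                               flags = "non-identifiable: flat likelihood"))
  }
  i <- which.max(lc)                      # which.max takes the first maximum
  lo <- max(lower, coarse[i] - 5e-3)
  hi <- min(upper, coarse[i] + 5e-3)
  fine <- seq(lo, hi, by = 1e-4)
  lf <- vapply(fine, ll, numeric(1))
  j <- which.max(lf)
  lo2 <- max(lower, fine[j] - 1e-4)
  hi2 <- min(upper, fine[j] + 1e-4)
  opt <- stats::optimize(ll, c(lo2, hi2), maximum = TRUE, tol = 1e-9)
  r_hat <- if (opt$objective >= lf[j]) opt$maximum else fine[j]
  if (ll(lower) >= ll(r_hat)) r_hat <- lower   # ties toward smaller r
  ll_max <- ll(r_hat)
  # 1-unit support interval: where log-likelihood stays within 1 of the max
  drop1 <- function(r) ll(r) - (ll_max - 1)
  s_lo <- lower
  if (r_hat > lower && drop1(lower) < 0)
    s_lo <- stats::uniroot(drop1, c(lower, r_hat), tol = 1e-6)$root
  s_hi <- upper
  if (r_hat < upper && drop1(upper) < 0)
    s_hi <- stats::uniroot(drop1, c(r_hat, upper), tol = 1e-6)$root
  new_recomb_estimate(r_hat, "ML", 2L * sum(observed),
                      support = c(s_lo, s_hi))
}

#' Class-probability functions of r
#'
#' \code{semidwarf_class_probs} gives the conditional distribution of the
#' \code{GW2} genotype within the d60d60 semidwarf class of a coupling-phase
#' F2 under the d60/gal lethality rule: among surviving d60-bearing gametes
#' the recurrent \code{gw2} allele has probability r, so the class segregates
#' \eqn{(1-r)^2 : 2r(1-r) : r^2} (donor homozygote : heterozygote : recurrent
#' homozygote). \code{design_class_probs} builds the analogous function for
#' any design/classifier pair by resolving the design at each r.
#'
#' @param r recombination fraction.
#' @return \code{semidwarf_class_probs}: numeric(3). \code{design_class_probs}:
#'   a function of r returning probabilities in the classifier's label order.
#' @examples
#' semidwarf_class_probs(0.176)
#' @export
semidwarf_class_probs <- function(r) c((1 - r)^2, 2 * r * (1 - r), r^2)

#' @rdname semidwarf_class_probs
#' @param design_fun function of r returning a \code{\link{cross_design}},
#'   e.g. \code{design_bc4f2}.
#' @param classifier a \code{"phenotype_classifier"}.
#' @export
design_class_probs <- function(design_fun, classifier) {
  function(r)
    expected_class_probabilities(resolve_design(design_fun(r)), classifier)$prob
}

#' Marker-trait recombination from a recessive-class genotype table
#'
#' For each marker scored in trait-homozygous recessive-class segregants
#' (e.g. small-grain \code{gw2gw2} F2 plants), counts gametes recombinant
#' between marker and trait locus. Under complete linkage every individual is
#' homozygous for the recurrent-side marker allele; heterozygotes carry one
#' donor-side (recombinant) gamete and donor homozygotes two.
#'
#' @param table data frame with one row per individual: an optional \code{id}
#'   column plus one column per marker holding codes from \code{codes}
#'   (NA allowed; per-marker N is reduced and reported).
#' @param marker_info optional data frame (\code{marker}, \code{chromosome},
#'   \code{pos_mb}) used to order the output by position.
#' @param codes named character(3): codes meaning donor homozygote,
#'   heterozygote, recurrent homozygote.
#' @return Data frame with one row per marker: \code{marker}, \code{pos_mb},
#'   \code{n} (individuals scored), \code{n_missing}, \code{value}
#'   (recombination value, 100 x r) and \code{r_hat}; sorted by position when
#'   known.
#' @examples
#' tab <- data.frame(M1 = c("R", "R", "H"), M2 = c("H", "R", "D"))
#' marker_trait_recombination(tab)
#' @export
marker_trait_recombination <- function(table, marker_info = NULL,
                                       codes = c(donor = "D", het = "H",
                                                 recurrent = "R")) {
  markers <- setdiff(names(table), "id")
  rows <- lapply(markers, function(m) {
    g <- table[[m]]
    bad <- !is.na(g) & !g %in% codes
    if (any(bad))
      abort(sprintf("marker '%s' has codes outside {%s}", m,
                    paste(codes, collapse = ",")), "seglethal_invalid_table")
    n_missing <- sum(is.na(g))
    g <- g[!is.na(g)]
    if (!length(g))
      abort(sprintf("marker '%s' has no scored individuals", m),
            "seglethal_empty_class")
    est <- counting_estimator(n_donor_homo = sum(g == codes[["recurrent"]]),
                              n_het = sum(g == codes[["het"]]),
                              n_other_homo = sum(g == codes[["donor"]]))
    data.frame(marker = m, pos_mb = NA_real_, n = length(g),
               n_missing = n_missing, value = est$value, r_hat = est$r_hat,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(marker_info)) {
    out$pos_mb <- marker_info$pos_mb[match(out$marker, marker_info$marker)]
    out <- out[order(out$pos_mb), ]
    rownames(out) <- NULL
  }
  out
}

#' Haldane map function
#'
#' Converts map distance in centimorgans to a recombination fraction under
#' the no-interference Poisson crossover model, and back:
#' \eqn{r = (1 - e^{-2d/100})/2}, \eqn{d = -50 \log(1 - 2r)}.
#'
#' @param d_cm map distance in cM (>= 0).
#' @param r recombination fraction in [0, 0.5).
#' @return \code{haldane_r}: r; \code{haldane_d}: distance in cM.
#' @examples
#' haldane_d(0.176)   # 21.7 cM
#' haldane_r(21.69)
#' @export
haldane_r <- function(d_cm) {
  if (any(d_cm < 0)) abort("map distance must be non-negative",
                           "seglethal_invalid_map")
  (1 - exp(-2 * d_cm / 100)) / 2
}

#' @rdname haldane_r
#' @export
haldane_d <- function(r) {
  if (any(r < 0 | r >= 0.5))
    abort("r >= 0.5 corresponds to infinite map distance",
          "seglethal_infinite_distance")
  -50 * log(1 - 2 * r)
}
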