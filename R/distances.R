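#' Allele-sharing distance between individual samples
#'
#' For each pair of samples, over loci where both calls are non-missing,
#' the per-locus identity-by-state share is (2 - |c_i - c_j|) / 2 for allele
#' counts c; the distance is one minus the mean share (plink `--distance
#' 1-ibs` semantics). A pair with no overlapping non-missing loci is an
#' error.
#'
#' @param g a [genotype_matrix()].
#' @return symmetric matrix over samples with attribute `kind =
#'   "allele_sharing"`; entries in \[0, 1\].
#' @export
allele_sharing_distance <- function(g) {
  if (nrow(g) < 2L) stop("need at least 2 samples")
  m <- unclass(g)
  if (!anyNA(m)) {
    d <- as.matrix(stats::dist(m, method = "manhattan")) / (2 * ncol(m))
  } else {
    n <- nrow(m)
    d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(n - 1L)) {
      xi <- m[i, ]
      for (j in (i + 1L):n) {
        ok <- !is.na(xi) & !is.na(m[j, ])
        if (!any(ok))
          stop("no overlapping non-missing loci for pair ",
               rownames(m)[i], " / ", rownames(m)[j])
        v <- mean(abs(xi[ok] - m[j, ok])) / 2
        d[i, j] <- v
        d[j, i] <- v
      }
    }
  }
  attr(d, "kind") <- "allele_sharing"
  d
}

## per-locus Weir-Cockerham (1984) variance components for two populations;
## gA, gB: genotype matrices restricted to the two populations' samples.
## Returns a data.frame with one row per locus: a, b, c, n1, n2, p1, p2.
wc_components <- function(gA, gB) {
  n1 <- colSums(!is.na(gA)); n2 <- colSums(!is.na(gB))
  p1 <- colSums(gA, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(gB, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(gA == 1L, na.rm = TRUE) / n1
  h2 <- colSums(gB == 1L, na.rm = TRUE) / n2
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  ## a locus is informative when both pops have data, within-pop df exist and
  ## the pooled sample is polymorphic
  ok <- n1 >= 1 & n2 >= 1 & nbar > 1 & pbar > 0 & pbar < 1
  a[!ok] <- 0; b[!ok] <- 0; cc[!ok] <- 0
  data.frame(locus = colnames(gA), a = a, b = b, c = cc,
             n1 = n1, n2 = n2, p1 = p1, p2 = p2,
             informative = ok, row.names = NULL)
}

#' Per-locus Weir-Cockerham variance components for two populations
#'
#' Exposes the among-population (a), among-individual-within-population (b)
#' and within-individual (c) components of the Weir & Cockerham (1984)
#' estimator at every locus, including the heterozygosity term. Loci
#' monomorphic across both populations (or lacking within-population degrees
#' of freedom) are marked non-informative and carry a = b = c = 0.
#'
#' @inheritParams classify_locus
#' @param popA,popB unit names.
#' @param unit_level `"subspecies"` or `"group"`.
#' @return `data.frame` with columns `locus`, `a`, `b`, `c`, `n1`, `n2`,
#'   `p1`, `p2`, `informative`.
#' @export
wc_fst_components <- function(g, sheet, popA, popB,
                              unit_level = c("subspecies", "group")) {
  unit_level <- match.arg(unit_level)
  sheet <- check_sheet(g, sheet)
  sa <- unit_samples(sheet, popA, unit_level)
  sb <- unit_samples(sheet, popB, unit_level)
  if (!length(sa)) stop("unknown unit: ", popA)
  if (!length(sb)) stop("unknown unit: ", popB)
  wc_components(unclass(g)[sa, , drop = FALSE], unclass(g)[sb, , drop = FALSE])
}

#' Weir-Cockerham F_ST between two populations
#'
#' Multi-locus ratio-of-sums estimator: theta-hat = sum(a) / sum(a + b + c)
#' over informative loci. The raw estimate is returned and may be negative.
#'
#' @inheritParams wc_fst_components
#' @return numeric scalar.
#' @export
wc_fst <- function(g, sheet, popA, popB,
                   unit_level = c("subspecies", "group")) {
  comp <- wc_fst_components(g, sheet, popA, popB, unit_level)
  denom <- sum(comp$a + comp$b + comp$c)
  if (!any(comp$informative) || denom == 0)
    stop("no informative loci between ", popA, " and ", popB)
  sum(comp$a) / denom
}

#' Pairwise F_ST distance matrix over populations
#'
#' Computes [wc_fst()] for every pair of units. For use as a dissimilarity
#' (neighbor joining requires non-negative input) negative estimates are
#' floored at zero when `floor_negative = TRUE`; flooring events are recorded
#' in the `"floored"` attribute. Raw estimates should be reported from
#' [wc_fst()] directly. Outgroup species are units like any other; they can
#' alternatively be pooled into a single `OUTGROUP` unit.
#'
#' @inheritParams classify_locus
#' @param unit_level `"subspecies"` or `"group"`.
#' @param pool_outgroups pool all outgroup samples into one unit.
#' @param floor_negative floor negative estimates at 0 (default TRUE).
#' @return symmetric matrix with attributes `kind = "fst"` and `floored`
#'   (logical matrix of flooring events).
#' @export
fst_matrix <- function(g, sheet, unit_level = c("subspecies", "group"),
                       pool_outgroups = FALSE, floor_negative = TRUE) {
  unit_level <- match.arg(unit_level)
  sh <- check_sheet(g, sheet)
  if (pool_outgroups) {
    og <- sh$group == "OUTGROUP"
    sh$subspecies[og] <- "OUTGROUP"
  }
  units <- unique(sh[[unit_level]])
  if (length(units) < 3L) stop("need at least 3 units")
  n <- length(units)
  d <- matrix(0, n, n, dimnames = list(units, units))
  fl <- matrix(FALSE, n, n, dimnames = list(units, units))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v <- wc_fst(g, sh, units[i], units[j], unit_level)
    if (floor_negative && v < 0) {
      fl[i, j] <- fl[j, i] <- TRUE
      v <- 0
    }
    d[i, j] <- d[j, i] <- v
  }
  attr(d, "kind") <- "fst"
  attr(d, "floored") <- fl
  d
}
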