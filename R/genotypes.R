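#' Construct a validated genotype matrix
#'
#' A genotype matrix stores diploid biallelic SNP calls as the count of the
#' alternate allele: 0 (homozygous reference), 1 (heterozygous), 2 (homozygous
#' alternate), or `NA` for a missing call. Rows are samples, columns are loci.
#' Haploid samples (e.g. drones) may be represented with calls restricted to
#' \{0, 2\}, a single allele counted twice; see the `ploidy` column of
#' [sample_sheet()].
#'
#' @param calls numeric or integer matrix, samples x loci, values in
#'   \{0, 1, 2, NA\}. Row names are sample ids, column names locus ids.
#' @return an integer matrix of class `genotype_matrix`.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, 0, NA, 2), nrow = 3,
#'   dimnames = list(c("s1", "s2", "s3"), c("l1", "l2"))))
#' @export
genotype_matrix <- function(calls) {
  if (!is.matrix(calls)) stop("'calls' must be a matrix")
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("'calls' must have sample row names and locus column names")
  if (anyDuplicated(rownames(calls))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(calls))) stop("duplicate locus ids")
  if (nrow(calls) < 2L) stop("need at least 2 samples")
  if (ncol(calls) < 1L) stop("need at least 1 locus")
  storage.mode(calls) <- "integer"
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) stop("genotype calls must be 0, 1, 2 or NA")
  allmiss <- colSums(!is.na(calls)) == 0L
  if (any(allmiss))
    stop("loci with all calls missing: ", paste(colnames(calls)[allmiss], collapse = ", "))
  class(calls) <- c("genotype_matrix", class(calls))
  calls
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x), "samples x", ncol(x), "loci;",
      sum(is.na(x)), "missing calls\n")
  invisible(x)
}

VALID_GROUPS <- c("M", "C", "O", "A", "OUTGROUP")

#' Construct a sample metadata sheet
#'
#' Maps each sample to a subspecies, a lineage group (one of `M`, `C`, `O`,
#' `A` for *A. mellifera* lineage groups, or `OUTGROUP` for samples from other
#' Apis species) and, for outgroup rows, a species name.
#'
#' @param sample character vector of sample ids.
#' @param subspecies character vector, subspecies (or outgroup taxon) name.
#' @param group character vector over \{M, C, O, A, OUTGROUP\}.
#' @param species optional character vector; species name for outgroup rows.
#' @param ploidy optional integer vector (1 or 2), defaults to diploid.
#' @return a `data.frame` of class `sample_sheet`.
#' @export
sample_sheet <- function(sample, subspecies, group, species = NA_character_,
                         ploidy = 2L) {
  df <- data.frame(sample = as.character(sample),
                   subspecies = as.character(subspecies),
                   group = as.character(group),
                   species = as.character(species),
                   ploidy = as.integer(ploidy),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample)) stop("duplicate sample ids in sheet")
  if (!all(df$group %in% VALID_GROUPS))
    stop("lineage group must be one of ", paste(VALID_GROUPS, collapse = ", "))
  if (!all(df$ploidy %in% 1:2)) stop("ploidy must be 1 or 2")
  class(df) <- c("sample_sheet", class(df))
  df
}

## every sample of g must have exactly one sheet row
check_sheet <- function(g, sheet) {
  miss <- setdiff(rownames(g), sheet$sample)
  if (length(miss))
    stop("samples missing from sheet: ", paste(miss, collapse = ", "))
  sheet[match(rownames(g), sheet$sample), , drop = FALSE]
}

unit_samples <- function(sheet, unit, unit_level) {
  sheet$sample[sheet[[unit_level]] == unit]
}

## a unit's calls at one locus show both alleles iff a het is present or both
## homozygote classes are
both_alleles_seen <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (!length(calls)) return(NA)
  any(calls == 1L) || (any(calls == 0L) && any(calls == 2L))
}

## set of distinct alleles (0 = ref, 1 = alt) carried by a call vector
alleles_seen <- function(calls) {
  calls <- calls[!is.na(calls)]
  out <- logical(2)
  out[1] <- any(calls < 2L)
  out[2] <- any(calls > 0L)
  out
}

#' Classify one locus within one unit
#'
#' A locus is *polymorphic* in a unit if both alleles are observed among the
#' unit's non-missing calls; *private* if additionally all other units (other
#' *A. mellifera* units; outgroup species are skipped) are monomorphic for a
#' single allele; *fixed private* if the unit is monomorphic for an allele
#' observed in no other unit. Polymorphic and fixed-private are disjoint
#' classifications.
#'
#' @param g a [genotype_matrix()].
#' @param sheet a [sample_sheet()].
#' @param locus locus id.
#' @param unit subspecies or group name.
#' @param unit_level `"subspecies"` or `"group"`.
#' @return logical vector `c(polymorphic, private, fixed_private)`, or all
#'   `NA` when the unit has no non-missing call at the locus.
#' @export
classify_locus <- function(g, sheet, locus, unit,
                           unit_level = c("subspecies", "group")) {
  unit_level <- match.arg(unit_level)
  sheet <- check_sheet(g, sheet)
  if (!locus %in% colnames(g)) stop("unknown locus: ", locus)
  own <- unit_samples(sheet, unit, unit_level)
  if (!length(own)) stop("unknown unit: ", unit)
  calls_unit <- g[own, locus]
  if (all(is.na(calls_unit)))
    return(c(polymorphic = NA, private = NA, fixed_private = NA))
  ## "elsewhere" = other A. mellifera units at the same level
  other <- sheet$sample[sheet[[unit_level]] != unit & sheet$group != "OUTGROUP"]
  other <- setdiff(other, own)
  calls_other <- g[other, locus]
  poly <- isTRUE(both_alleles_seen(calls_unit))
  other_alleles <- alleles_seen(calls_other)
  priv <- poly && sum(other_alleles) <= 1L
  fixed_priv <- FALSE
  if (!poly) {
    a <- alleles_seen(calls_unit) # monomorphic: exactly one TRUE
    fixed_priv <- any(a & !other_alleles)
  }
  c(polymorphic = poly, private = priv, fixed_private = fixed_priv)
}

## vectorized classification over all loci for one unit; returns a 3-row
## logical matrix (polymorphic / private / fixed_private), NA columns where
## the unit has no data
classify_unit_loci <- function(g, sheet, unit, unit_level) {
  own <- unit_samples(sheet, unit, unit_level)
  other <- sheet$sample[sheet[[unit_level]] != unit & sheet$group != "OUTGROUP"]
  other <- setdiff(other, own)
  gu <- g[own, , drop = FALSE]
  go <- g[other, , drop = FALSE]
  n_u <- colSums(!is.na(gu))
  het_u <- colSums(gu == 1L, na.rm = TRUE) > 0L
  ref_u <- colSums(gu < 2L, na.rm = TRUE) > 0L
  alt_u <- colSums(gu > 0L, na.rm = TRUE) > 0L
  poly <- het_u | (colSums(gu == 0L, na.rm = TRUE) > 0L &
                   colSums(gu == 2L, na.rm = TRUE) > 0L)
  ref_o <- colSums(go < 2L, na.rm = TRUE) > 0L
  alt_o <- colSums(go > 0L, na.rm = TRUE) > 0L
  other_mono <- (ref_o + alt_o) <= 1L
  priv <- poly & other_mono
  fixed_priv <- !poly & ((ref_u & !ref_o) | (alt_u & !alt_o))
  out <- rbind(polymorphic = poly, private = priv, fixed_private = fixed_priv)
  out[, n_u == 0L] <- NA
  out
}

#' Polymorphism-sharing table per subspecies and lineage group
#'
#' Counts, for every *A. mellifera* subspecies and for every lineage group
#' ("All group" rows), the loci that are polymorphic, private, and fixed
#' private within that unit. Outgroup species are excluded both as units and
#' from the "elsewhere" comparison. Loci at which a unit has no non-missing
#' call are excluded from that unit's counts.
#'
#' @inheritParams classify_locus
#' @return a `data.frame` with columns `group`, `unit`, `level`, `n_samples`,
#'   `n_loci_assayed`, `polymorphic`, `private`, `fixed_private`.
#' @export
polymorphism_table <- function(g, sheet) {
  sheet <- check_sheet(g, sheet)
  mel <- sheet[sheet$group != "OUTGROUP", , drop = FALSE]
  rows <- list()
  for (grp in intersect(c("M", "C", "O", "A"), unique(mel$group))) {
    subs <- unique(mel$subspecies[mel$group == grp])
    for (s in subs) {
      cl <- classify_unit_loci(g, sheet, s, "subspecies")
      rows[[length(rows) + 1L]] <- data.frame(
        group = grp, unit = s, level = "subspecies",
        n_samples = sum(mel$subspecies == s),
        n_loci_assayed = sum(!is.na(cl[1, ])),
        polymorphic = sum(cl[1, ], na.rm = TRUE),
        private = sum(cl[2, ], na.rm = TRUE),
        fixed_private = sum(cl[3, ], na.rm = TRUE))
    }
    cl <- classify_unit_loci(g, sheet, grp, "group")
    rows[[length(rows) + 1L]] <- data.frame(
      group = grp, unit = "All group", level = "group",
      n_samples = sum(mel$group == grp),
      n_loci_assayed = sum(!is.na(cl[1, ])),
      polymorphic = sum(cl[1, ], na.rm = TRUE),
      private = sum(cl[2, ], na.rm = TRUE),
      fixed_private = sum(cl[3, ], na.rm = TRUE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group-sharing spectrum of polymorphism
#'
#' Assigns each locus to the exact subset of lineage groups \{M, C, O, A\} in
#' which it is polymorphic; loci polymorphic in no group (e.g. fixed
#' differences against the outgroup only) fall into the `"none"` bucket.
#' Bucket counts sum to the number of loci.
#'
#' @inheritParams classify_locus
#' @return named integer vector over the 15 non-empty group subsets (names
#'   like `"M+C+O+A"`, in fixed group order M, C, O, A) plus `"none"`.
#' @export
group_sharing_spectrum <- function(g, sheet) {
  sheet <- check_sheet(g, sheet)
  grps <- c("M", "C", "O", "A")
  if (!all(grps %in% sheet$group))
    stop("all four lineage groups must be present")
  polys <- sapply(grps, function(grp) {
    classify_unit_loci(g, sheet, grp, "group")[1, ]
  })
  polys[is.na(polys)] <- FALSE
  subset_names <- c(unlist(lapply(seq_along(grps), function(k) {
    apply(utils::combn(grps, k), 2, paste, collapse = "+")
  })), "none")
  key <- apply(polys, 1, function(z) {
    if (!any(z)) "none" else paste(grps[z], collapse = "+")
  })
  counts <- table(factor(key, levels = subset_names))
  out <- as.integer(counts)
  names(out) <- subset_names
  out
}
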