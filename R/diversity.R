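#' Watterson's theta for one unit
#'
#' Estimates the population mutation parameter from the number of segregating
#' loci within a unit, corrected for sample size: theta = S / a_n with
#' a_n = sum(1/i, i = 1..n-1) and n the number of chromosomes sampled. With
#' missing data n varies by locus; by default the modal per-locus chromosome
#' count is used for a single correction (one figure per unit), or
#' `correction = "per_locus"` sums 1/a_{n_l} over segregating loci.
#'
#' The panel carries no sequence length, so theta is reported both raw and
#' per assayed locus; no per-base-pair scaling is possible.
#'
#' @inheritParams classify_locus
#' @param unit subspecies (or group) name.
#' @param unit_level `"subspecies"` or `"group"`.
#' @param correction `"modal"` (default) or `"per_locus"`.
#' @return object of class `theta_estimate`: list with `unit`, `S`,
#'   `n_chrom`, `a_n`, `theta`, `theta_per_locus`, `n_loci_assayed`,
#'   `correction`.
#' @export
watterson_theta <- function(g, sheet, unit,
                            unit_level = c("subspecies", "group"),
                            correction = c("modal", "per_locus")) {
  unit_level <- match.arg(unit_level)
  correction <- match.arg(correction)
  sheet <- check_sheet(g, sheet)
  own <- unit_samples(sheet, unit, unit_level)
  if (!length(own)) stop("unknown unit: ", unit)
  gu <- g[own, , drop = FALSE]
  ploidy <- sheet$ploidy[match(own, sheet$sample)]
  ## chromosomes per locus: ploidy summed over samples with a call
  n_loc <- colSums((!is.na(gu)) * ploidy)
  assayed <- n_loc > 0L
  if (!any(assayed)) stop("unit has no non-missing data")
  seg <- apply(gu[, assayed, drop = FALSE], 2, both_alleles_seen)
  seg[is.na(seg)] <- FALSE
  S <- sum(seg)
  n_loc_assayed <- n_loc[assayed]
  ## modal chromosome count across loci (ties -> larger n)
  tab <- table(n_loc_assayed)
  n_modal <- max(as.integer(names(tab)[tab == max(tab)]))
  if (n_modal < 2L) stop("theta undefined: fewer than 2 chromosomes")
  harm <- function(n) sum(1 / seq_len(n - 1L))
  if (correction == "modal") {
    a_n <- harm(n_modal)
    theta <- S / a_n
  } else {
    n_seg <- n_loc_assayed[seg]
    if (any(n_seg < 2L)) stop("theta undefined: segregating locus with < 2 chromosomes")
    theta <- sum(1 / vapply(n_seg, harm, numeric(1)))
    a_n <- harm(n_modal)
  }
  structure(list(unit = unit, S = S, n_chrom = n_modal, a_n = a_n,
                 theta = theta, theta_per_locus = theta / sum(assayed),
                 n_loci_assayed = sum(assayed), correction = correction),
            class = "theta_estimate")
}

#' @export
print.theta_estimate <- function(x, ...) {
  cat(sprintf("Watterson's theta [%s]: S = %d, n = %d chromosomes, theta = %.4f (%.3g per locus)\n",
              x$unit, x$S, x$n_chrom, x$theta, x$theta_per_locus))
  invisible(x)
}

#' Watterson's theta for every unit at a level
#'
#' @inheritParams watterson_theta
#' @param include_outgroups count outgroup species as units (default FALSE).
#' @return `data.frame` with one row per unit.
#' @export
theta_table <- function(g, sheet, unit_level = c("subspecies", "group"),
                        correction = c("modal", "per_locus"),
                        include_outgroups = FALSE) {
  unit_level <- match.arg(unit_level)
  correction <- match.arg(correction)
  sh <- check_sheet(g, sheet)
  if (!include_outgroups) sh <- sh[sh$group != "OUTGROUP", , drop = FALSE]
  units <- unique(sh[[unit_level]])
  rows <- lapply(units, function(u) {
    th <- watterson_theta(g, sheet, u, unit_level, correction)
    data.frame(unit = u, group = sh$group[sh[[unit_level]] == u][1],
               n_samples = sum(sh[[unit_level]] == u), S = th$S,
               n_chrom = th$n_chrom, theta = th$theta,
               theta_per_locus = th$theta_per_locus)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
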