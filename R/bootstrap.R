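#' Bootstrap neighbor-joining trees by locus resampling
#'
#' Each replicate resamples loci (columns) with replacement to the original
#' locus count, recomputes the requested distance matrix and runs
#' [neighbor_joining()]. Allele-sharing distances are over individual
#' samples; F_ST distances over populations at `unit_level` (negative
#' estimates floored). A replicate whose resampled panel yields a degenerate
#' distance matrix (a pair with no shared data, or no informative loci for
#' some population pair) is rejected and redrawn; the number of redraws is
#' recorded in the `"redraws"` attribute.
#'
#' @inheritParams classify_locus
#' @param distance_kind `"allele_sharing"` or `"fst"`.
#' @param R number of bootstrap replicates.
#' @param seed integer seed; the run is reproducible given the seed.
#' @param unit_level unit level for F_ST distances.
#' @param pool_outgroups pool outgroup samples into one F_ST unit.
#' @param resample set `FALSE` to disable resampling (every "replicate" uses
#'   the original loci; testing aid).
#' @param max_redraws abort after this many rejected replicates.
#' @return a list of `phylo` trees (class `multiPhylo`) with attribute
#'   `redraws`.
#' @export
bootstrap_trees <- function(g, sheet = NULL,
                            distance_kind = c("allele_sharing", "fst"),
                            R = 100, seed = 1,
                            unit_level = c("subspecies", "group"),
                            pool_outgroups = FALSE, resample = TRUE,
                            max_redraws = 100L) {
  distance_kind <- match.arg(distance_kind)
  unit_level <- match.arg(unit_level)
  if (R < 1L) stop("R must be >= 1")
  if (distance_kind == "fst" && is.null(sheet))
    stop("F_ST distances require a sample sheet")
  set.seed(seed)
  L <- ncol(g)
  dist_fun <- function(gg) {
    if (distance_kind == "allele_sharing") allele_sharing_distance(gg)
    else fst_matrix(gg, sheet, unit_level, pool_outgroups,
                    floor_negative = TRUE)
  }
  trees <- vector("list", R)
  redraws <- 0L
  for (r in seq_len(R)) {
    repeat {
      idx <- if (resample) sample.int(L, L, replace = TRUE) else seq_len(L)
      gg <- unclass(g)[, idx, drop = FALSE]
      colnames(gg) <- paste0("b", seq_len(L))
      tr <- tryCatch(neighbor_joining(dist_fun(genotype_matrix(gg))),
                     error = function(e) e)
      if (!inherits(tr, "error")) break
      redraws <- redraws + 1L
      if (redraws > max_redraws)
        stop("too many degenerate bootstrap replicates: ",
             conditionMessage(tr))
    }
    trees[[r]] <- tr
  }
  class(trees) <- "multiPhylo"
  attr(trees, "redraws") <- redraws
  trees
}
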