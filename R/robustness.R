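#' Configuration for an end-to-end rooting analysis
#'
#' @param distance_kind `"allele_sharing"` (distances over samples) or
#'   `"fst"` (distances over populations).
#' @param replicates bootstrap replicate count (>= 1).
#' @param seed integer seed; the same base seed is reused across baseline and
#'   exclusion runs so locus resampling is comparable (common random
#'   numbers).
#' @param exclude character vector of subspecies to drop before the run.
#' @param consensus_threshold majority-rule threshold.
#' @param pool_outgroups pool outgroup species into one F_ST unit.
#' @param unit_level unit level for F_ST distances.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(distance_kind = c("allele_sharing", "fst"),
                            replicates = 100, seed = 1,
                            exclude = character(),
                            consensus_threshold = 0.5,
                            pool_outgroups = FALSE,
                            unit_level = c("subspecies", "group")) {
  distance_kind <- match.arg(distance_kind)
  unit_level <- match.arg(unit_level)
  if (replicates < 1L) stop("replicates must be >= 1")
  structure(list(distance_kind = distance_kind,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed),
                 exclude = as.character(exclude),
                 consensus_threshold = consensus_threshold,
                 pool_outgroups = pool_outgroups,
                 unit_level = unit_level),
            class = "analysis_config")
}

#' Run a (taxon-exclusion) rooting analysis
#'
#' Drops the samples of the excluded subspecies, then runs the full pipeline:
#' locus-bootstrap neighbor-joining trees, majority-rule consensus,
#' compatibility filtering against the consensus, and outgroup-placement
#' tallies — both over all replicates and over the post-filter remainder
#' (the competing signal). Deterministic given the config seed. An empty
#' exclusion list reproduces the baseline full-panel run.
#'
#' @inheritParams classify_locus
#' @param cfg an [analysis_config()].
#' @return object of class `robustness_report`: list with `config`, `trees`,
#'   `consensus`, `tally_all`, `tally_remainder`, `n_compatible`,
#'   `n_remainder`, `second_consensus`, `n_samples`.
#' @export
run_exclusion_analysis <- function(g, sheet, cfg = analysis_config()) {
  sheet <- check_sheet(g, sheet)
  unknown <- setdiff(cfg$exclude, sheet$subspecies)
  if (length(unknown))
    stop("excluded subspecies not in sheet: ", paste(unknown, collapse = ", "))
  keep <- !(sheet$subspecies %in% cfg$exclude)
  sh <- sheet[keep, , drop = FALSE]
  gone <- setdiff(unique(sheet$group[sheet$group != "OUTGROUP"]),
                  unique(sh$group))
  if (length(gone))
    stop("exclusion empties lineage group(s): ", paste(gone, collapse = ", "))
  if (!any(sh$group == "OUTGROUP")) stop("no outgroup samples remain")
  gg <- unclass(g)[sh$sample, , drop = FALSE]
  gg <- genotype_matrix(gg)
  trees <- bootstrap_trees(gg, sh, cfg$distance_kind, R = cfg$replicates,
                           seed = cfg$seed, unit_level = cfg$unit_level,
                           pool_outgroups = cfg$pool_outgroups)
  cons <- majority_rule_consensus(trees, cfg$consensus_threshold)
  flt <- filter_compatible(trees, cons, cfg$consensus_threshold)
  ## placement sheet: F_ST trees have population-level leaves
  psheet <- if (cfg$distance_kind == "fst") population_sheet(sh, cfg) else sh
  structure(list(config = cfg,
                 trees = trees,
                 consensus = cons,
                 tally_all = placement_frequencies(trees, psheet),
                 tally_remainder = if (length(flt$remainder))
                   placement_frequencies(flt$remainder, psheet) else NULL,
                 n_compatible = flt$n_compatible,
                 n_remainder = flt$n_remainder,
                 second_consensus = flt$second_consensus,
                 n_samples = nrow(gg)),
            class = "robustness_report")
}

## sheet whose "samples" are the population units of an F_ST analysis
population_sheet <- function(sh, cfg) {
  if (cfg$pool_outgroups) sh$subspecies[sh$group == "OUTGROUP"] <- "OUTGROUP"
  units <- unique(sh[, c(cfg$unit_level, "group"), drop = FALSE])
  if (cfg$unit_level == "group") units$group <- units[[1]]
  sample_sheet(units[[cfg$unit_level]], units[[cfg$unit_level]], units$group)
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("rooting analysis:", x$config$distance_kind, "distances,",
      x$config$replicates, "replicates, seed", x$config$seed, "\n")
  if (length(x$config$exclude))
    cat("  excluded:", paste(x$config$exclude, collapse = ", "), "\n")
  cat("  compatible with consensus:", x$n_compatible, "/",
      x$n_compatible + x$n_remainder, "\n")
  print(x$tally_all)
  invisible(x)
}

#' Compare two robustness reports
#'
#' @param r1,r2 `robustness_report` objects over the same category alphabet.
#' @return list with `fraction_delta` (per-category, r2 - r1),
#'   `shared_splits`, `only_r1`, `only_r2` (consensus split keys; keys are
#'   over each tree's own sorted leaf set).
#' @export
compare_reports <- function(r1, r2) {
  f1 <- r1$tally_all$fractions
  f2 <- r2$tally_all$fractions
  if (!identical(names(f1), names(f2))) stop("category alphabets differ")
  k1 <- split_keys_labeled(r1$consensus)
  k2 <- split_keys_labeled(r2$consensus)
  list(fraction_delta = f2 - f1,
       shared_splits = intersect(k1, k2),
       only_r1 = setdiff(k1, k2),
       only_r2 = setdiff(k2, k1))
}

## label-based split keys so trees over different leaf sets can be diffed
split_keys_labeled <- function(tree) {
  sp <- tree_splits(tree)
  vapply(sp$sides, function(s) paste(sp$labels[s], collapse = "|"),
         character(1))
}

#' Serialize a robustness report to JSON (with Newick sidecar strings)
#'
#' @param report a `robustness_report`.
#' @param path output path for the JSON file.
#' @export
write_report_json <- function(report, path) {
  obj <- list(
    config = unclass(report$config),
    n_samples = report$n_samples,
    consensus_newick = ape::write.tree(report$consensus),
    second_consensus_newick = if (!is.null(report$second_consensus))
      ape::write.tree(report$second_consensus) else NULL,
    n_compatible = report$n_compatible,
    n_remainder = report$n_remainder,
    tally_all = as.list(report$tally_all$fractions),
    tally_remainder = if (!is.null(report$tally_remainder))
      as.list(report$tally_remainder$fractions) else NULL)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
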