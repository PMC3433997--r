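#' Sample design of the reference honeybee panel
#'
#' The default simulated panel mirrors the sampling design of the SNP panel
#' the analyses were built for: 14 *A. mellifera* subspecies in four lineage
#' groups plus three outgroup species, with the North-African taxon modeled
#' as an A/M-ancestry admixture assigned to group A. `scale` shrinks every
#' subspecies proportionally (ceiling, minimum one sample) for desk-scale
#' runs.
#'
#' @param scale proportional scaling of all sample counts (default 1).
#' @return list with `groups` (named list: group -> named integer vector of
#'   samples per subspecies), `outgroups` (named integer vector), `admix_n`
#'   (samples in the admixed subspecies).
#' @export
study_design <- function(scale = 1) {
  sc <- function(v) {
    ## floor of 2 keeps every unit usable for pairwise F_ST (one diploid
    ## carries no within-population degrees of freedom), as in the full panel
    out <- pmax(2L, as.integer(ceiling(v * scale)))
    names(out) <- names(v)
    out
  }
  list(groups = list(
         M = sc(c(mellifera = 20, iberiensis = 11)),
         C = sc(c(ligustica = 18, carnica = 17)),
         O = sc(c(anatoliaca = 19, caucasica = 11, syriaca = 9, pomonella = 3)),
         A = sc(c(scutellata = 22, lamarckii = 19, capensis = 3, litorea = 2,
                  unicolor = 2))),
       outgroups = sc(c(cerana = 7, florea = 2, dorsata = 4)),
       admix_n = sc(19))
}

#' Configuration of the synthetic SNP panel generator
#'
#' The generator draws a Balding-Nichols frequency hierarchy: an ancestral
#' frequency per locus, drifted into two super-groups according to the
#' planted group topology `((A,M),(C,O))`, then into lineage groups, then
#' into subspecies; genotypes are binomial draws from the subspecies
#' frequency. An admixed subspecies draws each locus's frequency from its
#' first source group with probability `alpha`, else from the second.
#' Outgroup species are fixed at each locus: for the rare panel allele with
#' probability `og_div_shared` (shared across the outgroup clade) plus
#' `og_div_species` (per species), else for the common allele.
#'
#' Drift parameters F are inbreeding-style coefficients in \[0, 1\]: the
#' daughter frequency is Beta(p(1-F)/F, (1-p)(1-F)/F) around the parent
#' frequency p (F = 0 copies p; F = 1 fixes one allele). Defaults were
#' calibrated once against the reference panel's polymorphism-sharing
#' proportions and its weakly resolved between-group relationships, with
#' per-group drift asymmetry mirroring the panel: weak drift in the African
#' group (large effective size, high within-group polymorphism), strong
#' drift in the bottlenecked western-European M group (the panel's
#' long-branch lineage with the lowest subspecies polymorphism counts), and
#' intermediate drift in C and O.
#'
#' @param seed integer seed.
#' @param L number of background loci.
#' @param design a [study_design()] (or same-shaped list).
#' @param group_tree planted topology as a list of two character vectors of
#'   group names (the two super-groups).
#' @param F_super,F_group,F_sub drift at the super-group, group and
#'   subspecies level; `F_group`/`F_sub` may be a single value or named per
#'   group.
#' @param freq_shape,freq_min ancestral frequency law: `freq_min +
#'   (1 - 2 freq_min) * Beta(freq_shape, freq_shape)` (U-shaped spectrum).
#' @param og_div_shared,og_div_species outgroup fixed-difference
#'   probabilities (shared clade component, per-species component).
#' @param admix admixed-subspecies spec: list with `name`, `group` (sheet
#'   assignment), `sources` (two group names), `alpha`, `n`; `NULL` for
#'   none.
#' @param planted_private,planted_fixed_private named integer vectors
#'   (subspecies -> count of planted loci of that class).
#' @param missing_rate per-call missing probability.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1, L = 1029, design = study_design(),
                       group_tree = list(c("A", "M"), c("C", "O")),
                       F_super = 0.01,
                       F_group = c(A = 0.08, M = 0.45, C = 0.12, O = 0.12),
                       F_sub = c(A = 0.03, M = 0.10, C = 0.04, O = 0.04),
                       freq_shape = 0.35, freq_min = 0.01,
                       og_div_shared = 0.35, og_div_species = 0.05,
                       admix = list(name = "intermissa", group = "A",
                                    sources = c("A", "M"), alpha = 0.5,
                                    n = design$admix_n),
                       planted_private = integer(),
                       planted_fixed_private = integer(),
                       missing_rate = 0) {
  grps <- names(design$groups)
  expand <- function(f, what) {
    if (length(f) == 1L && is.null(names(f)))
      f <- stats::setNames(rep(f, length(grps)), grps)
    if (!all(grps %in% names(f))) stop(what, " must cover all groups")
    f[grps]
  }
  F_group <- expand(F_group, "F_group")
  F_sub <- expand(F_sub, "F_sub")
  stopifnot(L >= 1, all(c(F_super, F_group, F_sub) >= 0),
            all(c(F_super, F_group, F_sub) <= 1),
            og_div_shared >= 0, og_div_shared <= 1,
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(admix)) {
    stopifnot(admix$alpha >= 0, admix$alpha <= 1,
              all(admix$sources %in% grps), length(admix$sources) == 2L)
  }
  if (!setequal(unlist(group_tree), grps))
    stop("group_tree must partition the group names")
  structure(list(seed = as.integer(seed), L = as.integer(L), design = design,
                 group_tree = group_tree, F_super = F_super,
                 F_group = F_group, F_sub = F_sub, freq_shape = freq_shape,
                 freq_min = freq_min, og_div_shared = og_div_shared,
                 og_div_species = og_div_species, admix = admix,
                 planted_private = planted_private,
                 planted_fixed_private = planted_fixed_private,
                 missing_rate = missing_rate),
            class = "sim_config")
}

## Balding-Nichols drift of a frequency vector; F = 0 copies, fixed loci stay
## fixed (the Beta is undefined there and drift cannot unfix an allele)
bn_drift <- function(p, F) {
  if (F <= 0) return(p)
  if (F >= 1) return(ifelse(stats::runif(length(p)) < p, 1, 0))
  out <- p
  seg <- p > 0 & p < 1
  out[seg] <- stats::rbeta(sum(seg), p[seg] * (1 - F) / F,
                           (1 - p[seg]) * (1 - F) / F)
  out
}

#' Simulate a structured SNP panel with ground truth
#'
#' @param cfg a [sim_config()].
#' @return object of class `sim_panel`: list with `genotypes` (a
#'   [genotype_matrix()]), `sheet` (a [sample_sheet()]) and `truth` (list:
#'   `ancestral`, `group_freq`, `sub_freq`, `admix_source`,
#'   `planted_private`, `planted_fixed_private`, `group_tree`).
#' @export
simulate_panel <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  L <- cfg$L
  grps <- names(cfg$design$groups)
  p <- cfg$freq_min + (1 - 2 * cfg$freq_min) *
    stats::rbeta(L, cfg$freq_shape, cfg$freq_shape)
  ## planted topology: drift ancestral -> super-groups -> groups -> subspecies
  super_freq <- lapply(cfg$group_tree, function(gs) bn_drift(p, cfg$F_super))
  group_freq <- sapply(grps, function(g) {
    k <- which(vapply(cfg$group_tree, function(gs) g %in% gs, logical(1)))
    bn_drift(super_freq[[k]], cfg$F_group[[g]])
  })
  subs <- unlist(lapply(grps, function(g) names(cfg$design$groups[[g]])))
  sub_group <- unlist(lapply(grps, function(g)
    rep(g, length(cfg$design$groups[[g]]))))
  names(sub_group) <- subs
  sub_freq <- sapply(subs, function(s)
    bn_drift(group_freq[, sub_group[[s]]], cfg$F_sub[[sub_group[[s]]]]))
  calls <- list(); sheet_rows <- list()
  draw_sub <- function(name, grp, freq, n, species = NA_character_) {
    m <- matrix(stats::rbinom(n * L, 2L, rep(freq, each = n)), nrow = n)
    rownames(m) <- paste0(name, "_", seq_len(n))
    calls[[length(calls) + 1L]] <<- m
    sheet_rows[[length(sheet_rows) + 1L]] <<- data.frame(
      sample = rownames(m), subspecies = name, group = grp,
      species = species, stringsAsFactors = FALSE)
  }
  for (s in subs)
    draw_sub(s, sub_group[[s]], sub_freq[, s], cfg$design$groups[[sub_group[[s]]]][[s]])
  admix_source <- NULL
  if (!is.null(cfg$admix)) {
    a <- cfg$admix
    admix_source <- ifelse(stats::runif(L) < a$alpha, a$sources[1], a$sources[2])
    fsrc <- ifelse(admix_source == a$sources[1],
                   group_freq[, a$sources[1]], group_freq[, a$sources[2]])
    fad <- bn_drift(fsrc, cfg$F_sub[[a$group]])
    draw_sub(a$name, a$group, fad, a$n)
  }
  ## outgroups: fixed alleles, mostly shared across the outgroup clade
  rare <- ifelse(p <= 0.5, 2L, 0L)
  common <- 2L - rare
  og_shared <- ifelse(stats::runif(L) < cfg$og_div_shared, rare, common)
  for (og in names(cfg$design$outgroups)) {
    allele <- ifelse(stats::runif(L) < cfg$og_div_species, rare, og_shared)
    n <- cfg$design$outgroups[[og]]
    m <- matrix(rep(allele, each = n), nrow = n)
    rownames(m) <- paste0(og, "_", seq_len(n))
    calls[[length(calls) + 1L]] <- m
    sheet_rows[[length(sheet_rows) + 1L]] <- data.frame(
      sample = rownames(m), subspecies = og, group = "OUTGROUP",
      species = og, stringsAsFactors = FALSE)
  }
  G <- do.call(rbind, calls)
  colnames(G) <- sprintf("snp%04d", seq_len(L))
  sheet_df <- do.call(rbind, sheet_rows)
  ## planted private / fixed-private loci (appended after the L background
  ## loci): a private locus is heterozygous in one sample of the target
  ## subspecies and reference-homozygous everywhere else; a fixed-private
  ## locus is alternate-homozygous across the target and reference elsewhere
  planted_private <- list(); planted_fixed <- list()
  plant <- function(counts, fixed) {
    out <- list()
    for (s in names(counts)) {
      if (counts[[s]] < 1L) next
      block <- matrix(0L, nrow(G), counts[[s]])
      own <- which(sheet_df$subspecies == s)
      if (!length(own)) stop("planted subspecies not in design: ", s)
      if (fixed) block[own, ] <- 2L else block[own[1], ] <- 1L
      colnames(block) <- sprintf("%s_%s_%03d",
                                 if (fixed) "fpv" else "prv", s,
                                 seq_len(counts[[s]]))
      out[[s]] <- colnames(block)
      G <<- cbind(G, block)
    }
    out
  }
  planted_private <- plant(cfg$planted_private, fixed = FALSE)
  planted_fixed <- plant(cfg$planted_fixed_private, fixed = TRUE)
  if (cfg$missing_rate > 0) {
    mask <- matrix(stats::runif(length(G)) < cfg$missing_rate, nrow(G))
    ## never blank out a whole locus
    for (j in which(colSums(!mask) == 0L)) mask[1, j] <- FALSE
    G[mask] <- NA_integer_
  }
  structure(list(
    genotypes = genotype_matrix(G),
    sheet = sample_sheet(sheet_df$sample, sheet_df$subspecies,
                         sheet_df$group, sheet_df$species),
    truth = list(ancestral = p, group_freq = group_freq, sub_freq = sub_freq,
                 admix_source = admix_source,
                 planted_private = planted_private,
                 planted_fixed_private = planted_fixed,
                 group_tree = cfg$group_tree, config = cfg)),
    class = "sim_panel")
}

#' Ascertainment filter: keep loci discovered in a panel subset
#'
#' Emulates SNP discovery restricted to a subset of subspecies: a locus is
#' retained iff its minor-allele count within the panel subset's samples is
#' at least `min_mac` (threshold 0 retains everything). Loci monomorphic in
#' the panel but polymorphic elsewhere are removed at any positive threshold.
#'
#' @inheritParams classify_locus
#' @param panel character vector of subspecies forming the discovery panel.
#' @param min_mac minimal minor-allele count within the panel.
#' @param truth optional `sim_panel` truth list; returned updated with a
#'   `kept` mask.
#' @return list with `genotypes` (filtered [genotype_matrix()]), `kept`
#'   (logical mask over input loci), and `truth`.
#' @export
apply_ascertainment <- function(g, sheet, panel, min_mac = 1, truth = NULL) {
  sheet <- check_sheet(g, sheet)
  if (!length(panel)) stop("panel subset must be non-empty")
  bad <- setdiff(panel, sheet$subspecies)
  if (length(bad)) stop("panel subspecies not in sheet: ",
                        paste(bad, collapse = ", "))
  samp <- sheet$sample[sheet$subspecies %in% panel]
  gp <- unclass(g)[samp, , drop = FALSE]
  alt <- colSums(gp, na.rm = TRUE)
  tot <- 2L * colSums(!is.na(gp))
  mac <- pmin(alt, tot - alt)
  kept <- mac >= min_mac
  if (!any(kept)) stop("ascertainment filter removed all loci")
  if (!is.null(truth)) truth$kept <- kept
  list(genotypes = genotype_matrix(unclass(g)[, kept, drop = FALSE]),
       kept = kept, truth = truth)
}
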