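test_that("allele-sharing distance equals brute-force allele counting on all 9 genotype pairs", {
  for (ci in 0:2) for (cj in 0:2) {
    m <- matrix(c(ci, cj), 2, 1, dimnames = list(c("s1", "s2"), "l1"))
    m <- cbind(m, l2 = c(0L, 0L)) # second locus keeps the panel valid
    storage.mode(m) <- "integer"
    g <- genotype_matrix(m)
    expect_equal(allele_sharing_distance(g), asd_brute(g),
                 ignore_attr = TRUE)
  }
  ## the documented het vs homozygote case: IBS = 1/2 at that locus
  m <- matrix(c(1L, 0L, 0L, 0L), 2, 2,
              dimnames = list(c("s1", "s2"), c("l1", "l2")))
  d <- allele_sharing_distance(genotype_matrix(m))
  expect_equal(d["s1", "s2"], mean(c(0.5, 0)))
})

test_that("allele-sharing distance matches brute force on random panels with missing data", {
  set.seed(91)
  for (rep in 1:25) {
    n <- sample(3:7, 1); L <- sample(5:25, 1)
    m <- matrix(sample(0:2, n * L, replace = TRUE), n)
    m[sample(length(m), ceiling(0.15 * length(m)))] <- NA
    m <- m[, colSums(!is.na(m)) > 0, drop = FALSE]
    rownames(m) <- paste0("s", 1:n); colnames(m) <- paste0("l", seq_len(ncol(m)))
    ## ensure every pair overlaps somewhere
    m[, 1] <- 1L
    g <- genotype_matrix(m)
    expect_equal(allele_sharing_distance(g), asd_brute(g),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("allele-sharing endpoints and degenerate pairs behave per definition", {
  g <- genotype_matrix(matrix(c(1L, 1L, 1L, 1L, 1L, 1L), 2,
                              dimnames = list(c("a", "b"), paste0("l", 1:3))))
  expect_equal(max(allele_sharing_distance(g)), 0) # identical vectors
  g2 <- genotype_matrix(matrix(c(0L, 2L, 0L, 2L), 2,
                               dimnames = list(c("a", "b"), c("l1", "l2"))))
  expect_equal(allele_sharing_distance(g2)["a", "b"], 1) # opposite homozygotes
  ## pair with no shared non-missing loci errors with the pair named
  m3 <- matrix(c(0L, NA, NA, 1L, 0L, NA), 2, 3,
               dimnames = list(c("a", "b"), paste0("l", 1:3)))
  expect_error(allele_sharing_distance(genotype_matrix(m3)), "a / b")
})

test_that("Weir-Cockerham components equal the ANOVA mean-squares oracle on random panels", {
  set.seed(77)
  worst <- 0
  for (rep in 1:50) {
    pan <- random_two_pop_panel(sample(2:6, 1), sample(2:6, 1),
                                sample(3:20, 1))
    comp <- wc_fst_components(pan$g, pan$sheet, "pA", "pB")
    gA <- unclass(pan$g)[seq_len(pan$nA), , drop = FALSE]
    gB <- unclass(pan$g)[pan$nA + seq_len(pan$nB), , drop = FALSE]
    for (j in seq_len(ncol(pan$g))) {
      if (!comp$informative[j]) next
      o <- wc_anova_oracle(gA[, j], gB[, j])
      worst <- max(worst, abs(c(comp$a[j], comp$b[j], comp$c[j]) - o))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("F_ST endpoints: full fixation gives 1, duplicated populations give <= 0", {
  m <- rbind(a1 = c(0L, 0L), a2 = c(0L, 0L), b1 = c(2L, 2L), b2 = c(2L, 2L))
  colnames(m) <- c("l1", "l2")
  sheet <- sample_sheet(rownames(m), rep(c("pA", "pB"), each = 2),
                        rep(c("M", "C"), each = 2))
  expect_equal(wc_fst(genotype_matrix(m), sheet, "pA", "pB"), 1)
  set.seed(13)
  for (rep in 1:10) {
    base <- matrix(sample(0:2, 5 * 12, replace = TRUE), 5)
    m <- rbind(base, base)
    rownames(m) <- paste0("s", 1:10); colnames(m) <- paste0("l", 1:12)
    sheet <- sample_sheet(rownames(m), rep(c("pA", "pB"), each = 5),
                          rep(c("M", "C"), each = 5))
    g <- genotype_matrix(m)
    est <- tryCatch(wc_fst(g, sheet, "pA", "pB"), error = function(e) NA)
    if (!is.na(est)) expect_lte(est, 0)
  }
})

test_that("F_ST is invariant to population-label swap and global allele swap", {
  set.seed(29)
  for (rep in 1:10) {
    pan <- random_two_pop_panel(4, 5, 15, missing = FALSE)
    est <- wc_fst(pan$g, pan$sheet, "pA", "pB")
    expect_equal(wc_fst(pan$g, pan$sheet, "pB", "pA"), est, tolerance = 1e-12)
    swapped <- genotype_matrix(2L - unclass(pan$g))
    expect_equal(wc_fst(swapped, pan$sheet, "pA", "pB"), est,
                 tolerance = 1e-12)
  }
})

test_that("monomorphic panels have no informative loci", {
  m <- matrix(0L, 4, 3, dimnames = list(paste0("s", 1:4), paste0("l", 1:3)))
  m[1, 1] <- 0L
  sheet <- sample_sheet(rownames(m), rep(c("pA", "pB"), each = 2),
                        rep(c("M", "C"), each = 2))
  expect_error(wc_fst(genotype_matrix(m), sheet, "pA", "pB"),
               "no informative loci")
})

test_that("the F_ST matrix floors negatives, records flooring, and orders planted structure", {
  ## three identical populations: all entries 0 after flooring
  set.seed(59)
  base <- matrix(sample(0:2, 4 * 30, replace = TRUE), 4)
  m <- rbind(base, base, base)
  rownames(m) <- paste0("s", 1:12); colnames(m) <- paste0("l", 1:30)
  sheet <- sample_sheet(rownames(m), rep(c("pA", "pB", "pC"), each = 4),
                        rep(c("M", "C", "O"), each = 4))
  fm <- fst_matrix(genotype_matrix(m), sheet)
  expect_true(all(fm == 0))
  expect_true(any(attr(fm, "floored")))
  ## planted hierarchy ((A,M),(C,O)): the A-M pair is the closest
  ## between-group pair
  design <- list(groups = list(M = c(m1 = 8), C = c(c1 = 8),
                               O = c(o1 = 8), A = c(a1 = 8)),
                 outgroups = c(og1 = 2), admix_n = 2)
  hits <- 0
  for (seed in 1:5) {
    cfg <- sim_config(seed = seed, L = 800, design = design, F_super = 0.06,
                      F_group = 0.03, F_sub = 0.01, admix = NULL)
    sim <- simulate_panel(cfg)
    fm <- fst_matrix(sim$genotypes, sim$sheet, pool_outgroups = TRUE)
    between <- c(am = fm["a1", "m1"], ac = fm["a1", "c1"], ao = fm["a1", "o1"],
                 mc = fm["m1", "c1"], mo = fm["m1", "o1"], co = fm["c1", "o1"])
    hits <- hits + (names(which.min(between)) %in% c("am", "co"))
  }
  expect_gte(hits, 4)
})

test_that("flooring never changes NJ topology when no entry is negative", {
  set.seed(101)
  add <- random_additive(7)
  t1 <- neighbor_joining(add$d)
  expect_equal(ape::dist.topo(t1, add$tree), 0, ignore_attr = TRUE)
})

test_that("PHYLIP distance matrices round-trip", {
  set.seed(3)
  add <- random_additive(6)
  path <- withr::local_tempfile(fileext = ".phy")
  write_phylip_dist(add$d, path)
  d2 <- read_phylip_dist(path)
  expect_equal(d2, add$d, tolerance = 1e-9, ignore_attr = TRUE)
  expect_identical(rownames(d2), rownames(add$d))
})
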