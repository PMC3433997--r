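test_that("genotype matrix validation enforces the coding contract", {
  m <- matrix(c(0L, 1L, 2L, 0L, NA, 2L), nrow = 3,
              dimnames = list(paste0("s", 1:3), c("l1", "l2")))
  g <- genotype_matrix(m)
  expect_s3_class(g, "genotype_matrix")
  expect_error(genotype_matrix(m[1, , drop = FALSE]), "2 samples")
  m2 <- m; m2[, 2] <- NA
  expect_error(genotype_matrix(m2), "all calls missing")
  m3 <- m; m3[1, 1] <- 3L
  expect_error(genotype_matrix(m3), "0, 1, 2 or NA")
  expect_error(sample_sheet("s1", "mel", "Z"), "lineage group")
})

test_that("tabular genotypes round-trip bit-exactly", {
  m <- matrix(c(0L, 1L, 2L, NA, 2L, 0L), nrow = 3,
              dimnames = list(paste0("s", 1:3), c("l1", "l2")))
  g <- genotype_matrix(m)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, path)
  g2 <- read_genotypes(path, "tabular")
  expect_identical(unclass(g2), unclass(g))
  ## malformed cell names its line
  bad <- readLines(path)
  bad[3] <- sub("\t2", "\tX", bad[3])
  writeLines(bad, path)
  expect_error(read_genotypes(path, "tabular"), "line 3")
})

test_that("VCF genotypes are coded 0/1/2/NA and multi-allelic records rejected", {
  skip_if_not_installed("vcfR")
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsA\tsB",
           "chr1\t10\tsnp1\tA\tG\t.\tPASS\t.\tGT\t0/1\t./.",
           "chr1\t20\tsnp2\tA\tG\t.\tPASS\t.\tGT\t1|1\t0/0")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  g <- read_genotypes(path, "vcf")
  expect_identical(g["sA", "snp1"], 1L)
  expect_true(is.na(g["sB", "snp1"]))
  expect_identical(g["sA", "snp2"], 2L) # phased het treated as unphased
  expect_identical(g["sB", "snp2"], 0L)
  vcf_multi <- c(vcf, "chr1\t30\tsnp3\tA\tG,T\t.\tPASS\t.\tGT\t0/1\t0/0")
  writeLines(vcf_multi, path)
  expect_error(read_genotypes(path, "vcf"), "non-biallelic")
  g3 <- read_genotypes(path, "vcf", multiallelic = "drop")
  expect_equal(ncol(g3), 2L)
})

make_unit_panel <- function(unit_calls, other_calls) {
  ## 2-subspecies panel, single locus, plus an outgroup that must be ignored
  n1 <- length(unit_calls); n2 <- length(other_calls)
  m <- matrix(c(unit_calls, other_calls, 2L), ncol = 1)
  rownames(m) <- c(paste0("u", seq_len(n1)), paste0("v", seq_len(n2)), "og1")
  colnames(m) <- "l1"
  ## a second locus so the matrix is never degenerate
  m <- cbind(m, l2 = 1L)
  sheet <- sample_sheet(rownames(m),
                        c(rep("unitA", n1), rep("unitB", n2), "ogsp"),
                        c(rep("M", n1), rep("C", n2), "OUTGROUP"))
  list(g = genotype_matrix(m), sheet = sheet)
}

test_that("locus classification follows the polymorphic/private/fixed-private definitions", {
  p <- make_unit_panel(c(0L, 1L, 2L), c(0L, 0L))
  cl <- classify_locus(p$g, p$sheet, "l1", "unitA")
  expect_true(cl[["polymorphic"]] && cl[["private"]] && !cl[["fixed_private"]])
  ## fixed for the alternate allele, absent elsewhere (the unicolor pattern)
  p <- make_unit_panel(c(2L, 2L), c(0L, 0L))
  cl <- classify_locus(p$g, p$sheet, "l1", "unitA")
  expect_equal(unname(cl), c(FALSE, FALSE, TRUE))
  ## monomorphic unit, polymorphic elsewhere: none of the three
  p <- make_unit_panel(c(0L, 0L), c(0L, 1L, 2L))
  cl <- classify_locus(p$g, p$sheet, "l1", "unitA")
  expect_equal(unname(cl), c(FALSE, FALSE, FALSE))
  ## all-missing unit call at the locus -> NA classification
  m <- matrix(c(NA, NA, 0L, 1L, 0L, 1L, 1L, 1L), ncol = 2)
  rownames(m) <- paste0("s", 1:4); colnames(m) <- c("l1", "l2")
  sheet <- sample_sheet(rownames(m), rep(c("uA", "uB"), each = 2),
                        rep(c("M", "C"), each = 2))
  expect_true(all(is.na(classify_locus(genotype_matrix(m), sheet, "l1", "uA"))))
})

test_that("classification is invariant to sample order and allele-label swap", {
  set.seed(41)
  for (rep in 1:20) {
    calls_u <- sample(0:2, 4, replace = TRUE)
    calls_v <- sample(0:2, 3, replace = TRUE)
    p <- make_unit_panel(calls_u, calls_v)
    base <- classify_locus(p$g, p$sheet, "l1", "unitA")
    ## sample reordering
    perm <- sample(nrow(p$g))
    gp <- genotype_matrix(unclass(p$g)[perm, , drop = FALSE])
    expect_identical(classify_locus(gp, p$sheet, "l1", "unitA"), base)
    ## allele-label swap (0 <-> 2): polymorphic predicate unchanged
    gs <- genotype_matrix(2L - unclass(p$g))
    swapped <- classify_locus(gs, p$sheet, "l1", "unitA")
    expect_identical(swapped[["polymorphic"]], base[["polymorphic"]])
  }
})

test_that("polymorphism table collapses correctly in degenerate panels", {
  ## every locus polymorphic in every subspecies -> no private, no fixed
  blocks <- list(
    M = list(mel = rbind(c(0L, 0L), c(1L, 1L), c(2L, 2L))),
    C = list(lig = rbind(c(0L, 0L), c(2L, 1L))))
  p <- panel_from_blocks(blocks, 2)
  pt <- polymorphism_table(p$g, p$sheet)
  expect_true(all(pt$private == 0) && all(pt$fixed_private == 0))
  expect_true(all(pt$polymorphic == 2))
  ## single-subspecies panel: private collapses onto polymorphic
  m <- rbind(s1 = c(0L, 0L, 2L), s2 = c(1L, 0L, 2L), s3 = c(2L, 0L, 2L))
  colnames(m) <- paste0("l", 1:3)
  sheet <- sample_sheet(rownames(m), "mel", "M")
  pt <- polymorphism_table(genotype_matrix(m), sheet)
  sub <- pt[pt$level == "subspecies", ]
  expect_equal(sub$private, sub$polymorphic)
})

test_that("group-sharing spectrum assigns loci to exact group subsets and conserves totals", {
  ## hand-planted spectrum: l1 polymorphic in all four, l2 only in M,
  ## l3 nowhere (fixed difference vs outgroup only)
  blocks <- list(
    M = list(mel = rbind(c(1L, 1L, 0L), c(1L, 0L, 0L))),
    C = list(lig = rbind(c(1L, 0L, 0L), c(1L, 0L, 0L))),
    O = list(ana = rbind(c(0L, 0L, 0L), c(1L, 0L, 0L))),
    A = list(scu = rbind(c(2L, 0L, 0L), c(0L, 0L, 0L))))
  og <- rbind(c(0L, 0L, 2L))
  p <- panel_from_blocks(blocks, 3, outgroup = rbind(og, og))
  sp <- group_sharing_spectrum(p$g, p$sheet)
  expect_equal(sp[["M+C+O+A"]], 1L)
  expect_equal(sp[["M"]], 1L)
  expect_equal(sp[["none"]], 1L)
  expect_equal(sum(sp), ncol(p$g))
})

test_that("spectrum buckets sum to the locus count on simulated panels", {
  for (seed in 1:3) {
    sim <- simulate_panel(sim_config(seed = seed, L = 120,
                                     design = study_design(0.1)))
    sp <- group_sharing_spectrum(sim$genotypes, sim$sheet)
    expect_equal(sum(sp), ncol(sim$genotypes))
  }
})
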