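## Independent oracles and fixture builders used across the suite. Each
## oracle deliberately takes a different computational route from the
## package code it checks.

## Weir-Cockerham variance components for one locus via the nested-ANOVA
## mean-squares route (sums of squares built from per-allele indicators),
## not the closed-form component expressions the package uses.
wc_anova_oracle <- function(callsA, callsB) {
  callsA <- callsA[!is.na(callsA)]
  callsB <- callsB[!is.na(callsB)]
  n1 <- length(callsA); n2 <- length(callsB)
  if (n1 < 1 || n2 < 1 || (n1 + n2) < 3) return(c(a = 0, b = 0, c = 0))
  ntot <- n1 + n2
  p1 <- sum(callsA) / (2 * n1)
  p2 <- sum(callsB) / (2 * n2)
  pbar <- (2 * n1 * p1 + 2 * n2 * p2) / (2 * ntot)
  if (pbar == 0 || pbar == 1) return(c(a = 0, b = 0, c = 0))
  SSG <- 0; SSI <- 0
  acc <- function(cl, p) {
    for (g in cl) {
      alleles <- c(g >= 1, g == 2) * 1 # genotype -> two allele indicators
      ybar <- g / 2
      SSG <<- SSG + sum((alleles - ybar)^2)
      SSI <<- SSI + 2 * (ybar - p)^2
    }
  }
  acc(callsA, p1); acc(callsB, p2)
  SSP <- 2 * n1 * (p1 - pbar)^2 + 2 * n2 * (p2 - pbar)^2
  MSG <- SSG / ntot
  MSI <- SSI / (ntot - 2)
  MSP <- SSP / 1
  nc <- (ntot - (n1^2 + n2^2) / ntot) / 1
  c(a = (MSP - MSI) / (2 * nc), b = (MSI - MSG) / 2, c = MSG)
}

## brute-force allele-sharing distance: per pair, per locus, count shared
## alleles by multiset intersection of the two genotypes' allele bags
asd_brute <- function(g) {
  m <- unclass(g)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shares <- c(); used <- 0
    for (l in seq_len(ncol(m))) {
      ci <- m[i, l]; cj <- m[j, l]
      if (is.na(ci) || is.na(cj)) next
      shared <- min(ci, cj) + min(2 - ci, 2 - cj)
      shares <- c(shares, shared / 2)
      used <- used + 1
    }
    stopifnot(used > 0)
    d[i, j] <- d[j, i] <- 1 - mean(shares)
  }
  d
}

## canonical label-based split keys of a tree via phangorn (independent of
## beeroot::tree_splits)
split_keys_phangorn <- function(tree) {
  sp <- phangorn::as.splits(tree)
  labs <- attr(sp, "labels")
  ref <- sort(labs)[1]
  n <- length(labs)
  keys <- character(0)
  for (s in sp) {
    side <- labs[s]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) < 2 || length(side) > n - 2) next
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

## naive majority-rule support counting over a tree list
naive_split_counts <- function(trees) {
  all_keys <- unlist(lapply(trees, split_keys_phangorn))
  table(all_keys)
}

## label-based keys for beeroot consensus supports
beeroot_support_keys <- function(cons) {
  sup <- attr(cons, "supports")
  sp <- tree_splits(cons)
  labs <- sp$labels
  vapply(strsplit(sup$key, ","), function(idx)
    paste(sort(labs[as.integer(idx)]), collapse = "|"), character(1))
}

## random unrooted binary tree with branch lengths and its additive matrix
random_additive <- function(ntax, min_len = 0.1, max_len = 2) {
  tr <- ape::rtree(ntax, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), min_len, max_len)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

## exhaustive non-negative least squares by support enumeration: try every
## subset of columns, solve ordinary least squares, keep feasible solutions
nnls_enumerate <- function(A, y) {
  k <- ncol(A)
  best <- list(rss = Inf, x = rep(0, k))
  for (mask in 0:(2^k - 1)) {
    cols <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    if (!length(cols)) {
      rss <- sum(y^2)
      if (rss < best$rss - 1e-12) best <- list(rss = rss, x = rep(0, k))
      next
    }
    fit <- stats::lm.fit(A[, cols, drop = FALSE], y)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    if (any(beta < -1e-9)) next
    rss <- sum(fit$residuals^2)
    if (rss < best$rss - 1e-12) {
      x <- rep(0, k); x[cols] <- beta
      best <- list(rss = rss, x = x)
    }
  }
  best
}

## small random genotype panel (two populations) with optional missing data
random_two_pop_panel <- function(nA, nB, L, missing = TRUE) {
  G <- matrix(sample(0:2, (nA + nB) * L, replace = TRUE), nA + nB)
  if (missing) {
    G[sample(length(G), ceiling(length(G) * 0.1))] <- NA
    G <- G[, colSums(!is.na(G)) > 0, drop = FALSE]
  }
  rownames(G) <- paste0("s", seq_len(nA + nB))
  colnames(G) <- paste0("l", seq_len(ncol(G)))
  sheet <- sample_sheet(rownames(G), rep(c("pA", "pB"), c(nA, nB)),
                        rep(c("M", "C"), c(nA, nB)))
  list(g = genotype_matrix(G), sheet = sheet, nA = nA, nB = nB)
}

## fully labeled miniature panel: one group per column block, every call set
## by hand; `blocks` is a named list group -> named list subspecies -> call
## matrix (samples x L)
panel_from_blocks <- function(blocks, L, outgroup = NULL) {
  calls <- NULL; rows <- NULL
  for (grp in names(blocks)) for (s in names(blocks[[grp]])) {
    m <- blocks[[grp]][[s]]
    rownames(m) <- paste0(s, "_", seq_len(nrow(m)))
    calls <- rbind(calls, m)
    rows <- rbind(rows, data.frame(sample = rownames(m), subspecies = s,
                                   group = grp))
  }
  if (!is.null(outgroup)) {
    rownames(outgroup) <- paste0("og_", seq_len(nrow(outgroup)))
    calls <- rbind(calls, outgroup)
    rows <- rbind(rows, data.frame(sample = rownames(outgroup),
                                   subspecies = "og", group = "OUTGROUP"))
  }
  colnames(calls) <- paste0("l", seq_len(ncol(calls)))
  list(g = genotype_matrix(calls),
       sheet = sample_sheet(rows$sample, rows$subspecies, rows$group))
}

## hand-built placement fixture trees on a fixed 11-leaf panel
placement_fixture <- function() {
  sheet <- sample_sheet(
    c("m1", "m2", "c1", "c2", "o1", "o2", "a1", "a2", "a3", "x1", "x2"),
    c("mel", "mel", "lig", "lig", "ana", "ana", "scu", "scu", "uni",
      "ogA", "ogB"),
    c("M", "M", "C", "C", "O", "O", "A", "A", "A", "OUTGROUP", "OUTGROUP"))
  trees <- list(
    sister_to_M = ape::read.tree(
      text = "(((x1,x2),(m1,m2)),((a1,a2),a3),((c1,c2),(o1,o2)));"),
    between_AM_and_CO = ape::read.tree(
      text = "((x1,x2),((m1,m2),((a1,a2),a3)),((c1,c2),(o1,o2)));"),
    within_A = ape::read.tree(
      text = "((((x1,x2),a3),(a1,a2)),(m1,m2),((c1,c2),(o1,o2)));"))
  list(sheet = sheet, trees = trees)
}

## one-unit panel with exactly n chromosomes (mixing diploids and one
## haploid when n is odd) and exactly S segregating loci out of L
chrom_panel <- function(n, S, L = max(S, 1) + 5) {
  if (n < 2) stop("need n >= 2")
  n_dip <- n %/% 2
  hap <- n %% 2 == 1
  n_samp <- n_dip + hap
  m <- matrix(0L, max(n_samp, 2), L) # padded with a second-unit sample
  rownames(m) <- paste0("s", seq_len(nrow(m)))
  colnames(m) <- paste0("l", seq_len(L))
  if (S > 0) m[1, seq_len(S)] <- 1L # het in one diploid: locus segregates
  ploidy <- rep(2L, nrow(m))
  if (hap) {
    ploidy[n_samp] <- 1L
    m[n_samp, ] <- 0L
  }
  subsp <- c(rep("unitA", n_samp), rep("pad", nrow(m) - n_samp))
  grp <- c(rep("M", n_samp), rep("C", nrow(m) - n_samp))
  sheet <- sample_sheet(rownames(m), subsp, grp, ploidy = ploidy)
  list(g = genotype_matrix(m), sheet = sheet)
}
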