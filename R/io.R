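#' Read a genotype panel from disk
#'
#' Two formats are supported. The tabular dialect is a TSV with header
#' `sample<TAB>locus1<TAB>locus2...` and cells in \{0, 1, 2, NA\}. VCF v4.x
#' files are read through the `vcfR` package: the GT field is parsed, `./.`
#' becomes a missing call and phasing is ignored. Records with more than one
#' ALT allele are rejected in strict mode (`multiallelic = "error"`, the
#' default) or dropped (`"drop"`).
#'
#' @param path path to the file.
#' @param format `"tabular"` or `"vcf"`.
#' @param multiallelic how to treat multi-allelic VCF records.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tabular", "vcf"),
                           multiallelic = c("error", "drop")) {
  format <- match.arg(format)
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tabular") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (colnames(df)[1] != "sample")
      stop("parse error at line 1: first column must be 'sample'")
    m <- as.matrix(df[, -1, drop = FALSE])
    bad <- which(!is.na(m) & !(m %in% c("0", "1", "2")))
    if (length(bad)) {
      row <- ((bad[1] - 1L) %% nrow(m)) + 1L
      stop("parse error at line ", row + 1L, ": cell value '",
           m[bad[1]], "' is not 0/1/2/NA")
    }
    storage.mode(m) <- "integer"
    rownames(m) <- df$sample
    return(genotype_matrix(m))
  }
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(vcf)
  multi <- grepl(",", alt) | is.na(alt) | alt == ""
  if (any(multi)) {
    if (multiallelic == "error")
      stop("non-biallelic VCF record(s) at ",
           paste(utils::head(vcfR::getPOS(vcf)[multi], 5), collapse = ", "),
           " (strict mode)")
    vcf <- vcf[!multi, ]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ids <- rownames(gt)
  if (is.null(ids) || anyNA(ids) || anyDuplicated(ids))
    ids <- paste0(vcfR::getCHROM(vcf), "_", vcfR::getPOS(vcf))
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  code[gt == "0/0"] <- 0L
  code[gt %in% c("0/1", "1/0")] <- 1L
  code[gt == "1/1"] <- 2L
  code[gt %in% c("0", "1")] <- 2L * (gt[gt %in% c("0", "1")] == "1") # haploid GT
  m <- t(code)
  rownames(m) <- colnames(gt)
  colnames(m) <- ids
  genotype_matrix(m)
}

#' Write a genotype panel in the tabular dialect
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @export
write_genotypes <- function(g, path) {
  df <- data.frame(sample = rownames(g), unclass(g), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample sheet (TSV with header
#' `sample<TAB>subspecies<TAB>group<TAB>species`)
#'
#' @param path file path.
#' @return [read_sample_sheet()] returns a [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample", "subspecies", "group")
  if (!all(need %in% colnames(df)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  sample_sheet(df$sample, df$subspecies, df$group,
               species = if ("species" %in% colnames(df)) df$species else NA,
               ploidy = if ("ploidy" %in% colnames(df)) df$ploidy else 2L)
}

#' @rdname read_sample_sheet
#' @param sheet a [sample_sheet()].
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a distance matrix in PHYLIP square format
#'
#' The writer emits the relaxed PHYLIP square dialect: a first line with the
#' number of taxa, then one line per taxon (label, whitespace, the full row).
#'
#' @param d symmetric numeric matrix with labels as dimnames.
#' @param path file path.
#' @export
write_phylip_dist <- function(d, path) {
  check_dist_matrix(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste(c(rownames(d)[i], sprintf("%.10g", d[i, ])),
                     collapse = "  "), con)
  invisible(path)
}

#' @rdname write_phylip_dist
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) < n + 1L)
    stop("malformed PHYLIP distance file: ", path)
  labs <- character(n)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(parts) != n + 1L)
      stop("parse error at line ", i + 1L, ": expected ", n + 1L, " fields")
    labs[i] <- parts[1]
    d[i, ] <- as.numeric(parts[-1])
  }
  dimnames(d) <- list(labs, labs)
  check_dist_matrix(d)
  d
}

## shared validation for symmetric zero-diagonal non-negative matrices
check_dist_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance input must be a square matrix")
  if (is.null(rownames(d))) stop("distance matrix must be labeled")
  if (any(is.na(d))) stop("distance matrix contains NA")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  if (any(d < 0)) stop("distance matrix has negative entries")
  invisible(d)
}

#' Write a list of trees as one-per-line Newick or as a Nexus TREES block
#'
#' Internal-node support labels, when present, are written rounded to integer
#' percentages (Newick convention); use the consensus object's `supports`
#' attribute for full precision.
#'
#' @param trees a `phylo` or list of `phylo` objects.
#' @param path file path.
#' @export
write_trees_newick <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  txt <- vapply(trees, function(tr) {
    if (!is.null(tr$node.label)) {
      lab <- suppressWarnings(as.numeric(tr$node.label))
      tr$node.label <- ifelse(is.na(lab), tr$node.label,
                              as.character(round(lab)))
    }
    ape::write.tree(tr)
  }, character(1))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_trees_newick
#' @export
write_trees_nexus <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  class(trees) <- "multiPhylo"
  ape::write.nexus(trees, file = path)
  invisible(path)
}

#' @rdname write_trees_newick
#' @export
read_trees_newick <- function(path) {
  trees <- ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- structure(list(trees),
                                                   class = "multiPhylo")
  trees
}
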