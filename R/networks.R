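#' NeighborNet circular split network
#'
#' Builds a circular split system from a distance matrix: (i) the NeighborNet
#' agglomeration (Bryant & Moulton 2004) produces a circular ordering of the
#' taxa; (ii) the weights of all n(n-1)/2 interval splits of that ordering are
#' estimated by least squares under non-negativity constraints against the
#' observed distances; (iii) splits with weight below `epsilon` are
#' discarded. On an additive (tree-metric) input the surviving splits are
#' exactly the tree's splits with weights equal to its branch lengths; on
#' conflicting data incompatible splits can coexist, which is what makes the
#' network display ambiguous signal.
#'
#' @param d symmetric non-negative matrix with zero diagonal, >= 4 labels.
#' @param epsilon weight threshold below which splits are dropped.
#' @return object of class `split_system`: list with `taxa` (input label
#'   order), `order` (taxa indices in circular order), `splits` (list of
#'   integer vectors over `taxa`, each the split side not containing the
#'   first taxon in the circular order), `weights`, `rss` (residual sum of
#'   squares of the constrained fit).
#' @export
neighbor_net <- function(d, epsilon = 1e-9) {
  check_dist_matrix(d)
  taxa <- rownames(d)
  n <- length(taxa)
  if (n < 4L) stop("need at least 4 labels")
  nn <- phangorn::neighborNet(stats::as.dist(d))
  spl <- nn$splits
  ord_labels <- attr(spl, "labels")[attr(spl, "cycle")]
  ord <- match(ord_labels, taxa)
  if (length(ord) != n || anyNA(ord)) {
    ## degenerate inputs (e.g. all-equal distances) can leave the
    ## agglomeration without a defined cycle; any ordering is then circular,
    ## so fall back to the input order
    ord <- seq_len(n)
  }
  ## all interval splits of the circular order, excluding position 1 so each
  ## side is canonical (never contains the first taxon of the ordering)
  sides <- list()
  for (i in 2:n) for (j in i:n)
    sides[[length(sides) + 1L]] <- sort(ord[i:j])
  memb <- matrix(FALSE, length(sides), n)
  for (s in seq_along(sides)) memb[s, sides[[s]]] <- TRUE
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  A <- matrix(0, nrow(pairs), length(sides))
  for (s in seq_along(sides))
    A[, s] <- as.numeric(xor(memb[s, pairs[, 1]], memb[s, pairs[, 2]]))
  dvec <- d[pairs]
  fit <- pracma::lsqnonneg(A, dvec)
  w <- fit$x
  keep <- w > epsilon
  structure(list(taxa = taxa, order = ord, splits = sides[keep],
                 weights = w[keep],
                 rss = sum((A %*% w - dvec)^2)),
            class = "split_system")
}

#' @export
print.split_system <- function(x, ...) {
  cat("circular split system on", length(x$taxa), "taxa:",
      length(x$splits), "splits, fit RSS =", format(x$rss, digits = 4), "\n")
  invisible(x)
}

#' Distance matrix induced by a split system
#'
#' The induced metric between two taxa is the sum of the weights of the
#' splits separating them.
#'
#' @param s a `split_system` (or any list with `taxa`, `splits`, `weights`).
#' @return symmetric matrix over `s$taxa`.
#' @export
split_system_distance <- function(s) {
  n <- length(s$taxa)
  d <- matrix(0, n, n, dimnames = list(s$taxa, s$taxa))
  for (k in seq_along(s$splits)) {
    side <- s$splits[[k]]
    inside <- seq_len(n) %in% side
    d[inside, !inside] <- d[inside, !inside] + s$weights[k]
    d[!inside, inside] <- d[!inside, inside] + s$weights[k]
  }
  d
}

#' Write a split system as a SplitsTree-compatible Nexus SPLITS block
#'
#' @param s a `split_system`.
#' @param path file path.
#' @export
write_splits_nexus <- function(s, path) {
  n <- length(s$taxa)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#NEXUS", con)
  writeLines(c("", "BEGIN Taxa;",
               sprintf("DIMENSIONS ntax=%d;", n), "TAXLABELS"), con)
  writeLines(sprintf("[%d] '%s'", seq_len(n), s$taxa), con)
  writeLines(c(";", "END; [Taxa]", "", "BEGIN Splits;",
               sprintf("DIMENSIONS ntax=%d nsplits=%d;", n, length(s$splits)),
               "FORMAT labels=no weights=yes confidences=no intervals=no;",
               sprintf("CYCLE %s;", paste(s$order, collapse = " ")),
               "MATRIX"), con)
  for (k in seq_along(s$splits))
    writeLines(sprintf("[%d, size: %d] \t %.10g \t %s,", k,
                       length(s$splits[[k]]), s$weights[k],
                       paste(s$splits[[k]], collapse = " ")), con)
  writeLines(c(";", "END; [Splits]"), con)
  invisible(path)
}

#' @rdname write_splits_nexus
#' @export
write_splits_tsv <- function(s, path) {
  df <- data.frame(
    split = vapply(s$splits, function(z) paste(s$taxa[z], collapse = "|"),
                   character(1)),
    size = lengths(s$splits),
    weight = s$weights)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
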