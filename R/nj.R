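#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler Q criterion:
#' Q(i, j) = (m - 2) d(i, j) - r_i - r_j with r_i the row sum over active
#' nodes. Ties in Q are broken deterministically by the minimal pair (i, j)
#' in label-sorted order. Estimated branch lengths that come out negative are
#' clamped to zero with the deficit transferred to the adjacent branch of the
#' same join (Kuhner-Felsenstein convention), preserving path lengths, which
#' matters for non-metric inputs such as F_ST matrices.
#'
#' @param d symmetric non-negative matrix with zero diagonal and unique
#'   labels (>= 3).
#' @return an unrooted `phylo` tree (class from \pkg{ape}).
#' @export
neighbor_joining <- function(d) {
  check_dist_matrix(d)
  labs <- rownames(d)
  if (length(labs) < 3L) stop("need at least 3 labels")
  if (any(grepl("[():,;[:space:]]", labs)))
    stop("labels may not contain Newick metacharacters or whitespace")
  ord <- order(labs)
  D <- d[ord, ord, drop = FALSE]
  node <- rownames(D)
  act <- seq_along(node)
  fmt <- function(x) sprintf("%.15g", x)
  while (length(act) > 3L) {
    m <- length(act)
    Dm <- D[act, act]
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    idx <- which(Q <= min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    dij <- Dm[i, j]
    vi <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- dij - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- max(vi + vj, 0); vj <- 0 }
    ai <- act[i]; aj <- act[j]
    rest <- act[-c(i, j)]
    dnew <- (D[ai, rest] + D[aj, rest] - dij) / 2
    node[ai] <- paste0("(", node[ai], ":", fmt(vi), ",", node[aj], ":",
                       fmt(vj), ")")
    D[ai, rest] <- dnew
    D[rest, ai] <- dnew
    act <- sort(c(rest, ai))
  }
  a <- act[1]; b <- act[2]; c3 <- act[3]
  v <- c((D[a, b] + D[a, c3] - D[b, c3]) / 2,
         (D[a, b] + D[b, c3] - D[a, c3]) / 2,
         (D[a, c3] + D[b, c3] - D[a, b]) / 2)
  v[v < 0] <- 0
  txt <- paste0("(", node[a], ":", fmt(v[1]), ",", node[b], ":", fmt(v[2]),
                ",", node[c3], ":", fmt(v[3]), ");")
  ape::read.tree(text = txt)
}
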