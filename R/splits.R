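#' Bipartitions (splits) of an unrooted tree
#'
#' Every edge of a leaf-labeled tree induces a bipartition of the leaf set.
#' Splits are canonicalized deterministically: leaves are indexed in sorted
#' label order and the stored side is the one *not* containing the first
#' (reference) leaf. Duplicate bipartitions arising from a rooted
#' representation are collapsed.
#'
#' @param tree a `phylo` object.
#' @param include_trivial include single-leaf (pendant-edge) splits.
#' @return list with `labels` (sorted leaf labels), `sides` (list of integer
#'   vectors, indices into `labels`), and `keys` (canonical string keys).
#' @export
tree_splits <- function(tree, include_trivial = FALSE) {
  labels <- sort(tree$tip.label)
  n <- length(labels)
  tipmap <- match(tree$tip.label, labels)
  po <- ape::reorder.phylo(tree, "postorder")
  nnode <- n + tree$Nnode
  sets <- vector("list", nnode)
  for (i in seq_len(n)) sets[[i]] <- tipmap[i]
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sides <- list(); keys <- character(0)
  for (k in seq_len(nrow(po$edge))) {
    s <- sets[[po$edge[k, 2]]]
    if (length(s) == 0L || length(s) >= n) next
    s <- sort(s)
    if (1L %in% s) s <- setdiff(seq_len(n), s)
    if (!include_trivial && (length(s) <= 1L || length(s) >= n - 1L)) next
    key <- paste(s, collapse = ",")
    if (!key %in% keys) {
      sides[[length(sides) + 1L]] <- s
      keys <- c(keys, key)
    }
  }
  list(labels = labels, sides = sides, keys = keys)
}

#' Are two splits compatible?
#'
#' Two bipartitions can coexist in one tree iff one of the four pairwise
#' side-intersections is empty. For canonical sides (both excluding the
#' reference leaf) this reduces to disjointness or containment.
#'
#' @param s1,s2 integer vectors: canonical sides over the same leaf indexing.
#' @return logical.
#' @export
splits_compatible <- function(s1, s2) {
  !any(s1 %in% s2) || all(s1 %in% s2) || all(s2 %in% s1)
}

## assert identical leaf sets across a list of trees, return sorted labels
common_labels <- function(trees) {
  labels <- sort(trees[[1]]$tip.label)
  for (tr in trees)
    if (!identical(sort(tr$tip.label), labels))
      stop("trees have differing leaf sets")
  labels
}

#' Majority-rule consensus tree
#'
#' Retains exactly the non-trivial splits present in more than `threshold`
#' (strictly) of the input trees; such splits are mutually compatible, and
#' unresolved regions become polytomies. Branch support is the occurrence
#' fraction times 100, stored as internal node labels and, at full precision,
#' in the `supports` attribute (a `data.frame` with `key`, `count`,
#' `support`).
#'
#' @param trees list of `phylo` objects with identical leaf sets.
#' @param threshold retain splits with frequency > threshold (default 0.5;
#'   values below 0.5 do not guarantee compatibility and are rejected).
#' @return a `phylo` tree with node labels carrying supports.
#' @export
majority_rule_consensus <- function(trees, threshold = 0.5) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("need at least one tree")
  if (threshold < 0.5) stop("threshold below 0.5 does not guarantee a tree")
  labels <- common_labels(trees)
  ntree <- length(trees)
  counts <- new.env(hash = TRUE)
  sides_by_key <- new.env(hash = TRUE)
  for (tr in trees) {
    sp <- tree_splits(tr)
    for (i in seq_along(sp$keys)) {
      k <- sp$keys[i]
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
      if (is.null(sides_by_key[[k]])) sides_by_key[[k]] <- sp$sides[[i]]
    }
  }
  keys <- ls(counts)
  cnt <- vapply(keys, function(k) counts[[k]], integer(1))
  keep <- cnt / ntree > threshold
  sides <- lapply(keys[keep], function(k) sides_by_key[[k]])
  support <- 100 * cnt[keep] / ntree
  tree <- splits_to_tree(labels, sides, support)
  attr(tree, "supports") <- data.frame(
    key = keys[keep], count = cnt[keep], support = support,
    row.names = NULL, stringsAsFactors = FALSE)
  tree
}

## build a (possibly multifurcating) tree from a laminar family of canonical
## sides; `support` labels internal nodes
splits_to_tree <- function(labels, sides, support = NULL) {
  n <- length(labels)
  k <- length(sides)
  if (k > 1L) {
    ord <- order(lengths(sides))
    sides <- sides[ord]
    if (!is.null(support)) support <- support[ord]
  }
  sizes <- lengths(sides)
  ## parent of cluster i = smallest cluster strictly containing it (0 = root)
  parent_cluster <- integer(k)
  for (i in seq_len(k)) {
    parent_cluster[i] <- 0L
    if (i < k) for (j in (i + 1L):k) {
      if (sizes[j] > sizes[i] && all(sides[[i]] %in% sides[[j]])) {
        parent_cluster[i] <- j
        break
      }
    }
  }
  ## parent of each leaf = smallest cluster containing it (0 = root)
  leaf_parent <- integer(n)
  for (l in seq_len(n)) {
    leaf_parent[l] <- 0L
    for (j in seq_len(k)) {
      if (l %in% sides[[j]]) { leaf_parent[l] <- j; break }
    }
  }
  render <- character(k)
  fmt_sup <- function(i) {
    if (is.null(support)) "" else sprintf("%.6g", support[i])
  }
  for (i in seq_len(k)) {
    kids <- c(labels[which(leaf_parent == i)], render[which(parent_cluster == i)])
    render[i] <- paste0("(", paste(kids, collapse = ","), ")", fmt_sup(i))
  }
  root_kids <- c(labels[which(leaf_parent == 0L)],
                 render[which(parent_cluster == 0L)])
  txt <- paste0("(", paste(root_kids, collapse = ","), ");")
  ape::read.tree(text = txt)
}

#' Partition trees by compatibility with a reference tree
#'
#' A tree is *compatible* with the reference iff every non-trivial split of
#' the reference is compatible with every non-trivial split of the tree
#' (split-wise compatibility). Returns the compatible set, the remainder, and
#' a second majority-rule consensus computed from the remainder (the
#' competing signal); an empty remainder is flagged with a `NULL` second
#' consensus.
#'
#' @param trees list of `phylo` objects.
#' @param reference a `phylo` tree on the same leaf set.
#' @param threshold consensus threshold for the second consensus.
#' @return list with `compatible`, `remainder`, `second_consensus`,
#'   `n_compatible`, `n_remainder`.
#' @export
filter_compatible <- function(trees, reference, threshold = 0.5) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  labels <- common_labels(c(unclass(trees), list(reference)))
  ref <- tree_splits(reference)
  is_compat <- vapply(trees, function(tr) {
    sp <- tree_splits(tr)
    for (r in ref$sides) for (s in sp$sides)
      if (!splits_compatible(r, s)) return(FALSE)
    TRUE
  }, logical(1))
  remainder <- trees[!is_compat]
  list(compatible = trees[is_compat],
       remainder = remainder,
       second_consensus = if (length(remainder))
         majority_rule_consensus(remainder, threshold) else NULL,
       n_compatible = sum(is_compat),
       n_remainder = sum(!is_compat))
}
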