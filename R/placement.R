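PLACEMENT_CATEGORIES <- c("sister_to_M", "sister_to_C", "sister_to_O",
                          "sister_to_A", "within_A", "within_M", "within_C",
                          "within_O", "between_AM_and_CO", "other")

#' Classify the outgroup attachment position of one tree
#'
#' The outgroup leaves must form a connected subtree (a single split);
#' otherwise the tree is classified `"other"`. Removing the outgroup subtree,
#' the attachment edge induces a bipartition of the ingroup leaves:
#' `sister_to_X` if one side is all-and-only lineage group X, `within_X` if a
#' proper subset of a single group X is separated, `between_AM_and_CO` if the
#' bipartition is exactly \{A u M\} vs \{C u O\}, and `"other"` otherwise
#' (including attachment at a polytomy). The classification depends only on
#' the topology: it is invariant to leaf order and branch-length rescaling.
#'
#' @param tree a `phylo` tree containing at least one outgroup leaf and at
#'   least one leaf from each ingroup lineage group present in `sheet`.
#' @param sheet a [sample_sheet()] covering the tree's leaves.
#' @return one of `sister_to_M/C/O/A`, `within_A/M/C/O`,
#'   `between_AM_and_CO`, `other`.
#' @export
classify_outgroup_placement <- function(tree, sheet) {
  tips <- tree$tip.label
  grp <- sheet$group[match(tips, sheet$sample)]
  if (anyNA(grp)) stop("tree leaves missing from sheet: ",
                       paste(tips[is.na(grp)], collapse = ", "))
  if (ape::is.rooted(tree) && length(tips) > 2L) {
    tree <- ape::unroot(tree)
    grp <- sheet$group[match(tree$tip.label, sheet$sample)]
    tips <- tree$tip.label
  }
  og <- which(grp == "OUTGROUP")
  if (!length(og)) stop("tree contains no outgroup leaf")
  ingroups <- intersect(c("M", "C", "O", "A"), unique(sheet$group))
  missing_grp <- setdiff(ingroups, unique(grp))
  if (length(missing_grp))
    stop("tree lacks leaves from group(s): ", paste(missing_grp, collapse = ", "))
  n <- length(tips)
  ## leaf sets below each node (tree kept in its own tip indexing)
  po <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- i
  for (k in seq_len(nrow(po$edge)))
    sets[[po$edge[k, 1]]] <- c(sets[[po$edge[k, 1]]], sets[[po$edge[k, 2]]])
  ogs <- sort(og)
  edge <- tree$edge
  attach_edge <- 0L
  og_below <- FALSE
  for (k in seq_len(nrow(edge))) {
    s <- sort(sets[[edge[k, 2]]])
    if (identical(s, ogs)) { attach_edge <- k; og_below <- TRUE; break }
    if (identical(sort(setdiff(seq_len(n), s)), ogs)) { attach_edge <- k; break }
  }
  if (!attach_edge) return("other") # outgroup not monophyletic
  v <- if (og_below) edge[attach_edge, 1] else edge[attach_edge, 2]
  u <- if (og_below) edge[attach_edge, 2] else edge[attach_edge, 1]
  ## neighbors of the ingroup-side attachment node, excluding the outgroup side
  nb <- c(edge[edge[, 1] == v, 2], edge[edge[, 2] == v, 1])
  nb <- setdiff(nb, u)
  if (length(nb) != 2L) return("other") # polytomy at the attachment point
  part <- lapply(nb, function(w) {
    s <- if (any(edge[, 1] == v & edge[, 2] == w)) sets[[w]]
         else setdiff(seq_len(n), sets[[v]])
    sort(setdiff(s, og))
  })
  gset <- function(g) sort(which(grp == g))
  for (side in part)
    for (g in ingroups)
      if (identical(side, gset(g))) return(paste0("sister_to_", g))
  if (all(c("A", "M", "C", "O") %in% ingroups)) {
    am <- sort(c(gset("A"), gset("M")))
    co <- sort(c(gset("C"), gset("O")))
    if ((identical(part[[1]], am) && identical(part[[2]], co)) ||
        (identical(part[[1]], co) && identical(part[[2]], am)))
      return("between_AM_and_CO")
  }
  for (side in part) {
    if (!length(side)) next
    gs <- unique(grp[side])
    if (length(gs) == 1L && length(side) < length(gset(gs)))
      return(paste0("within_", gs))
  }
  "other"
}

#' Outgroup-placement frequencies over a set of trees
#'
#' Classifies every tree with [classify_outgroup_placement()] and tallies
#' per-category counts and fractions (fractions sum to one).
#'
#' @param trees list of `phylo` objects.
#' @param sheet a [sample_sheet()].
#' @return object of class `placement_tally`: list with `categories`
#'   (per-tree classification), `counts`, `fractions`, `n`.
#' @export
placement_frequencies <- function(trees, sheet) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("need at least one tree")
  cats <- vapply(trees, classify_outgroup_placement, character(1),
                 sheet = sheet)
  counts <- table(factor(cats, levels = PLACEMENT_CATEGORIES))
  structure(list(categories = cats,
                 counts = stats::setNames(as.integer(counts),
                                          PLACEMENT_CATEGORIES),
                 fractions = stats::setNames(as.numeric(counts) / length(cats),
                                             PLACEMENT_CATEGORIES),
                 n = length(cats)),
            class = "placement_tally")
}

#' @export
print.placement_tally <- function(x, ...) {
  cat("outgroup placement over", x$n, "trees:\n")
  nz <- x$counts > 0
  for (k in names(x$counts)[nz])
    cat(sprintf("  %-18s %4d  (%.1f%%)\n", k, x$counts[[k]],
                100 * x$fractions[[k]]))
  invisible(x)
}
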