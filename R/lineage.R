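## Lineage forests: rooted trees of tracks across generations, with the
## census and completeness metrics used to benchmark tracking platforms.

#' Construct a lineage forest
#'
#' @param nodes vector of node ids (track or cell ids).
#' @param parent parent id for each node (`NA` for roots). Every parent must
#'   itself be a node; a node has at most two children.
#' @return object of class `lineage_forest`.
#' @export
lineage_forest <- function(nodes, parent) {
  if (length(nodes) != length(parent)) {
    stop_param("lineage_forest: nodes and parent must have equal length")
  }
  if (anyDuplicated(nodes)) stop_param("lineage_forest: duplicated node ids")
  known <- parent %in% nodes | is.na(parent)
  if (!all(known)) stop_param("lineage_forest: parent ids missing from nodes")
  nkids <- table(parent[!is.na(parent)])
  if (any(nkids > 2L)) stop_param("lineage_forest: a node has more than two children")
  fo <- structure(list(nodes = tibble::tibble(node = nodes, parent = parent)),
                  class = "lineage_forest")
  d <- forest_depths(fo)   # also detects cycles / orphan chains
  if (anyNA(d)) stop_param("lineage_forest: cyclic or disconnected parent links")
  fo
}

#' @export
print.lineage_forest <- function(x, ...) {
  d <- forest_depths(x)
  cat(sprintf("<lineage_forest> %d nodes, %d roots, max generation %d\n",
              nrow(x$nodes), sum(is.na(x$nodes$parent)), max(d)))
  invisible(x)
}

#' Node depths (generation index, root = 1)
#' @param forest a [lineage_forest()].
#' @return integer vector aligned with `forest$nodes$node`.
#' @export
forest_depths <- function(forest) {
  nd <- forest$nodes
  n <- nrow(nd)
  depth <- rep(NA_integer_, n)
  pidx <- match(nd$parent, nd$node)
  depth[is.na(pidx)] <- 1L
  current <- which(is.na(pidx))
  g <- 1L
  while (length(current) && g <= n) {
    kids <- which(pidx %in% current)
    kids <- kids[is.na(depth[kids])]
    depth[kids] <- g + 1L
    current <- kids
    g <- g + 1L
  }
  depth
}

#' Roots of a lineage forest
#' @param forest a [lineage_forest()].
#' @export
forest_roots <- function(forest) {
  forest$nodes$node[is.na(forest$nodes$parent)]
}

## node ids of the subtree rooted at `root`, with depths relative to root (= 1)
subtree_depths <- function(forest, root) {
  nd <- forest$nodes
  pidx <- match(nd$parent, nd$node)
  ids <- match(root, nd$node)
  if (is.na(ids)) stop_param("unknown root node")
  depth <- rep(NA_integer_, nrow(nd))
  depth[ids] <- 1L
  current <- ids
  while (length(current)) {
    kids <- which(pidx %in% current & is.na(depth))
    depth[kids] <- depth[match(nd$parent[kids], nd$node)] + 1L
    current <- kids
  }
  keep <- !is.na(depth)
  stats::setNames(depth[keep], nd$node[keep])
}

#' Lineage tree completeness
#'
#' Completeness of a tree evaluated as a `g`-generation tree: the number of
#' observed leaves at generation `g + 1` (the positions a complete
#' `g`-generation tree would fill, `2^g` of them) divided by `2^g`. An
#' incomplete tree with both daughters, three of four granddaughters and
#' two of eight great-granddaughters is 75% complete for a 2-generation
#' tree and 25% complete for a 3-generation tree.
#'
#' @param forest a [lineage_forest()].
#' @param g number of generations (division cycles), `>= 1`.
#' @param root root node of the tree to evaluate; may be omitted when the
#'   forest has a single root.
#' @return fraction in `[0, 1]`.
#' @export
completeness <- function(forest, g, root = NULL) {
  if (!is.numeric(g) || length(g) != 1L || g < 1 || g != round(g)) {
    stop_param("completeness: g must be an integer >= 1")
  }
  if (is.null(root)) {
    roots <- forest_roots(forest)
    if (length(roots) != 1L) {
      stop_param("completeness: forest has ", length(roots),
                 " roots; specify `root`")
    }
    root <- roots
  }
  d <- subtree_depths(forest, root)
  sum(d == g + 1) / 2^g
}

#' Lineage census of a forest
#'
#' For each generation count `g`, reports the number of lineages traced
#' over `g` generations (root-anchored paths with `g` observed division
#' cycles, i.e. nodes at generation `g + 1`), the number of complete trees
#' of length `g` (all `2^g` leaf positions observed), and the average
#' completeness over trees that reach at least one leaf at that depth.
#'
#' @param forest a [lineage_forest()].
#' @param max_g largest generation count to report (default: forest depth).
#' @return tibble with columns `g`, `n_lineages`, `n_complete_trees`,
#'   `mean_completeness`.
#' @export
census <- function(forest, max_g = NULL) {
  roots <- forest_roots(forest)
  subs <- lapply(roots, function(r) subtree_depths(forest, r))
  if (is.null(max_g)) max_g <- max(1L, max(unlist(subs)) - 1L)
  out <- lapply(seq_len(max_g), function(g) {
    leaves <- vapply(subs, function(d) sum(d == g + 1), numeric(1))
    tibble::tibble(
      g = g,
      n_lineages = sum(leaves),
      n_complete_trees = sum(leaves == 2^g),
      mean_completeness = if (any(leaves > 0)) {
        mean(leaves[leaves > 0] / 2^g)
      } else {
        NA_real_
      }
    )
  })
  do.call(rbind, out)
}

#' Newick serialisation of a lineage forest
#'
#' One Newick string per root; node labels are `t<id>`. Single-child nodes
#' (lineages where one daughter was lost) are kept as unary nodes.
#'
#' @param forest a [lineage_forest()].
#' @return character vector of Newick strings.
#' @export
forest_newick <- function(forest) {
  nd <- forest$nodes
  rec <- function(id) {
    ch <- nd$node[nd$parent %in% id & !is.na(nd$parent)]
    lab <- paste0("t", id)
    if (!length(ch)) return(lab)
    paste0("(", paste(vapply(ch, rec, character(1)), collapse = ","), ")", lab)
  }
  vapply(forest_roots(forest), function(r) paste0(rec(r), ";"), character(1))
}

#' Indented text rendering of a lineage forest
#' @param forest a [lineage_forest()].
#' @return character vector, one line per node.
#' @export
forest_text <- function(forest) {
  nd <- forest$nodes
  out <- character(0)
  rec <- function(id, depth) {
    out <<- c(out, paste0(strrep("  ", depth), "t", id))
    for (ch in nd$node[nd$parent %in% id & !is.na(nd$parent)]) rec(ch, depth + 1L)
  }
  for (r in forest_roots(forest)) rec(r, 0L)
  out
}
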