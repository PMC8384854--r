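# PCA of Procrustes residuals, distances in PC space, neighbor-joining
# phenograms, and Newick serialization.

#' Principal component analysis of shape residuals
#'
#' Eigen-analysis of the covariance of the (unscaled) residual vectors.
#' Configurations from all chambers/sections and specimens are pooled, so each
#' specimen traces an ontogenetic trajectory in PC space. Eigenvector signs
#' are fixed so the largest-magnitude element of each loading is positive,
#' which makes scores bit-reproducible across runs.
#'
#' @param residuals n x p matrix of residual vectors (rows labelled), or a
#'   [gpa()] result.
#' @param labels row labels; defaults to the rownames / GPA labels.
#' @return object of class `shape_pca` with `eigenvalues`,
#'   `variance_fraction`, `scores`, `loadings`, `center`, `labels`.
#' @export
shape_pca <- function(residuals, labels = NULL) {
  if (inherits(residuals, "gpa")) residuals <- residuals$residuals
  residuals <- as.matrix(residuals)
  if (nrow(residuals) < 2L) stop("need at least 2 configurations")
  if (is.null(labels)) labels <- rownames(residuals)
  if (is.null(labels)) labels <- sprintf("config_%d", seq_len(nrow(residuals)))
  pc <- stats::prcomp(residuals, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    v <- pc$rotation[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, 0)
  loadings <- sweep(pc$rotation, 2L, flip, `*`)
  scores <- sweep(pc$x, 2L, flip, `*`)
  rownames(scores) <- labels
  ev <- pc$sdev^2
  structure(list(eigenvalues = ev, variance_fraction = ev / sum(ev),
                 scores = scores, loadings = loadings, center = pc$center,
                 labels = labels),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  npc <- min(5L, length(x$eigenvalues))
  cat(sprintf("<shape_pca> %d configurations, %d components\n",
              nrow(x$scores), length(x$eigenvalues)))
  cat("variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_len(npc), 100 * x$variance_fraction[seq_len(npc)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Plot ontogenetic trajectories in PC space
#'
#' Scatter of two PCs; points sharing `series` (usually the specimen) are
#' connected in the order given, tracing ontogenetic trajectories.
#'
#' @param x a [shape_pca()].
#' @param pcs length-2 integer, which components to plot.
#' @param series optional factor grouping rows into trajectories.
#' @param col colors per row (recycled).
#' @param ... passed to [graphics::plot()].
#' @export
plot.shape_pca <- function(x, pcs = c(1L, 2L), series = NULL, col = 1, ...) {
  s <- x$scores[, pcs, drop = FALSE]
  pct <- 100 * x$variance_fraction[pcs]
  graphics::plot(s, col = col,
                 xlab = sprintf("PC%d (%.1f%%)", pcs[1L], pct[1L]),
                 ylab = sprintf("PC%d (%.1f%%)", pcs[2L], pct[2L]), ...)
  if (!is.null(series)) {
    col <- rep_len(col, nrow(s))
    for (g in unique(series)) {
      i <- which(series == g)
      graphics::lines(s[i, 1L], s[i, 2L], col = col[i[1L]])
    }
  }
  invisible(x)
}

#' Euclidean distance matrix in PC space
#'
#' Pairwise Euclidean distances over all PC scores for the selected
#' configurations. Because the loadings are orthonormal these equal the
#' distances between the centered residual vectors themselves.
#'
#' @param pca a [shape_pca()].
#' @param subset labels to include (default: all). Unknown labels error.
#' @return symmetric distance matrix with labels as dimnames.
#' @export
pc_distance_matrix <- function(pca, subset = NULL) {
  labels <- pca$labels
  if (is.null(subset)) subset <- labels
  missing <- setdiff(subset, labels)
  if (length(missing)) stop("unknown labels: ", paste(missing, collapse = ", "))
  idx <- match(subset, labels)
  m <- as.matrix(stats::dist(pca$scores[idx, , drop = FALSE]))
  dimnames(m) <- list(subset, subset)
  diag(m) <- 0
  m
}

#' Neighbor-joining phenogram
#'
#' Canonical agglomerative neighbor joining (Q-criterion join selection,
#' standard branch-length and distance-update formulas). On an additive
#' distance matrix the tree's path-length metric reproduces the input exactly.
#' Ties in Q are broken toward the lexicographically smallest label pair, so
#' the result is deterministic. Negative branch lengths arising at a join are
#' optionally clamped to zero with the deficit transferred to the sibling
#' branch, preserving path lengths through the join.
#'
#' @param D symmetric nonnegative distance matrix with zero diagonal and
#'   unique dimnames.
#' @param clamp_negative clamp negative branch lengths (default TRUE).
#' @return an [ape::read.tree()] `phylo` object, unrooted (attribute
#'   `"unrooted"` set); >= 3 tips give the usual trifurcating root.
#' @export
neighbor_joining <- function(D, clamp_negative = TRUE) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 tips")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- sprintf("t%d", 1:n)
  labels <- rownames(D)
  if (anyDuplicated(labels)) stop("duplicate tip labels")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(D < 0)) stop("distance matrix has negative entries")
  if (any(diag(D) != 0)) stop("distance matrix diagonal must be zero")
  fmt <- function(x) sprintf("%.10g", x)
  clamp2 <- function(la, lb) {
    if (!clamp_negative) return(c(la, lb))
    if (la < 0) { lb <- lb + la; la <- 0 }
    if (lb < 0) { la <- la + lb; lb <- 0 }
    c(max(la, 0), max(lb, 0))
  }
  nodes <- lapply(labels, newick_quote)   # newick fragment per active node
  first <- labels                          # lexicographic tie-break key
  if (n == 2L) {
    nwk <- sprintf("(%s:%s,%s:%s);", nodes[[1L]], fmt(D[1, 2] / 2),
                   nodes[[2L]], fmt(D[1, 2] / 2))
    tr <- parse_newick(nwk)
    return(tr)
  }
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(abs(qmin), 1), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key <- vapply(seq_len(nrow(cand)), function(ii) {
      pr <- sort(c(first[cand[ii, 1L]], first[cand[ii, 2L]]))
      paste(pr, collapse = "\r")
    }, "")
    pick <- cand[order(key)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    ll <- clamp2(li, lj)
    newfrag <- sprintf("(%s:%s,%s:%s)", nodes[[i]], fmt(ll[1L]),
                       nodes[[j]], fmt(ll[2L]))
    newfirst <- min(first[i], first[j])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    nodes <- c(nodes[keep], newfrag)
    first <- c(first[keep], newfirst)
    dimnames(D) <- NULL
  }
  # final 3-way join (or pass-through when n == 3)
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  v <- if (clamp_negative) pmax(c(v1, v2, v3), 0) else c(v1, v2, v3)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[[1L]], fmt(v[1L]),
                 nodes[[2L]], fmt(v[2L]), nodes[[3L]], fmt(v[3L]))
  parse_newick(nwk)
}

# quote a Newick label when it contains reserved characters
newick_quote <- function(label) {
  if (grepl("[][(){}:;,'\"[:space:]]", label))
    paste0("'", gsub("'", "''", label), "'")
  else label
}

#' Serialize a tree to Newick text
#'
#' Standard Newick with branch lengths written with a fixed number of
#' decimals, so write -> read -> write is bit-identical. Labels containing
#' reserved characters are quoted. Rooting is whatever the `phylo` object
#' carries (for [neighbor_joining()] trees, the serialization root is the
#' last join; the tree itself is unrooted).
#'
#' @param tree a `phylo` object.
#' @param file optional output path; when `NULL` the text is returned.
#' @param digits decimals for branch lengths.
#' @return the Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, file = NULL, digits = 6L) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  ord <- topo_order(tree, root, n_tip, children)
  fmt <- paste0("%.", digits, "f")
  frag <- character(n_node)
  frag[seq_len(n_tip)] <- vapply(tree$tip.label, newick_quote, "")
  for (v in rev(ord)) {  # children before parents
    eidx <- children[[as.character(v)]]
    frag[v] <- paste0("(", paste0(frag[tree$edge[eidx, 2L]], ":",
                                  sprintf(fmt, tree$edge.length[eidx]),
                                  collapse = ","), ")")
  }
  txt <- paste0(frag[root], ";")
  if (!is.null(file)) { writeLines(txt, file); return(invisible(txt)) }
  txt
}

# internal nodes in breadth-first order from the root (parents first);
# iterative so deep (caterpillar-like) trees cannot exhaust the call stack
topo_order <- function(tree, root, n_tip, children) {
  ord <- integer(0)
  queue <- root
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    ord <- c(ord, v)
    kids <- tree$edge[children[[as.character(v)]], 2L]
    queue <- c(queue, kids[kids > n_tip])
  }
  ord
}

#' Read a Newick file
#'
#' Parses standard Newick with branch lengths, including single-quoted labels
#' (with `''` escaping embedded quotes), which [ape::read.tree()] does not
#' support.
#'
#' @param file path to a Newick file.
#' @param text Newick text (alternative to `file`).
#' @return a `phylo` object.
#' @export
read_newick <- function(file = NULL, text = NULL) {
  if (is.null(text)) text <- paste(readLines(file), collapse = "")
  parse_newick(text)
}

# tokenizer + stack-based parser; returns an ape-compatible phylo object
parse_newick <- function(text) {
  chars <- strsplit(text, "")[[1L]]
  n <- length(chars)
  tokens <- list()
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t", "\n", "\r")) { i <- i + 1L; next }
    if (ch %in% c("(", ")", ",", ":", ";")) {
      tokens[[length(tokens) + 1L]] <- ch
      i <- i + 1L
    } else if (ch == "'") {
      lab <- character(0)
      i <- i + 1L
      while (i <= n) {
        if (chars[i] == "'") {
          if (i < n && chars[i + 1L] == "'") { lab <- c(lab, "'"); i <- i + 2L }
          else { i <- i + 1L; break }
        } else { lab <- c(lab, chars[i]); i <- i + 1L }
      }
      tokens[[length(tokens) + 1L]] <- list(label = paste(lab, collapse = ""))
    } else {
      j <- i
      while (j <= n && !chars[j] %in% c("(", ")", ",", ":", ";")) j <- j + 1L
      tokens[[length(tokens) + 1L]] <-
        list(label = paste(chars[i:(j - 1L)], collapse = ""))
      i <- j
    }
  }
  # build tree: nodes as a growing list; stack of open internal nodes
  parent <- integer(0); child <- integer(0); brlen <- numeric(0)
  tipnames <- character(0)
  node_id <- 0L
  new_node <- function() { node_id <<- node_id + 1L; node_id }
  is_tip <- logical(0)
  stack <- integer(0)
  last <- NA_integer_   # node the next ':' length applies to
  k <- 1L
  root <- NA_integer_
  while (k <= length(tokens)) {
    tk <- tokens[[k]]
    if (identical(tk, "(")) {
      v <- new_node(); is_tip[v] <- FALSE; tipnames[v] <- NA
      if (length(stack)) { parent <- c(parent, stack[length(stack)])
        child <- c(child, v); brlen <- c(brlen, NA) } else root <- v
      stack <- c(stack, v)
      k <- k + 1L
    } else if (identical(tk, ")")) {
      last <- stack[length(stack)]
      stack <- stack[-length(stack)]
      k <- k + 1L
      # optional internal label (ignored for tree structure)
      if (k <= length(tokens) && is.list(tokens[[k]])) k <- k + 1L
    } else if (identical(tk, ",")) {
      k <- k + 1L
    } else if (identical(tk, ":")) {
      lt <- tokens[[k + 1L]]
      brlen[which(child == last)] <- as.numeric(lt$label)
      k <- k + 2L
    } else if (identical(tk, ";")) {
      break
    } else {
      v <- new_node(); is_tip[v] <- TRUE; tipnames[v] <- tk$label
      parent <- c(parent, stack[length(stack)])
      child <- c(child, v); brlen <- c(brlen, NA)
      last <- v
      k <- k + 1L
    }
  }
  tips <- which(is_tip)
  internals <- which(!is_tip)
  n_tip <- length(tips)
  remap <- integer(node_id)
  remap[tips] <- seq_len(n_tip)
  remap[internals] <- n_tip + seq_along(internals)
  edge <- cbind(remap[parent], remap[child])
  tr <- list(edge = edge, edge.length = unname(brlen),
             tip.label = tipnames[tips], Nnode = length(internals))
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  attr(tr, "unrooted") <- TRUE
  tr
}

#' Tip bipartition of every internal edge
#'
#' For an unrooted tree, each internal edge splits the tips in two; returns
#' the side containing the edge's child subtree, with the edge length.
#' Used to locate the deepest (longest) bipartition and to test whether a
#' group of tips forms an exclusive clade.
#'
#' @param tree a `phylo` object.
#' @return list of `list(tips, length)`.
#' @export
tree_bipartitions <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  ord <- topo_order(tree, root, n_tip, children)
  tipsets <- vector("list", max(tree$edge))
  for (i in seq_len(n_tip)) tipsets[[i]] <- i
  for (v in rev(ord)) {  # children before parents
    kids <- tree$edge[children[[as.character(v)]], 2L]
    tipsets[[v]] <- unlist(tipsets[kids])
  }
  internal <- which(tree$edge[, 2L] > n_tip)
  lapply(internal, function(e) {
    list(tips = sort(tree$tip.label[tipsets[[tree$edge[e, 2L]]]]),
         length = tree$edge.length[e])
  })
}

#' Does a set of tips form an exclusive clade?
#'
#' TRUE when some edge of the (unrooted) tree separates exactly these tips
#' from all others.
#'
#' @param tree a `phylo` object.
#' @param tips character vector of tip labels.
#' @return logical.
#' @export
is_exclusive_clade <- function(tree, tips) {
  tips <- sort(tips)
  all_tips <- sort(tree$tip.label)
  if (!all(tips %in% all_tips)) stop("unknown tips")
  if (length(tips) %in% c(1L, length(all_tips))) return(TRUE)
  comp <- setdiff(all_tips, tips)
  for (bp in tree_bipartitions(tree)) {
    if (identical(bp$tips, tips) || identical(bp$tips, comp)) return(TRUE)
  }
  FALSE
}

#' The deepest bipartition of a tree
#'
#' The internal edge with the largest branch length; returns the two tip sets
#' it separates.
#'
#' @param tree a `phylo` object.
#' @return list with `side_a`, `side_b` (tip labels) and `length`.
#' @export
deepest_bipartition <- function(tree) {
  bps <- tree_bipartitions(tree)
  if (!length(bps)) stop("tree has no internal edge")
  i <- which.max(vapply(bps, `[[`, 0, "length"))
  side <- bps[[i]]$tips
  list(side_a = side, side_b = sort(setdiff(tree$tip.label, side)),
       length = bps[[i]]$length)
}
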