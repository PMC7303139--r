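# Clan analysis on unrooted trees.  A clan is a set of leaves separated
# from all other leaves by a single edge -- the unrooted analogue of a
# monophyletic group.  The orthology test asks for the smallest clan
# containing both a query sequence and its archetype and inspects the
# family labels inside it.

# adjacency list over node ids (1..Ntip+Nnode)
.treeAdjacency <- function(tree) {
  nn <- ape::Ntip(tree) + tree$Nnode
  adj <- vector("list", nn)
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1L]; b <- tree$edge[k, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# numeric support value of an internal node label ("" and non-numeric -> NA)
.nodeSupport <- function(tree, node) {
  nt <- ape::Ntip(tree)
  if (is.null(tree$node.label) || node <= nt) return(NA_real_)
  lab <- tree$node.label[node - nt]
  if (is.null(lab) || is.na(lab) || !nzchar(lab)) return(NA_real_)
  suppressWarnings(as.numeric(lab))
}

#' Enumerate all clans of an unrooted tree
#'
#' Every edge of the tree defines a bipartition of the leaves; both sides
#' are clans.  A binary unrooted tree with n leaves therefore has
#' 2n - 3 edges and 2(2n - 3) clans.
#'
#' @param tree a \code{phylo}.
#' @return a \code{data.frame} with one row per clan: \code{edge} (row
#'   index into \code{tree$edge}), \code{side} (\code{"child"} or
#'   \code{"parent"}), \code{size}, \code{support} (support of the
#'   defining edge, NA for pendant edges and unlabeled nodes) and a list
#'   column \code{leaves}.
#' @export
treeClans <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  nt <- ape::Ntip(tree)
  tips <- tree$tip.label
  # postorder accumulation of the tip set below each edge's child
  below <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) below[[i]] <- i
  po <- ape::postorder(tree)
  for (k in po) {
    par <- tree$edge[k, 1L]; ch <- tree$edge[k, 2L]
    below[[par]] <- c(below[[par]], below[[ch]])
  }
  rows <- vector("list", 2L * nrow(tree$edge))
  for (k in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[k, 2L]
    side1 <- sort(tips[below[[ch]]])
    side2 <- sort(setdiff(tips, side1))
    sup <- .nodeSupport(tree, ch)
    rows[[2L * k - 1L]] <- list(edge = k, side = "child",
                                size = length(side1), support = sup,
                                leaves = side1)
    rows[[2L * k]] <- list(edge = k, side = "parent",
                           size = length(side2), support = sup,
                           leaves = side2)
  }
  data.frame(
    edge = vapply(rows, `[[`, 0L, "edge"),
    side = vapply(rows, `[[`, "", "side"),
    size = vapply(rows, `[[`, 0L, "size"),
    support = vapply(rows, `[[`, 0, "support"),
    leaves = I(lapply(rows, `[[`, "leaves")),
    stringsAsFactors = FALSE)
}

#' Is a leaf set a clan of the tree?
#'
#' @param tree a \code{phylo}.
#' @param S a non-empty proper subset of the leaf labels.
#' @return \code{TRUE} iff the removal of some single edge separates S
#'   exactly from its complement.
#' @examples
#' tr <- readNewickUnrooted(text = "((A,B),(C,D));")
#' isClan(tr, c("A", "B"))  # TRUE
#' isClan(tr, c("A", "C"))  # FALSE
#' @export
isClan <- function(tree, S) {
  tips <- tree$tip.label
  if (length(S) == 0L) stop("S must be non-empty")
  if (!all(S %in% tips)) stop("S contains labels not in the tree")
  if (setequal(S, tips)) stop("S must be a proper subset of the leaves")
  key <- paste(sort(S), collapse = "\r")
  cl <- treeClans(tree)
  any(vapply(cl$leaves, function(x) paste(x, collapse = "\r") == key,
             logical(1L)))
}

#' Smallest clan containing a query and its archetype
#'
#' Among all clans containing the given leaves, returns the one of
#' minimum size (ties: clans with a support value first, then the
#' lexicographically smallest leaf set -- ties only arise on
#' multifurcating trees).  When family labels are supplied, the clan is
#' turned into an orthology call: \code{not_orthologue} if the clan
#' contains a leaf of a different family, otherwise
#' \code{orthologue_supported} when the defining edge's support reaches
#' the threshold and \code{orthologue_unsupported} when it does not (or
#' no support is recorded).  Leaves without a family label are treated
#' as uninformative and never contradict orthology.
#'
#' @param tree a \code{phylo}.
#' @param query,archetype leaf labels that the clan must contain.
#' @param extra additional leaf labels the clan must contain.
#' @param families optional named character vector mapping leaf labels
#'   to family labels; the archetype's family is the reference.
#' @param supportThreshold bootstrap support (percent) needed for a
#'   \code{supported} call; default 75.
#' @return a list of class \code{"ClanResult"}: \code{query},
#'   \code{archetype}, \code{smallest_clan} (sorted leaf labels),
#'   \code{support}, \code{is_pair_clan}, \code{call}, \code{trivial}
#'   (TRUE when only the full leaf set would contain the input, in which
#'   case \code{smallest_clan} is the full leaf set and no call is
#'   made).
#' @export
smallestClan <- function(tree, query, archetype, extra = character(),
                         families = NULL, supportThreshold = 75) {
  must <- unique(c(query, archetype, extra))
  if (length(must) < 2L) stop("need at least two distinct leaves")
  tips <- tree$tip.label
  if (!all(must %in% tips))
    stop("leaves not in tree: ",
         paste(setdiff(must, tips), collapse = ", "))
  cl <- treeClans(tree)
  keep <- vapply(cl$leaves, function(x) all(must %in% x), logical(1L))
  res <- list(query = query, archetype = archetype)
  if (!any(keep)) {
    res$smallest_clan <- sort(tips)
    res$support <- NA_real_
    res$is_pair_clan <- FALSE
    res$call <- NA_character_
    res$trivial <- TRUE
    class(res) <- "ClanResult"
    return(res)
  }
  cand <- cl[keep, , drop = FALSE]
  cand <- cand[order(cand$size, is.na(cand$support),
                     vapply(cand$leaves, paste, "", collapse = "\r")), ,
               drop = FALSE]
  pick <- cand[1L, ]
  clan <- pick$leaves[[1L]]
  support <- pick$support
  res$smallest_clan <- clan
  res$support <- support
  res$trivial <- FALSE
  if (!is.null(families)) {
    archFam <- unname(families[archetype])
    if (is.na(archFam)) stop("archetype has no family label")
    others <- setdiff(clan, query)
    fams <- families[others]
    foreign <- !is.na(fams) & fams != archFam
    res$is_pair_clan <- !any(foreign)
    res$call <- if (any(foreign)) "not_orthologue"
      else if (!is.na(support) && support >= supportThreshold)
        "orthologue_supported"
      else "orthologue_unsupported"
  } else {
    res$is_pair_clan <- NA
    res$call <- NA_character_
  }
  class(res) <- "ClanResult"
  res
}

#' @export
print.ClanResult <- function(x, ...) {
  cat(sprintf("ClanResult: %s + %s -> clan of %d leaves%s%s\n",
              x$query, x$archetype, length(x$smallest_clan),
              if (!is.na(x$support)) sprintf(", support %.0f", x$support)
              else "",
              if (!is.na(x$call)) paste0(", call ", x$call) else ""))
  invisible(x)
}

#' Adjacent groups of a clan
#'
#' The adjacent group plays the role of the sister group in an unrooted
#' tree: the clans B disjoint from the input whose union with it is
#' again a clan, maximal with that property.  For a clan defined by an
#' edge into a degree-3 node these are the two clans meeting at that
#' node.
#'
#' @param tree a \code{phylo}.
#' @param clan a leaf set that is a clan of the tree.
#' @return a list of sorted leaf-label vectors (possibly empty when the
#'   complement is a single leaf or the attachment node multifurcates).
#' @export
adjacentGroup <- function(tree, clan) {
  tips <- tree$tip.label
  cl <- treeClans(tree)
  key <- paste(sort(clan), collapse = "\r")
  hit <- which(vapply(cl$leaves, function(x)
    paste(x, collapse = "\r") == key, logical(1L)))
  if (length(hit) == 0L) stop("the given leaf set is not a clan")
  k <- cl$edge[hit[1L]]
  par <- tree$edge[k, 1L]; ch <- tree$edge[k, 2L]
  # v = the node on the complement side of the defining edge
  childSide <- cl$side[hit[1L]] == "child"
  v <- if (childSide) par else ch
  u <- if (childSide) ch else par
  nt <- ape::Ntip(tree)
  if (v <= nt) return(list())            # complement is a single leaf
  adj <- .treeAdjacency(tree)
  nbr <- setdiff(adj[[v]], u)
  if (length(nbr) != 2L) return(list())  # multifurcation: no maximal B
  lapply(nbr, function(w) {
    seen <- logical(nt + tree$Nnode)
    seen[v] <- TRUE
    stack <- w
    leaves <- integer()
    while (length(stack)) {
      x <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (seen[x]) next
      seen[x] <- TRUE
      if (x <= nt) leaves <- c(leaves, x)
      stack <- c(stack, setdiff(adj[[x]], which(seen)))
    }
    sort(tips[leaves])
  })
}
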