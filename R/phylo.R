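# Ancestral-state reconstruction of repeat classes on a dated phylogeny,
# and emergence (stem-interval) reporting per class.
#
# The default is unordered Fitch parsimony, generalized to polytomies by
# iterated pairwise set intersection in the tree's fixed (cladewise) child
# order. An ordered mode (Wagner-style, cost = ordinal distance along
# ABSENT < PROTO < PRIMITIVE < VARIABLE) reflects the progressive
# emergence narrative; it is a Sankoff dynamic program and never reports
# fewer changes than unordered Fitch on the same data.

# internal nodes in children-before-parent order, plus fixed child lists
tree_orders <- function(phy) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  root <- ntip + 1L
  kids <- vector("list", nn)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]
    kids[[p]] <- c(kids[[p]], phy$edge[e, 2])
  }
  parent <- integer(nn)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  # topological depth from the root (cladewise edges visit parents first)
  depth <- integer(nn)
  cw <- ape::reorder.phylo(phy, "cladewise")$edge
  for (e in seq_len(nrow(cw))) depth[cw[e, 2]] <- depth[cw[e, 1]] + 1L
  internal <- (ntip + 1L):nn
  internal_postorder <- internal[order(depth[internal], decreasing = TRUE)]
  list(ntip = ntip, nn = nn, root = root, kids = kids,
       postorder = internal_postorder, parent = parent)
}

#' Reconstruct ancestral repeat classes by parsimony
#'
#' @param tree A `dated_tree` (see [as_dated_tree()]) or `ape::phylo`.
#' @param leaf_states Named character vector mapping every tip label to a
#'   state in `classes`. Missing tips are a hard error listing them.
#' @param ordered `FALSE` (default) for unordered Fitch; `TRUE` for the
#'   ordered mode where a change between states costs their ordinal
#'   distance.
#' @param classes State space in ordinal order (default
#'   [repeat_classes()]).
#' @return An `emergence_report`: `node_states` (resolved state per node,
#'   tips first in `ape` numbering), `state_sets` (bottom-up candidate
#'   sets), `changes` (Fitch union count, or total ordinal cost in ordered
#'   mode), `origins` (data frame of origin nodes per class with node and
#'   parent ages; `parent_age` is `Inf` at the root; `convergent` flags
#'   classes with multiple independent origins), plus the `tree`,
#'   `leaf_states` and `ordered` flag.
#'
#' @details Top-down resolution of ambiguous nodes prefers the parent's
#'   resolved state, then the ordinally lower state, making the
#'   reconstruction deterministic. An origin node is a node whose resolved
#'   state differs from its parent's (the root is the origin of its own
#'   state).
#' @export
fitch_reconstruct <- function(tree, leaf_states, ordered = FALSE,
                              classes = repeat_classes()) {
  if (inherits(tree, "phylo")) tree <- as_dated_tree(tree)
  stopifnot(inherits(tree, "dated_tree"))
  phy <- tree$phylo
  ord <- tree_orders(phy)
  tips <- phy$tip.label
  miss <- setdiff(tips, names(leaf_states))
  if (length(miss)) {
    stop("no state for leaf/leaves: ", paste(miss, collapse = ", "))
  }
  ls <- unname(leaf_states[tips])
  tip_idx <- match(ls, classes)
  if (anyNA(tip_idx)) {
    stop("unknown state(s): ",
         paste(unique(ls[is.na(tip_idx)]), collapse = ", "))
  }
  K <- length(classes)
  nn <- ord$nn
  ntip <- ord$ntip
  root <- ntip + 1L
  state <- integer(nn)
  state[seq_len(ntip)] <- tip_idx
  sets <- vector("list", nn)

  if (!ordered) {
    for (i in seq_len(ntip)) sets[[i]] <- tip_idx[i]
    changes <- 0L
    for (nd in ord$postorder) {
      ks <- ord$kids[[nd]]
      S <- sets[[ks[1]]]
      for (k in ks[-1]) {
        I <- intersect(S, sets[[k]])
        if (length(I)) {
          S <- I
        } else {
          S <- sort(union(S, sets[[k]]))
          changes <- changes + 1L
        }
      }
      sets[[nd]] <- S
    }
    for (nd in rev(ord$postorder)) {     # preorder over internal nodes
      if (nd == root) {
        state[nd] <- min(sets[[nd]])
      } else {
        ps <- state[ord$parent[nd]]
        state[nd] <- if (ps %in% sets[[nd]]) ps else min(sets[[nd]])
      }
    }
  } else {
    cost <- matrix(Inf, nn, K)
    for (i in seq_len(ntip)) cost[i, tip_idx[i]] <- 0
    for (nd in ord$postorder) {
      for (s in seq_len(K)) {
        tot <- 0
        for (k in ord$kids[[nd]]) {
          tot <- tot + min(cost[k, ] + abs(s - seq_len(K)))
        }
        cost[nd, s] <- tot
      }
      sets[[nd]] <- which(cost[nd, ] == min(cost[nd, ]))
    }
    for (i in seq_len(ntip)) sets[[i]] <- tip_idx[i]
    changes <- min(cost[root, ])
    for (nd in rev(ord$postorder)) {
      if (nd == root) {
        cand <- which(cost[nd, ] == min(cost[nd, ]))
        state[nd] <- min(cand)
      } else {
        ps <- state[ord$parent[nd]]
        v <- cost[nd, ] + abs(seq_len(K) - ps)
        cand <- which(v == min(v))
        state[nd] <- if (ps %in% cand) ps else min(cand)
      }
    }
    # tips below a differently-resolved parent keep their observed state;
    # nothing to resolve there (tip costs are 0/Inf)
  }

  resolved <- classes[state]
  labels <- c(tips, phy$node.label %||% paste0("node_", (ntip + 1L):nn))
  if (length(labels) < nn) labels <- c(labels, paste0("node_", (length(labels) + 1L):nn))
  labels[!nzchar(labels)] <- paste0("node_", which(!nzchar(labels)))
  ages <- tree$ages
  is_origin <- vapply(seq_len(nn), function(nd) {
    nd == root || resolved[ord$parent[nd]] != resolved[nd]
  }, logical(1))
  ons <- which(is_origin)
  parent_age <- ages[pmax(ord$parent[ons], 1L)]  # placeholder at the root
  parent_age[ons == root] <- Inf
  origins <- data.frame(
    class = resolved[ons],
    node = ons,
    label = labels[ons],
    node_age = ages[ons],
    parent_age = parent_age,
    stringsAsFactors = FALSE)
  n_orig <- table(origins$class)
  origins$convergent <- unname(n_orig[origins$class] > 1)
  origins <- origins[order(class_rank(origins$class), -origins$node_age), ]
  rownames(origins) <- NULL
  structure(list(tree = tree, classes = classes, ordered = ordered,
                 node_states = setNames(resolved, labels),
                 state_sets = sets, changes = changes,
                 origins = origins, leaf_states = setNames(ls, tips)),
            class = "emergence_report")
}

#' Stem intervals of class origins
#'
#' For each repeat class present among the leaves, the age interval of the
#' branch on which it arose: `lower_ma` is the origin node's age and
#' `upper_ma` its parent's age. A class fixed at the root gets
#' `upper_ma = Inf`, rendered `">rootage"` in the label. Classes with
#' several independent origins are listed once per origin and flagged
#' convergent. Classes absent from all leaves are omitted with a note.
#'
#' @param report An `emergence_report` from [fitch_reconstruct()].
#' @return Data frame with columns `class`, `lower_ma`, `upper_ma`,
#'   `convergent`, `label`.
#' @export
emergence_ages <- function(report) {
  stopifnot(inherits(report, "emergence_report"))
  present <- unique(report$leaf_states)
  absent <- setdiff(report$classes, present)
  if (length(absent)) {
    message("class(es) absent from all leaves, omitted: ",
            paste(absent, collapse = ", "))
  }
  orig <- report$origins[report$origins$class %in% present, , drop = FALSE]
  lab <- ifelse(is.infinite(orig$parent_age),
                sprintf(">%g", orig$node_age),
                sprintf("%g-%g", orig$node_age, orig$parent_age))
  out <- data.frame(class = orig$class,
                    lower_ma = orig$node_age,
                    upper_ma = orig$parent_age,
                    convergent = orig$convergent,
                    label = lab,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.emergence_report <- function(x, ...) {
  cat(sprintf("Parsimony reconstruction (%s): %s change%s\n",
              if (x$ordered) "ordered" else "unordered Fitch",
              format(x$changes), if (x$changes == 1) "" else "s"))
  print(x$origins)
  invisible(x)
}
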