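#' Build a dated phylogeny from a taxonomic classification
#'
#' Constructs a rooted, ultrametric tree from a family/genus/language
#' classification table. All language families attach directly to the root at
#' depth `root_depth`; each family's crown node sits at depth `family_depth`;
#' taxonomic levels nested inside a family (here: genus) are spaced at equal
#' height fractions between the family crown and the tips. Levels that contain
#' a single child are collapsed, so two languages that are alone in their
#' family always coalesce at `family_depth`.
#'
#' @param classification data.frame with columns `family`, `genus`,
#'   `language_id`. One row per language; `language_id` must be unique.
#' @param family_depth crown age of every language family, in years
#'   (default 6000).
#' @param root_depth age of the common root joining all families, in years
#'   (default 60000). Must satisfy `family_depth <= root_depth`.
#' @param outgroup optional language id (typically an isolate) used to root
#'   the tree: its lineage is rotated to be the first child of the root.
#'   An error is raised if it is absent from the classification.
#' @param min_branch minimum branch length in years (default 1); guards the
#'   positive definiteness of downstream covariance matrices.
#' @return an [ape::read.tree()] `"phylo"` object with branch lengths in
#'   years and tip labels equal to `language_id`.
#' @examples
#' cls <- data.frame(
#'   family = rep(c("F1", "F2"), each = 2),
#'   genus = c("g1", "g2", "g3", "g3"),
#'   language_id = c("a", "b", "c", "d")
#' )
#' tr <- build_tree(cls)
#' patristic_matrix(tr)["a", "c"] # two families: 2 * 60000
#' @export
build_tree <- function(classification, family_depth = 6000,
                       root_depth = 60000, outgroup = NULL,
                       min_branch = 1) {
  stopifnot(is.data.frame(classification), nrow(classification) >= 1)
  need <- c("family", "genus", "language_id")
  if (!all(need %in% names(classification))) {
    stop("classification needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(classification$language_id)) {
    stop("duplicate language ids in classification")
  }
  if (!(family_depth > 0 && family_depth <= root_depth)) {
    stop("require 0 < family_depth <= root_depth")
  }
  cls <- classification
  cls[] <- lapply(cls, as.character)

  if (!is.null(outgroup)) {
    if (!outgroup %in% cls$language_id) {
      stop("outgroup '", outgroup, "' absent from classification")
    }
    og_fam <- cls$family[cls$language_id == outgroup]
    fams <- c(og_fam, setdiff(unique(cls$family), og_fam))
  } else {
    fams <- unique(cls$family)
  }

  # newick for the subtree of one family; parent_h is the height of the node
  # the returned string attaches to
  family_newick <- function(rows, parent_h) {
    genera <- unique(rows$genus)
    if (nrow(rows) == 1) {
      return(sprintf("%s:%.8f", rows$language_id, max(parent_h, min_branch)))
    }
    if (length(genera) == 1) {
      # single genus collapses onto the family crown
      crown <- family_depth
      tips <- sprintf("%s:%.8f", rows$language_id, max(crown, min_branch))
      return(sprintf("(%s):%.8f", paste(tips, collapse = ","),
                     max(parent_h - crown, min_branch)))
    }
    crown <- family_depth
    genus_h <- family_depth / 2 # one internal level, evenly spaced
    parts <- vapply(genera, function(g) {
      sub <- rows[rows$genus == g, , drop = FALSE]
      if (nrow(sub) == 1) {
        sprintf("%s:%.8f", sub$language_id, max(crown, min_branch))
      } else {
        tips <- sprintf("%s:%.8f", sub$language_id, max(genus_h, min_branch))
        sprintf("(%s):%.8f", paste(tips, collapse = ","),
                max(crown - genus_h, min_branch))
      }
    }, character(1))
    sprintf("(%s):%.8f", paste(parts, collapse = ","),
            max(parent_h - crown, min_branch))
  }

  parts <- vapply(fams, function(f) {
    family_newick(cls[cls$family == f, , drop = FALSE], root_depth)
  }, character(1))
  if (length(parts) == 1 && nrow(cls) == 1) {
    txt <- sprintf("(%s);", parts)
  } else if (length(parts) == 1) {
    # one family: its stem to the root is kept as a root edge
    txt <- sprintf("%s;", parts)
  } else {
    txt <- sprintf("(%s);", paste(parts, collapse = ","))
  }
  tree <- ape::read.tree(text = txt)
  tree
}

#' Rescale node heights by Grafen's method
#'
#' Assigns each internal node the height `(n_descendant_tips - 1) /
#' (n_tips - 1)` (so the root has height 1 and tips height 0), raises
#' heights to the power `rho`, and multiplies by `total_depth`. Values of
#' `rho` below 1 push splits toward the root; values above 1 push them
#' toward the tips. Topology is preserved.
#'
#' @param tree a `"phylo"` object.
#' @param rho positive exponent.
#' @param total_depth depth assigned to the root after rescaling, in years.
#' @return the rescaled `"phylo"` object.
#' @export
grafen_rescale <- function(tree, rho, total_depth = 60000) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.numeric(rho) || length(rho) != 1 || rho <= 0) {
    stop("rho must be a single positive number")
  }
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  # tips per node
  ntips <- numeric(n_tip + n_node)
  ntips[seq_len(n_tip)] <- 1
  for (e in rev(seq_len(nrow(tree$edge)))) {
    ntips[tree$edge[e, 1]] <- ntips[tree$edge[e, 1]] + ntips[tree$edge[e, 2]]
  }
  h <- ifelse(ntips > 1, ((ntips - 1) / (n_tip - 1))^rho, 0) * total_depth
  tree$edge.length <- h[tree$edge[, 1]] - h[tree$edge[, 2]]
  tree$edge.length <- pmax(tree$edge.length, .Machine$double.eps)
  tree
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the path between every pair of tips.
#'
#' @param tree a `"phylo"` object with branch lengths.
#' @return symmetric matrix with zero diagonal, dimnames = tip labels.
#' @export
patristic_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  d <- stats::cophenetic(tree)
  d[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Minimum number of state changes under parsimony
#'
#' Computes the parsimony score of a discrete character on a (possibly
#' multifurcating) rooted tree using Hartigan's generalization of the Fitch
#' algorithm: at each internal node the optimal state set is the set of
#' states held by the maximal number of children, and each child outside
#' that set contributes one change. Exact for polytomies.
#'
#' @param tree a `"phylo"` object.
#' @param trait named vector of tip states (names = tip labels). States may
#'   be any discrete values; binary 0/1 in typical use.
#' @return integer parsimony score.
#' @export
fitch_parsimony <- function(tree, trait) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (!all(tips %in% names(trait))) stop("every tip needs a trait value")
  x <- trait[tips]
  if (anyNA(x)) stop("missing tip values")
  states <- sort(unique(as.character(x)))
  n_tip <- length(tips)
  n_all <- n_tip + tree$Nnode
  # state sets as logical matrix: rows nodes, cols states
  sets <- matrix(FALSE, n_all, length(states))
  sets[cbind(seq_len(n_tip), match(as.character(x), states))] <- TRUE
  children <- split(tree$edge[, 2], tree$edge[, 1])
  score <- 0L
  po <- ape::reorder.phylo(tree, "postorder")
  done <- rep(FALSE, n_all)
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1]
    if (done[parent]) next
    kids <- children[[as.character(parent)]]
    if (all(vapply(kids, function(k) k <= n_tip || done[k], logical(1)))) {
      cnt <- colSums(sets[kids, , drop = FALSE])
      k_max <- max(cnt)
      sets[parent, ] <- cnt == k_max
      score <- score + length(kids) - k_max
      done[parent] <- TRUE
    }
  }
  # iterate until all internal nodes resolved (handles any edge ordering)
  while (!all(done[(n_tip + 1):n_all])) {
    progressed <- FALSE
    for (parent in which(!done)) {
      if (parent <= n_tip) next
      kids <- children[[as.character(parent)]]
      if (is.null(kids)) next
      if (all(vapply(kids, function(k) k <= n_tip || done[k], logical(1)))) {
        cnt <- colSums(sets[kids, , drop = FALSE])
        k_max <- max(cnt)
        sets[parent, ] <- cnt == k_max
        score <- score + length(kids) - k_max
        done[parent] <- TRUE
        progressed <- TRUE
      }
    }
    if (!progressed) stop("malformed tree: could not complete traversal")
  }
  as.integer(score)
}

#' Rate of cultural change implied by a parsimony reconstruction
#'
#' Total branch length of the tree divided by the parsimony score: the
#' average number of years of evolution per inferred state change.
#'
#' @inheritParams fitch_parsimony
#' @return years per change (numeric scalar).
#' @export
change_rate <- function(tree, trait) {
  score <- fitch_parsimony(tree, trait)
  if (score == 0) {
    stop("trait is constant on the tree: change rate undefined")
  }
  sum(tree$edge.length) / score
}
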