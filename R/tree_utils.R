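# Helpers over ape "phylo" trees: label management, clade maps, encoding.

#' Ensure a tree has unique internal-node labels
#'
#' Internal nodes without labels are auto-named `N1..Nk` in postorder, so
#' repeated runs on the same topology produce the same names. Collisions
#' between tip and internal labels are rejected.
#'
#' @param tree A rooted `phylo` tree.
#' @return The tree with complete `node.label`.
#' @export
ensure_node_labels <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) {
    stop("tree must be rooted; root it explicitly before analysis")
  }
  nnode <- tree$Nnode
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", nnode)
  lab[is.na(lab)] <- ""
  if (any(lab == "")) {
    po <- ape::reorder.phylo(tree, "postorder")
    ntip <- length(tree$tip.label)
    # internal nodes in the order their subtrees complete
    internal_po <- unique(po$edge[, 1][po$edge[, 1] > ntip])
    auto <- stats::setNames(paste0("N", seq_along(internal_po)), internal_po)
    idx <- which(lab == "")
    lab[idx] <- auto[as.character(idx + ntip)]
  }
  all_lab <- c(tree$tip.label, lab)
  if (anyDuplicated(all_lab)) {
    stop("duplicate node labels: ",
         paste(unique(all_lab[duplicated(all_lab)]), collapse = ", "))
  }
  tree$node.label <- lab
  tree
}

# labels for node indices 1..(ntip+nnode)
node_labels <- function(tree) {
  c(tree$tip.label, tree$node.label)
}

root_node <- function(tree) length(tree$tip.label) + 1L

#' Validate a branch-to-class clade map against a tree
#'
#' A clade map assigns every branch of the tree to a model class; a branch
#' is identified by the label of its child node, so the map must contain
#' one entry per non-root node.
#'
#' @param tree Rooted `phylo` with node labels (see [ensure_node_labels()]).
#' @param clade_map Named character vector: child-node label -> class name.
#' @return The clade map, reordered to the tree's edge order.
#' @export
validate_clade_map <- function(tree, clade_map) {
  tree <- ensure_node_labels(tree)
  labs <- node_labels(tree)
  child_labs <- labs[tree$edge[, 2]]
  missing <- setdiff(child_labs, names(clade_map))
  if (length(missing)) {
    stop("clade map is missing branches (child nodes): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(clade_map), child_labs)
  if (length(extra)) {
    stop("clade map names unknown branches: ", paste(extra, collapse = ", "))
  }
  clade_map[child_labs]
}

# Encode sequences (named character strings) as an integer matrix,
# rows = names(seqs), values 1..4 for A,C,G,T, NA for gaps/ambiguity.
encode_sequences <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("sequences have unequal lengths")
  }
  chars <- unlist(strsplit(toupper(seqs), ""), use.names = FALSE)
  mat <- matrix(match(chars, NUC), nrow = length(seqs), byrow = TRUE)
  rownames(mat) <- names(seqs)
  mat
}

decode_sequence <- function(states) {
  paste(ifelse(is.na(states), "-", NUC[states]), collapse = "")
}
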