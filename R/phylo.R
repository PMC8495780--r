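#' Read a phylogeny from a Newick file or string
#'
#' Strict Newick ingestion for the dated species tree that underlies the
#' phylogenetic relatedness matrix. Branch lengths are mandatory: the
#' relatedness matrix is built from shared root-to-MRCA path lengths, so a
#' cladogram without lengths is not usable and is rejected rather than
#' patched with invented unit lengths.
#'
#' Tip labels containing spaces are normalised to underscores (and a note is
#' emitted), matching the usual `Genus_species` convention of published
#' trees.
#'
#' @param path Path to a Newick file, or a single string containing a Newick
#'   description (detected by the presence of a terminal `;`).
#' @return An object of class [ape::phylo] with `edge.length` set.
#'   Polytomies are preserved.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
#' @export
read_newick <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  text <- if (grepl("[(;]", path)) {
    path
  } else {
    if (!file.exists(path)) stop("Newick file not found: ", path)
    paste(readLines(path, warn = FALSE), collapse = "")
  }
  check_newick_balance(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse failure: ", conditionMessage(e))
  )
  if (is.null(tree)) stop("Newick parse failure: no tree found in input")
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  if (is.null(tree$edge.length)) {
    stop("Newick tree has no branch lengths; lengths are required and are never invented")
  }
  if (anyNA(tree$edge.length)) {
    stop("Newick tree has missing branch lengths on ",
         sum(is.na(tree$edge.length)), " edge(s)")
  }
  if (any(tree$edge.length < 0)) {
    stop("Newick tree has negative branch lengths")
  }
  if (any(grepl(" ", tree$tip.label, fixed = TRUE))) {
    gs_log("phylo", "replacing spaces with underscores in %d tip label(s)",
           sum(grepl(" ", tree$tip.label, fixed = TRUE)))
    tree$tip.label <- gsub(" ", "_", tree$tip.label, fixed = TRUE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  tree
}

# Scan for unbalanced parentheses, reporting the byte offset of the first
# violation so malformed hand-edited files are easy to fix.
check_newick_balance <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("Newick format error: unmatched ')' at byte offset %d", i))
      }
    }
  }
  if (depth > 0L) {
    stop(sprintf(
      "Newick format error: %d unclosed '(' at end of input (byte offset %d)",
      depth, length(chars)))
  }
  invisible(TRUE)
}

#' Shared root-to-MRCA path-length matrix
#'
#' For species i and j, entry (i, j) is the summed branch length from the
#' root to their most recent common ancestor; the diagonal holds
#' root-to-tip depths. Under Brownian motion this is the expected trait
#' covariance structure (up to the rate), which is why it feeds the
#' phylogenetic species effect.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param species Character vector of tip labels to retain, in the desired
#'   output order. Defaults to all tips. Extra tips in the tree are simply
#'   ignored (equivalently, pruned: pruning never changes entries among
#'   retained tips).
#' @return A symmetric numeric matrix with `species` as dimnames.
#' @export
shared_path_matrix <- function(tree, species = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  species <- species %||% tree$tip.label
  species <- gsub(" ", "_", species, fixed = TRUE)
  missing <- setdiff(species, tree$tip.label)
  if (length(missing) > 0L) {
    stop("species absent from tree: ", paste(missing, collapse = ", "))
  }
  M <- ape::vcv.phylo(tree)
  M[species, species, drop = FALSE]
}

#' Scale a shared-path matrix to a correlation (relatedness) matrix
#'
#' Divides each entry by the geometric mean of the corresponding tip depths,
#' so the diagonal is exactly 1. For an ultrametric tree this equals
#' dividing by the tree depth; per-pair scaling keeps non-ultrametric trees
#' valid too. Unit diagonal makes the phylogenetic variance component
#' directly comparable with the non-phylogenetic one, which the heritability
#' index requires.
#'
#' @param M Symmetric positive semi-definite matrix with strictly positive
#'   diagonal (e.g. from [shared_path_matrix()]).
#' @return Correlation matrix of class `relatedness_matrix` (a plain matrix
#'   with an S3 class tag), diagonal exactly 1.
#' @export
to_correlation <- function(M) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  if (max(abs(M - t(M))) > 1e-8 * max(1, max(abs(M)))) {
    stop("matrix is not symmetric")
  }
  d <- diag(M)
  if (any(d <= 0)) {
    stop("zero or negative diagonal (zero-depth tip): ",
         paste(rownames(M)[d <= 0], collapse = ", "))
  }
  s <- 1 / sqrt(d)
  A <- M * tcrossprod(s)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  dimnames(A) <- dimnames(M)
  class(A) <- c("relatedness_matrix", class(A))
  A
}

#' Average relatedness matrix across a set of trees
#'
#' When some species lack a verified phylogenetic placement, tree databases
#' return a set of stochastically resolved trees rather than a single one.
#' The per-tree correlation matrices are averaged elementwise (the mean of
#' PSD matrices is PSD) and the diagonal re-set to exactly 1.
#'
#' @param trees A list of `phylo` objects (or a `multiPhylo`).
#' @param species Tip labels to retain; must be present in every tree.
#' @return A `relatedness_matrix`.
#' @export
average_correlation <- function(trees, species = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (length(trees) == 0L) stop("empty tree list")
  species <- species %||% trees[[1L]]$tip.label
  acc <- NULL
  for (tr in trees) {
    A <- to_correlation(shared_path_matrix(tr, species))
    acc <- if (is.null(acc)) unclass(A) else acc + unclass(A)
  }
  A <- acc / length(trees)
  diag(A) <- 1
  class(A) <- c("relatedness_matrix", class(A))
  A
}

# Cholesky factor of a relatedness matrix, adding diagonal jitter when the
# factorization fails numerically. Returns the upper factor R (A = R'R).
chol_relatedness <- function(A, jitter = 1e-8) {
  A <- unclass(A)
  R <- tryCatch(chol(A), error = function(e) NULL)
  tries <- 0L
  while (is.null(R) && tries < 6L) {
    gs_log("phylo", "relatedness matrix near-singular; adding jitter %g", jitter)
    R <- tryCatch(chol(A + diag(jitter, nrow(A))), error = function(e) NULL)
    jitter <- jitter * 100
    tries <- tries + 1L
  }
  if (is.null(R)) stop("relatedness matrix could not be factorized even with jitter")
  R
}
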