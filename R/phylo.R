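#' Parse a Newick tree
#'
#' Reads a rooted Newick string (or file) into an `ape::phylo` object and
#' validates it for comparative analysis: at least two uniquely labelled
#' tips, branch lengths present and positive. Polytomies are accepted.
#'
#' @param text Newick string, or `NULL` when `file` is given.
#' @param file optional path to a Newick file (one tree).
#' @return An object of class `phylo`.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) && is.null(file))
    stop("provide a Newick string or a file", call. = FALSE)
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE),
                                   collapse = "")
  # cheap structural pre-check so malformed input reports a position
  bal <- cumsum(ifelse(strsplit(text, "")[[1]] == "(", 1L,
                       ifelse(strsplit(text, "")[[1]] == ")", -1L, 0L)))
  if (length(bal) && (any(bal < 0L) || bal[length(bal)] != 0L)) {
    pos <- if (any(bal < 0L)) which(bal < 0L)[1L] else length(bal)
    stop(sprintf("unbalanced parentheses in Newick near character %d", pos),
         call. = FALSE)
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("could not parse Newick string", call. = FALSE)
  validate_phylogeny(tr)
}

#' Validate a phylogeny for comparative analysis
#'
#' @param tree a `phylo` object.
#' @return The tree, invisibly unchanged, or an error.
#' @export
validate_phylogeny <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::Ntip(tree) < 2L)
    stop("tree must have at least 2 tips", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree must have branch lengths on every edge", call. = FALSE)
  if (any(tree$edge.length <= 0))
    stop("all branch lengths must be positive", call. = FALSE)
  tree
}

#' Write a tree as Newick
#'
#' @param tree a `phylo` object.
#' @param file optional output path; when `NULL` the string is returned.
#' @return Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, file = NULL) {
  s <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Brownian phylogenetic covariance matrix
#'
#' The expected trait covariance under Brownian motion: entry (i, j) is the
#' shared root-to-ancestor path length of tips i and j (the depth of their
#' most recent common ancestor); the diagonal holds root-to-tip distances.
#' The tree is not assumed ultrametric.
#'
#' @param tree a validated `phylo` object.
#' @return Object of class `"phylo_vcv"`: list with `labels` (tip order) and
#'   `C` (n x n covariance matrix, dimnames = labels).
#' @export
phylo_covariance <- function(tree) {
  validate_phylogeny(tree)
  C <- ape::vcv.phylo(tree)
  structure(list(labels = rownames(C), C = C), class = "phylo_vcv")
}

#' @export
print.phylo_vcv <- function(x, ...) {
  cat(sprintf("Phylogenetic covariance: %d tips, max depth %.4g\n",
              length(x$labels), max(diag(x$C))))
  invisible(x)
}

# accept a phylo_vcv or a bare matrix; return the matrix
.vcv_mat <- function(C) {
  if (inherits(C, "phylo_vcv")) return(C$C)
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  C
}

#' Pagel's lambda transformation
#'
#' Multiplies the off-diagonal entries of a phylogenetic covariance matrix by
#' `lambda`, leaving the diagonal unchanged. `lambda = 1` retains the full
#' Brownian structure; `lambda = 0` yields a diagonal matrix, equivalent to
#' ordinary least squares in a regression context.
#'
#' @param C a `"phylo_vcv"` object or covariance matrix.
#' @param lambda scalar in \[0, 1\].
#' @return Same type as `C`, transformed.
#' @export
lambda_transform <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]", call. = FALSE)
  m <- .vcv_mat(C)
  d <- diag(m)
  out <- m * lambda
  diag(out) <- d
  if (inherits(C, "phylo_vcv")) {
    C$C <- out
    C
  } else out
}

#' Scale a covariance matrix to unit maximum diagonal
#'
#' Used by the ordinal model for identifiability of the phylogenetic
#' standard deviation.
#'
#' @inheritParams lambda_transform
#' @return Same type as `C`, scaled so `max(diag(C)) == 1`.
#' @export
scale_vcv <- function(C) {
  m <- .vcv_mat(C)
  out <- m / max(diag(m))
  if (inherits(C, "phylo_vcv")) {
    C$C <- out
    C
  } else out
}

#' Match a phylogeny to a species table
#'
#' Relabels tips according to a substitution map (used when a study species
#' is represented in the tree by its closest relative), prunes the tree to
#' the species set, and returns the index that orders the table rows as the
#' pruned tree's tips.
#'
#' @param tree a validated `phylo` object.
#' @param species character vector of species names (e.g. trait-table rows).
#' @param substitutions optional named character vector or 2-column data
#'   frame mapping table name -> tip name.
#' @return List with `tree` (pruned, relabelled) and `order` (integer index
#'   such that `species[order]` equals the pruned tree's tip labels).
#' @export
match_tips <- function(tree, species, substitutions = NULL) {
  validate_phylogeny(tree)
  stopifnot(is.character(species), length(species) >= 2L)
  if (anyDuplicated(species))
    stop("duplicate species in table: ",
         paste(unique(species[duplicated(species)]), collapse = ", "),
         call. = FALSE)
  if (!is.null(substitutions)) {
    if (is.data.frame(substitutions)) {
      if (ncol(substitutions) < 2L)
        stop("substitution map needs 2 columns (table_name, tip_name)",
             call. = FALSE)
      substitutions <- setNames(as.character(substitutions[[2L]]),
                                as.character(substitutions[[1L]]))
    }
    if (anyDuplicated(names(substitutions)) ||
        anyDuplicated(substitutions))
      stop("substitution map must be one-to-one", call. = FALSE)
    for (nm in names(substitutions)) {
      tip <- substitutions[[nm]]
      hit <- which(tree$tip.label == tip)
      if (length(hit) == 1L) tree$tip.label[hit] <- nm
    }
  }
  missing <- setdiff(species, tree$tip.label)
  if (length(missing))
    stop("species not resolvable in tree: ",
         paste(missing, collapse = ", "), call. = FALSE)
  pruned <- ape::keep.tip(tree, species)
  ord <- match(pruned$tip.label, species)
  list(tree = pruned, order = ord)
}

#' Read a substitution map from CSV
#'
#' Two columns: `table_name`, `tip_name`.
#'
#' @param path CSV file path.
#' @return Named character vector (table name -> tip name).
#' @export
read_substitutions <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("substitution CSV needs 2 columns", call. = FALSE)
  setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}
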