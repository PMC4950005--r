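#' Read and validate an ultrametric tree from Newick
#'
#' Parses a Newick string or file with [ape::read.tree()] and validates the
#' result as a time-calibrated (ultrametric) phylogeny: rooted, strictly
#' bifurcating, non-negative branch lengths, and all tips equidistant from
#' the root to a relative tolerance. Posterior-sample Newick files routinely
#' carry rounding error of the order 1e-8, so tip depths within
#' `tol * crown age` of the mean depth are snapped onto it by adjusting
#' pendant edges; larger deviations are an error naming the worst tip.
#'
#' @param x a Newick string (anything containing `(`) or a file path. Files
#'   may contain several trees, one per line.
#' @param tol relative ultrametricity tolerance.
#' @return an object of class `"phylo"` (a `"multiPhylo"` list when the file
#'   has several trees), validated and, if needed, snapped to ultrametric.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' crown_age(tr)
read_newick <- function(x, tol = 1e-6) {
  tr <- if (grepl("(", x, fixed = TRUE)) ape::read.tree(text = x)
        else ape::read.tree(x)
  if (is.null(tr)) stop("malformed Newick input")
  if (inherits(tr, "multiPhylo")) {
    out <- lapply(tr, validate_ultrametric, tol = tol)
    class(out) <- "multiPhylo"
    return(out)
  }
  validate_ultrametric(tr, tol = tol)
}

#' Write a tree to Newick
#'
#' @param tree a `phylo` object.
#' @param file optional path; when `NULL` the Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string, invisibly when writing to a file.
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' @rdname read_newick
#' @param tree a `phylo` object to validate in place.
#' @export
validate_ultrametric <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  n <- length(tree$tip.label)
  if (n < 2) stop("tree must have at least 2 tips")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (!ape::is.binary(tree) || tree$Nnode != n - 1)
    stop("tree contains polytomies or an unrooted basal trifurcation; ",
         "resolve them before analysis")
  depth <- ape::node.depth.edgelength(tree)[seq_len(n)]
  dbar <- mean(depth)
  if (dbar <= 0) stop("tree has zero depth")
  dev <- abs(depth - dbar)
  if (max(dev) > tol * dbar) {
    worst <- tree$tip.label[which.max(dev)]
    stop(sprintf(
      "tree is not ultrametric: tip '%s' has depth %.8g vs mean %.8g",
      worst, depth[which.max(dev)], dbar))
  }
  if (max(dev) > 0) {
    # snap: absorb the slop into the pendant edges
    pend <- match(seq_len(n), tree$edge[, 2])
    tree$edge.length[pend] <- tree$edge.length[pend] + (dbar - depth)
    if (any(tree$edge.length < 0))
      stop("ultrametric repair produced a negative pendant edge")
  }
  tree
}

#' Crown age of an ultrametric tree
#'
#' @param tree a `phylo` object.
#' @return age of the root (Myr, with tips at the present).
#' @export
crown_age <- function(tree) {
  max(ape::node.depth.edgelength(tree))
}

#' Branching times of an ultrametric tree
#'
#' Ages of the internal nodes measured back from the present (tips at age 0),
#' sorted in decreasing order so that the first element is the crown age.
#' This vector is the sufficient statistic for every homogeneous birth-death
#' likelihood in the package.
#'
#' @param tree a validated ultrametric `phylo` object.
#' @return numeric vector of length `n_tips - 1`, decreasing.
#' @export
#' @examples
#' branching_times(read_newick("((A:1,B:1):1,C:2);")) # 2 1
branching_times <- function(tree) {
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  ages <- max(depth[seq_len(n)]) - depth[(n + 1):(2 * n - 1)]
  ages[ages < 0] <- 0
  sort(unname(ages), decreasing = TRUE)
}

#' Attach clade tags to tips
#'
#' Clade membership drives clade-specific sampling fractions. Tags are given
#' either as a named character vector (names = tip labels) or a two-column
#' TSV file (`tip_label`, `clade`) without or with a header.
#'
#' @param tree a `phylo` object.
#' @param tags named character vector, or path to a two-column TSV.
#' @return the tree with a `clade_tags` component (named by tip label).
#' @export
set_clade_tags <- function(tree, tags) {
  if (is.character(tags) && length(tags) == 1 && file.exists(tags)) {
    df <- read.delim(tags, header = FALSE, stringsAsFactors = FALSE)
    if (identical(tolower(df[1, 1]), "tip_label")) df <- df[-1, , drop = FALSE]
    tags <- setNames(as.character(df[[2]]), df[[1]])
  }
  miss <- setdiff(tree$tip.label, names(tags))
  if (length(miss) > 0)
    stop("tips without a clade tag: ", paste(head(miss, 5), collapse = ", "))
  tree$clade_tags <- tags[tree$tip.label]
  tree
}

#' Clade-specific sampling fractions
#'
#' For each tagged clade, the fraction of its known extant richness present
#' as tips in the tree: `sampled / richness`. Mirrors the treatment of
#' incomplete sampling across the principal subclades of an Andean radiation
#' (e.g. a 550-species clade with 191 species sampled gives 0.35).
#'
#' @param tree a `phylo` with `clade_tags` (see [set_clade_tags()]).
#' @param full_richness named numeric vector of total extant species per clade.
#' @return named numeric vector of fractions in (0, 1].
#' @export
clade_sampling_fractions <- function(tree, full_richness) {
  if (is.null(tree$clade_tags)) stop("tree has no clade tags")
  counts <- table(tree$clade_tags)
  miss <- setdiff(names(counts), names(full_richness))
  if (length(miss) > 0)
    stop("clades missing from full_richness: ", paste(miss, collapse = ", "))
  rich <- full_richness[names(counts)]
  if (any(rich < counts))
    stop("full richness smaller than sampled count for: ",
         paste(names(counts)[rich < counts], collapse = ", "))
  setNames(as.numeric(counts) / as.numeric(rich), names(counts))
}
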