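#' @include formats-var.R
#' @importFrom ape read.tree
NULL

#' Read a clonal-evolution tree from NEWICK
#'
#' Parses a strictly binary clonal phylogeny in which every internal node
#' is labelled with the structural variant gained at that bifurcation and
#' weighted (via its branch length, or the root edge for the root) by the
#' conditional splitting fraction \eqn{f(V)} in [0,1].  Leaves carry
#' terminal genotype labels and, optionally, informational subpopulation
#' weights.  The reserved internal label \code{"-"} denotes an empty event
#' (multiclonal origin): its fraction shapes the population split but maps
#' to no variant.
#'
#' @param path NEWICK file, or \code{NULL} when \code{text} is given.
#' @param text NEWICK string (a trailing \code{";"} is added if missing).
#' @param gaining which listed child of each internal node gains the
#'   node's variant: \code{"first"} (default) or \code{"second"}.
#' @return A \linkS4class{ClonalTree}.
#' @examples
#' tr <- readClonalTree(text =
#'   "((C1, C2) V5: 0.8, ((C3, C4) V4:0.8, (C5, C6) V3: 0.9) V2:0.6) V1:0.5")
#' variantFrequencies(tr)
#' @export
readClonalTree <- function(path = NULL, text = NULL,
                           gaining = c("first", "second")) {
    gaining <- match.arg(gaining)
    if (is.null(text)) {
        if (is.null(path) || !file.exists(path))
            stop(sprintf("NEWICK file '%s' not found", path))
        text <- paste(readLines(path), collapse = "")
    }
    text <- trimws(text)
    if (!endsWith(text, ";"))
        text <- paste0(text, ";")
    phy <- tryCatch(ape::read.tree(text = text),
                    error = function(e) stop(sprintf(
                        "NEWICK parse error: %s", conditionMessage(e))))
    if (is.null(phy))
        stop("NEWICK parse error: unreadable tree")
    n <- length(phy$tip.label)
    m <- phy$Nnode
    kids <- tabulate(phy$edge[, 1L], nbins = n + m)
    if (any(kids[(n + 1L):(n + m)] != 2L))
        stop("structural error: every internal node must be binary")
    labs <- phy$node.label
    if (is.null(labs) || any(!nzchar(labs)))
        stop("every internal node needs a variant label")
    f <- numeric(m)
    for (j in seq_len(m)) {
        node <- n + j
        if (node == n + 1L) {            # root: fraction rides the root edge
            if (is.null(phy$root.edge) || !is.finite(phy$root.edge))
                stop(sprintf("missing conditional fraction for root node '%s'",
                             labs[j]))
            f[j] <- phy$root.edge
        } else {
            e <- which(phy$edge[, 2L] == node)
            if (is.null(phy$edge.length) || !is.finite(phy$edge.length[e]))
                stop(sprintf("missing conditional fraction for node '%s'",
                             labs[j]))
            f[j] <- phy$edge.length[e]
        }
    }
    if (any(f < 0 | f > 1))
        stop(sprintf("validation error: fraction %g outside [0,1]",
                     f[which(f < 0 | f > 1)[1L]]))
    obj <- new("ClonalTree", phylo = phy, fractions = setNames(f, labs),
               gaining = gaining)
    validObject(obj)
    obj
}

#' @rdname readClonalTree
#' @param x a \linkS4class{ClonalTree}.
#' @export
conditionalFractions <- function(x) {
    stopifnot(is(x, "ClonalTree"))
    x@fractions
}

## children of internal node `node`, in NEWICK input order
.treeChildren <- function(phy, node) {
    phy$edge[phy$edge[, 1L] == node, 2L]
}

#' Tertiary path vectors of a clonal tree
#'
#' For each leaf i and internal-node variant j the entry is 0 when the
#' bifurcation is not on the root-to-leaf path, 1 when it is on the path
#' but the leaf's lineage did not gain the variant, and 2 when the lineage
#' gained it (i.e. the path descends through the gaining child).
#'
#' @param tree a \linkS4class{ClonalTree}.
#' @return Integer matrix, leaves x internal nodes, dimnames from the
#'   genotype and variant labels.
#' @export
pathVectors <- function(tree) {
    stopifnot(is(tree, "ClonalTree"))
    phy <- tree@phylo
    n <- length(phy$tip.label)
    m <- phy$Nnode
    C <- matrix(0L, nrow = n, ncol = m,
                dimnames = list(phy$tip.label, names(tree@fractions)))
    gain_idx <- if (tree@gaining == "first") 1L else 2L
    walk <- function(node, path_nodes, path_codes) {
        if (node <= n) {
            C[node, path_nodes] <<- path_codes
            return(invisible())
        }
        kids <- .treeChildren(phy, node)
        j <- node - n
        for (k in 1:2) {
            code <- if (k == gain_idx) 2L else 1L
            walk(kids[k], c(path_nodes, j), c(path_codes, code))
        }
    }
    walk(n + 1L, integer(), integer())
    C
}

#' Final leaf (subpopulation) frequencies
#'
#' The final population frequency of each terminal genotype: the product,
#' over the internal nodes on its root-to-leaf path, of \eqn{f(V_j)} where
#' the lineage gains the variant and \eqn{1 - f(V_j)} where it does not.
#' Frequencies sum to one over leaves; a leaf reaches frequency zero
#' (a deceased population) when some fraction on its path is 0 or 1.
#'
#' @param tree a \linkS4class{ClonalTree}.
#' @return Named numeric vector of \eqn{F(C_i)} over leaves.
#' @export
leafFrequencies <- function(tree) {
    C <- pathVectors(tree)
    f <- tree@fractions
    F <- apply(C, 1L, function(ci) {
        on <- which(ci > 0L)
        prod(ifelse(ci[on] == 2L, f[on], 1 - f[on]))
    })
    setNames(as.numeric(F), rownames(C))
}

#' Final marginal variant frequencies
#'
#' The concurrent carrier fraction of each variant among all extant
#' cells: the marginal sum of the leaf frequencies over leaves whose path
#' vector carries the variant.  Events upstream on a carrying lineage
#' always have frequency at least that of their downstream events.
#'
#' @param tree a \linkS4class{ClonalTree}.
#' @return Named numeric vector of \eqn{F(V_j)} over internal nodes
#'   (including any \code{"-"} placeholder events).
#' @export
variantFrequencies <- function(tree) {
    C <- pathVectors(tree)
    Fc <- leafFrequencies(tree)
    Fv <- vapply(seq_len(ncol(C)),
                 function(j) sum(Fc[C[, j] == 2L]), numeric(1))
    setNames(Fv, colnames(C))
}

#' Rewrite VAR fractions from a clonal tree
#'
#' Replaces the allele fraction of every variant named by an internal
#' node of the tree with its computed final marginal frequency; records
#' not named in the tree are untouched.  Internal nodes labelled
#' \code{"-"} (empty events) shape the computation but rewrite nothing.
#' An ASCII rendering of the parsed tree is printed to standard error as
#' a diagnostic.  Optional leaf weights in the NEWICK input are compared
#' against the computed leaf frequencies and a mismatch is warned about;
#' the computed values are authoritative.
#'
#' @param tree a \linkS4class{ClonalTree}.
#' @param variants an \linkS4class{SVVariantSet} whose vids include every
#'   non-placeholder tree label (a missing label is a hard error).
#' @param quiet suppress the ASCII tree diagnostic.
#' @return The rewritten \linkS4class{SVVariantSet}.
#' @export
tree2var <- function(tree, variants, quiet = FALSE) {
    stopifnot(is(tree, "ClonalTree"), is(variants, "SVVariantSet"))
    Fv <- variantFrequencies(tree)
    Fv <- Fv[names(Fv) != "-"]
    if (length(Fv) == 0L)
        stop("tree carries no non-placeholder variant labels")
    missing <- setdiff(names(Fv), variantIds(variants))
    if (length(missing))
        stop(sprintf("tree label(s) with no matching variant id: %s",
                     paste(missing, collapse = ", ")))
    if (!quiet)
        message(paste(asciiTree(tree), collapse = "\n"))
    .checkLeafWeights(tree)
    fractions(variants) <- Fv
    variants
}

## warn when informational NEWICK leaf weights disagree with computed F(C)
.checkLeafWeights <- function(tree, tol = 1e-6) {
    phy <- tree@phylo
    if (is.null(phy$edge.length))
        return(invisible())
    n <- length(phy$tip.label)
    tip_edges <- match(seq_len(n), phy$edge[, 2L])
    w <- phy$edge.length[tip_edges]
    if (all(!is.finite(w)))
        return(invisible())
    Fc <- leafFrequencies(tree)
    bad <- which(is.finite(w) & abs(w - Fc) > tol)
    if (length(bad))
        warning(sprintf(
            "leaf weight(s) disagree with computed frequencies (e.g. %s: %g vs %g); computed values are authoritative",
            phy$tip.label[bad[1L]], w[bad[1L]], Fc[bad[1L]]))
    invisible()
}

#' ASCII rendering of a clonal tree
#'
#' @param tree a \linkS4class{ClonalTree}.
#' @return Character vector, one line per rendered row.
#' @export
asciiTree <- function(tree) {
    stopifnot(is(tree, "ClonalTree"))
    phy <- tree@phylo
    n <- length(phy$tip.label)
    f <- tree@fractions
    render <- function(node, prefix, branch) {
        if (node <= n) {
            lab <- phy$tip.label[node]
            return(paste0(prefix, branch, lab))
        }
        j <- node - n
        head <- paste0(prefix, branch,
                       sprintf("%s:%g", names(f)[j], f[j]))
        kids <- .treeChildren(phy, node)
        child_prefix <- paste0(prefix,
                               if (branch == "") ""
                               else if (branch == "+-") "| "
                               else "  ")
        c(head,
          render(kids[1L], child_prefix, "+-"),
          render(kids[2L], child_prefix, "`-"))
    }
    render(n + 1L, "", "")
}

setMethod("show", "ClonalTree", function(object) {
    phy <- object@phylo
    cat(sprintf("ClonalTree: %d terminal genotypes, %d bifurcation events (%s child gains)\n",
                length(phy$tip.label), phy$Nnode, object@gaining))
    cat(paste(asciiTree(object), collapse = "\n"), "\n")
})
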