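# Independent oracles the implementation is checked against.

# Monte-Carlo population oracle: push n_cells through the bifurcation
# cascade with binomial splits and count carriers.  Shares no code with
# pathVectors()/leafFrequencies()/variantFrequencies().
mcPopulationOracle <- function(newick, n_cells = 1e6, gaining = "first") {
    phy <- ape::read.tree(text = paste0(sub(";*$", "", newick), ";"))
    ntip <- length(phy$tip.label)
    f <- numeric(phy$Nnode)
    for (j in seq_len(phy$Nnode)) {
        node <- ntip + j
        f[j] <- if (node == ntip + 1L) phy$root.edge
                else phy$edge.length[which(phy$edge[, 2] == node)]
    }
    leaf_counts <- setNames(numeric(ntip), phy$tip.label)
    var_counts <- setNames(numeric(phy$Nnode), phy$node.label)
    descend <- function(node, count) {
        if (node <= ntip) {
            leaf_counts[node] <<- count
            return(invisible())
        }
        j <- node - ntip
        kids <- phy$edge[phy$edge[, 1] == node, 2]
        gain <- rbinom(1L, count, f[j])
        var_counts[j] <<- gain
        if (gaining == "first") {
            descend(kids[1], gain); descend(kids[2], count - gain)
        } else {
            descend(kids[1], count - gain); descend(kids[2], gain)
        }
    }
    descend(ntip + 1L, n_cells)
    list(leaf = leaf_counts / n_cells, var = var_counts / n_cells,
         n = n_cells)
}

# Naive single-string edit oracle working on character vectors, one base
# per element; deliberately different machinery from the forge path.
COMP <- c(A = "T", C = "G", G = "C", T = "A")

naiveEdit <- function(seq, svtype, pos, del_len, ins_seq = "") {
    v <- strsplit(seq, "")[[1]]
    seg <- if (del_len > 0) v[pos:(pos + del_len - 1)] else character()
    out <- switch(svtype,
        DEL = v[-(pos:(pos + del_len - 1))],
        INS = append(v, strsplit(ins_seq, "")[[1]], after = pos - 1),
        DUP = append(v, seg, after = pos + del_len - 1),
        IDUP = append(v, rev(unname(COMP[seg])), after = pos + del_len - 1),
        INV = { v[pos:(pos + del_len - 1)] <- rev(unname(COMP[seg])); v },
        stop("unknown type"))
    paste(out, collapse = "")
}
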