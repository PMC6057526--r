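#' @include AllClasses.R AllGenerics.R
#' @importFrom stats rbinom rnorm rpois runif setNames
#' @importFrom utils read.table write.table head tail
NULL

## --- ploidy codes -----------------------------------------------------------

## "P/h1,h2,..." with shorthands "hom" (all haplotypes) and "het"
## (haplotype 1).  Shorthands resolve against `default_p`.
## Returns list(P=, haps=) or NULL on a malformed code.
.parsePloidy <- function(code, default_p = 2L) {
    code <- trimws(code)
    if (code == "hom")
        return(list(P = as.integer(default_p), haps = seq_len(default_p)))
    if (code == "het")
        return(list(P = as.integer(default_p), haps = 1L))
    if (!grepl("^[0-9]+/[0-9]+(,[0-9]+)*$", code))
        return(NULL)
    parts <- strsplit(code, "/", fixed = TRUE)[[1L]]
    p <- as.integer(parts[1L])
    haps <- as.integer(strsplit(parts[2L], ",", fixed = TRUE)[[1L]])
    if (p < 1L || anyDuplicated(haps) || any(haps < 1L) || any(haps > p))
        return(NULL)
    list(P = p, haps = sort(haps))
}

.formatPloidy <- function(p, haps) {
    sprintf("%d/%s", p, paste(sort(haps), collapse = ","))
}

## --- distribution tokens ----------------------------------------------------

## "family:params".  Families: fixed:v | uniform:a,b | normal:mu,sd |
## bernoulli:p | hom | het.  Returns list(family=, params=numeric).
.parseDist <- function(token) {
    token <- trimws(token)
    if (token %in% c("hom", "het"))
        return(list(family = token, params = numeric()))
    if (!grepl(":", token, fixed = TRUE))
        stop(sprintf("malformed distribution token '%s'", token))
    parts <- strsplit(token, ":", fixed = TRUE)[[1L]]
    family <- parts[1L]
    params <- suppressWarnings(
        as.numeric(strsplit(parts[2L], ",", fixed = TRUE)[[1L]]))
    if (anyNA(params))
        stop(sprintf("non-numeric parameters in '%s'", token))
    need <- c(fixed = 1L, uniform = 2L, normal = 2L, bernoulli = 1L)
    if (!family %in% names(need))
        stop(sprintf("unknown distribution family '%s'", family))
    if (length(params) != need[[family]])
        stop(sprintf("family '%s' needs %d parameter(s)", family,
                     need[[family]]))
    if (family == "uniform" && params[2L] < params[1L])
        stop(sprintf("uniform bounds out of order in '%s'", token))
    if (family == "normal" && params[2L] < 0)
        stop(sprintf("negative sd in '%s'", token))
    if (family == "bernoulli" && (params[1L] < 0 || params[1L] > 1))
        stop(sprintf("bernoulli p outside [0,1] in '%s'", token))
    list(family = family, params = params)
}

## One draw from a parsed size/fraction distribution.
.drawDist <- function(dist, n = 1L) {
    switch(dist$family,
        fixed = rep(dist$params[1L], n),
        uniform = runif(n, dist$params[1L], dist$params[2L]),
        normal = rnorm(n, dist$params[1L], dist$params[2L]),
        bernoulli = rbinom(n, 1L, dist$params[1L]),
        stop(sprintf("cannot draw from family '%s'", dist$family)))
}

## --- seeds ------------------------------------------------------------------

## Deterministic per-task seed from (master seed, task ordinal), fixed at
## planning time so products are independent of worker scheduling.
## Kept below 2^31 - 1 for R's 32-bit integer seeds.
.taskSeed <- function(master_seed, ordinal) {
    s <- (as.double(master_seed) %% 2147483647) + 1
    o <- as.double(ordinal)
    as.integer((s * 48271 + o * 16807 + (s * o) %% 65537) %% 2147483629) + 1L
}

## --- sequences --------------------------------------------------------------

#' Random template sequence
#'
#' Uniform-composition DNA useful as a synthetic simulation template.
#'
#' @param n sequence length in bp.
#' @param chars alphabet to draw from.
#' @return A character scalar of length-\code{n} DNA.
#' @export
randomDna <- function(n, chars = c("A", "C", "G", "T")) {
    paste(sample(chars, n, replace = TRUE), collapse = "")
}

## Reverse complement of a plain character string, IUPAC-aware and
## case-preserving (soft-masked template case survives the flip).
.revcompChar <- function(x) {
    if (!nzchar(x))
        return(x)
    from <- "ACGTUMRWSYKVHDBNacgtumrwsykvhdbn"
    to   <- "TGCAAKYWSRMBDHVNtgcaakywsrmbdhvn"
    bad <- gsub(sprintf("[%s]", from), "", x)
    if (nzchar(bad))
        stop(sprintf("non-IUPAC character '%s' in sequence",
                     substr(bad, 1L, 1L)))
    paste(rev(strsplit(chartr(from, to, x), "")[[1L]]), collapse = "")
}

## --- tab-delimited control files --------------------------------------------

## Shared reader for the '#'-headed VAR/META/PAR dialects.  Returns a
## character matrix plus original line numbers for diagnostics.
.readControlFile <- function(path, n_min, n_max, what) {
    if (!file.exists(path))
        stop(sprintf("%s file '%s' not found", what, path))
    lines <- readLines(path)
    keep <- !grepl("^#", lines) & nzchar(trimws(lines))
    lineno <- which(keep)
    lines <- lines[keep]
    if (length(lines) == 0L)
        return(list(fields = list(), lineno = integer()))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf < n_min | nf > n_max)
    if (length(bad))
        stop(sprintf("%s parse error at line %d: expected %d-%d fields, got %d",
                     what, lineno[bad[1L]], n_min, n_max, nf[bad[1L]]))
    list(fields = lapply(fields, trimws), lineno = lineno)
}

.dotToEmpty <- function(x) ifelse(x == ".", "", x)
.emptyToDot <- function(x) ifelse(nzchar(x), x, ".")

## numeric field with a line-addressed diagnostic
.numField <- function(x, lineno, what, name) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v))
        stop(sprintf("%s parse error at line %d: %s '%s' is not numeric",
                     what, lineno[which(is.na(v))[1L]], name,
                     x[which(is.na(v))[1L]]))
    v
}
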