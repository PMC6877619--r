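#' Binomial downsampling of raw contact counts
#'
#' Replaces each raw count by a binomial draw with that count and retention
#' probability \code{p}. With \code{p = 0.5} this halves the expected read
#' number, emulating single-copy coverage on a two-copy chromosome.
#'
#' @param m a raw-counts \code{\link{ContactMatrix}}.
#' @param p retention probability in (0, 1].
#' @param seed integer seed; the same seed reproduces identical output.
#' @return A raw-counts \code{\link{ContactMatrix}}.
#' @export
downsampleBinomial <- function(m, p = 0.5, seed = 1L) {
    stopifnot(contactKind(m) == "raw")
    if (p <= 0 || p > 1) stop("p must lie in (0, 1]")
    e <- contactEntries(m)
    if (p < 1 && nrow(e)) {
        set.seed(seed)
        e$value <- rbinom(nrow(e), size = as.integer(e$value), prob = p)
    }
    contactMatrix(contactGenome(m), e$bin1, e$bin2, e$value, kind = "raw")
}

#' Downsample cis counts of one sample to match another, per chromosome
#'
#' For each chromosome, cis entries of \code{target} are binomially thinned
#' with p = (reference cis total) / (target cis total); chromosomes where the
#' ratio is >= 1 are left unchanged. This makes the observed cis read
#' counts comparable between samples chromosome by chromosome.
#'
#' @param target a raw-counts \code{\link{ContactMatrix}} to thin.
#' @param reference a raw-counts \code{\link{ContactMatrix}} whose cis totals
#'   set the per-chromosome targets; must cover the same chromosome names.
#' @param seed integer seed.
#' @return A raw-counts \code{\link{ContactMatrix}}.
#' @export
downsampleMatchedCis <- function(target, reference, seed = 1L) {
    stopifnot(contactKind(target) == "raw", contactKind(reference) == "raw")
    g <- contactGenome(target)
    miss <- setdiff(chromNames(g), chromNames(contactGenome(reference)))
    if (length(miss))
        stop("chromosome missing from reference: ", paste(miss, collapse = ", "))
    tTot <- cisTotals(target)
    rTot <- cisTotals(reference)[chromNames(g)]
    chrom <- binChrom(g)
    e <- contactEntries(target)
    cis <- chrom[e$bin1 + 1L] == chrom[e$bin2 + 1L]
    ch <- chrom[e$bin1 + 1L]
    set.seed(seed)
    for (cn in chromNames(g)) {
        if (tTot[[cn]] == 0) next
        ratio <- rTot[[cn]] / tTot[[cn]]
        if (ratio >= 1) next
        sel <- cis & ch == cn
        e$value[sel] <- rbinom(sum(sel), size = as.integer(e$value[sel]),
                               prob = ratio)
    }
    contactMatrix(g, e$bin1, e$bin2, e$value, kind = "raw")
}
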