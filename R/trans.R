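#' Tabulate trans contacts and cis totals
#'
#' Sums raw read counts by chromosome pair. A trans read pair is counted
#' once for each of the two chromosomes it involves, so the observed table
#' is symmetric; the trans total T of a chromosome is the sum of its row.
#'
#' @param m a raw-counts \code{\link{ContactMatrix}}.
#' @return list with \code{observed} (symmetric chromosome x chromosome
#'   matrix, NA diagonal), \code{cis} (named per-chromosome cis totals) and
#'   \code{genome}.
#' @export
transTable <- function(m) {
    g <- contactGenome(m)
    cn <- chromNames(g)
    chrom <- binChrom(g)
    e <- contactEntries(m)
    c1 <- factor(chrom[e$bin1 + 1L], levels = cn)
    c2 <- factor(chrom[e$bin2 + 1L], levels = cn)
    tab <- matrix(0, length(cn), length(cn), dimnames = list(cn, cn))
    agg <- tapply(e$value, list(c1, c2), sum, default = 0)
    tab[rownames(agg), colnames(agg)] <- agg
    tab <- tab + t(tab)          # symmetrize; cis ends up doubled
    cis <- diag(tab) / 2
    diag(tab) <- NA
    list(observed = tab, cis = setNames(cis, cn), genome = g)
}

#' Trans/cis read-count ratio per chromosome
#'
#' @param t a table from \code{\link{transTable}}.
#' @return Named numeric vector: (total trans involving the chromosome) /
#'   (its cis total).
#' @export
transCisRatio <- function(t) {
    if (any(t$cis <= 0))
        stop("zero cis total on ",
             paste(names(t$cis)[t$cis <= 0], collapse = ", "))
    rowSums(t$observed, na.rm = TRUE) / t$cis
}

#' Expected trans contacts under a uniform null
#'
#' Trans contacts originating from any chromosome are assumed uniformly
#' distributed over the other (target) chromosomes in proportion to copy
#' number times length:
#' E(a, b) = (c_b * l_b) / sum_{b' != a} (c_b' * l_b') * T_a,
#' where T_a is the total trans count originating from chromosome a. Row
#' sums of the expectation therefore equal the observed row totals exactly.
#'
#' @param t a table from \code{\link{transTable}} (or a compatible list with
#'   an \code{observed} matrix).
#' @param g a \code{\link{GenomeModel}} providing lengths and copy numbers.
#' @return origin x target matrix of expected counts (NA diagonal).
#' @export
expectedTrans <- function(t, g) {
    cn <- rownames(t$observed)
    if (length(cn) < 2) stop("need at least 2 chromosomes")
    w <- copyNumbers(g)[cn] * chromLengths(g)[cn]
    Ta <- rowSums(t$observed, na.rm = TRUE)
    E <- matrix(NA_real_, length(cn), length(cn), dimnames = list(cn, cn))
    for (a in cn) {
        others <- setdiff(cn, a)
        E[a, others] <- w[others] / sum(w[others]) * Ta[[a]]
    }
    E
}

#' Trans-contact propensity (log2 observed / expected)
#'
#' @param t a table from \code{\link{transTable}}.
#' @param g a \code{\link{GenomeModel}}.
#' @return list with \code{log2ratio} (origin x target, not symmetric in
#'   general), \code{observed}, \code{expected}, and \code{zeroObserved}
#'   flagging cells reported as -Inf.
#' @export
transPropensity <- function(t, g) {
    E <- expectedTrans(t, g)
    off <- !is.na(E)
    if (any(E[off] <= 0)) stop("expected count is zero for some cell")
    lr <- log2(t$observed / E)
    zero <- !is.na(t$observed) & t$observed == 0
    list(log2ratio = lr, observed = t$observed, expected = E,
         zeroObserved = zero)
}
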