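# The cumulative-binomial replication fidelity model: per-domain fidelity,
# inversion to a per-nucleotide fidelity, and endpoint-yield arithmetic for
# defective-set experiments.

#' Per-information-domain replication fidelity
#'
#' The probability that an N-nt information domain is replicated with fewer
#' than K per-nucleotide errors, given per-nucleotide fidelity p:
#' \deqn{p_K(N) = \sum_{k=0}^{K-1} \binom{N}{k} p^{N-k} (1-p)^k}
#'
#' @param model a [FidelityModel-class], or the per-nucleotide fidelity p as
#'   a plain number (then `N`, `K` apply).
#' @param N information-domain length, nt.
#' @param K tolerated mutation count.
#' @return Domain fidelity in \[0, 1\].
#' @examples
#' domainFidelity(0.85, N = 15, K = 3)
#' @export
domainFidelity <- function(model, N = 15, K = 3) {
  if (is(model, "FidelityModel")) {
    p <- model@p; N <- model@N; K <- model@K
  } else {
    p <- model
  }
  # K = N + 1 sums over all outcomes (vacuously 1); kept for sanity checks
  stopifnot(K >= 1, K <= N + 1, all(p >= 0 & p <= 1))
  stats::pbinom(K - 1, N, 1 - p)
}

#' Invert the domain fidelity to a per-nucleotide fidelity
#'
#' Solves domainFidelity(p; N, K) = target for p. The domain fidelity is
#' strictly increasing in p on (0, 1), so the root is unique; it is found
#' by bracketed root finding.
#'
#' @param N information-domain length, nt.
#' @param K tolerated mutation count.
#' @param target per-domain fidelity to match, in (0, 1).
#' @param tol root tolerance (default 1e-9, well below the 1e-6 contract).
#' @return Per-nucleotide fidelity p.
#' @examples
#' invertPerNtFidelity(15, 3, 0.62)   # ~0.85
#' invertPerNtFidelity(13, 2, 0.62)   # ~0.90
#' @export
invertPerNtFidelity <- function(N, K, target, tol = 1e-9) {
  stopifnot(K >= 1, K <= N)
  if (target <= 0 || target >= 1)
    stop("target domain fidelity must be in (0, 1)")
  lo <- 1e-12; hi <- 1 - 1e-12
  flo <- domainFidelity(lo, N, K); fhi <- domainFidelity(hi, N, K)
  if (target < flo || target > fhi)
    stop(sprintf("target %.3g outside achievable range [%.3g, %.3g]",
                 target, flo, fhi))
  stats::uniroot(function(p) domainFidelity(p, N, K) - target,
                 c(lo, hi), tol = tol)$root
}

#' Endpoint-yield replication fidelity
#'
#' Per-information-domain fidelity from the endpoint product concentrations
#' of a defective reaction (forced mutation) and the full reaction:
#' 1 - c_defect / c_full.
#'
#' @param cDefect endpoint concentration of the defective reaction, nM.
#' @param cFull endpoint concentration of the full reaction, nM.
#' @return Fidelity in \[0, 1\].
#' @examples
#' endpointDomainFidelity(14, 37)   # 0.62
#' @export
endpointDomainFidelity <- function(cDefect, cFull) {
  if (cFull <= 0) stop("cFull must be positive")
  if (cDefect < 0 || cDefect > cFull)
    stop("need 0 <= cDefect <= cFull")
  1 - cDefect / cFull
}

#' Expected relative yield under multiple independent defects
#'
#' Under the independence assumption, n defects each reducing the relative
#' yield to `singleDefectRelativeYield` combine multiplicatively.
#'
#' @param singleDefectRelativeYield relative yield of a single-defect
#'   reaction, in \[0, 1\].
#' @param nDefects number of defects (>= 1).
#' @return Relative yield in \[0, 1\].
#' @examples
#' multiDefectYield(0.4, 2)   # 0.16
#' @export
multiDefectYield <- function(singleDefectRelativeYield, nDefects) {
  stopifnot(singleDefectRelativeYield >= 0, singleDefectRelativeYield <= 1,
            nDefects >= 1)
  singleDefectRelativeYield^nDefects
}
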