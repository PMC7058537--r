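# Contact-matrix normalization, TAD signal, insulation profiles and
# boundary calling.

#' Apply Knight-Ruiz normalization scores to a raw contact matrix
#'
#' Divides each contact by the product of the two bins' KR scores,
#' \code{out[i,j] = raw[i,j] / (kr[i] * kr[j])}. Bins with a missing score
#' are masked in the output; non-positive scores are treated as missing
#' with a warning.
#'
#' @param raw A \linkS4class{ContactMatrix} of raw counts.
#' @param kr Numeric vector of per-bin KR scores (NA = missing), length
#'   \code{nBins(raw)}.
#' @return A normalized \linkS4class{ContactMatrix}.
#' @examples
#' m <- matrix(8, 3, 3)
#' out <- applyKR(ContactMatrix("chr1", 25000, m), kr = c(2, 2, 2))
#' contactValues(out)[1, 2]  # 2
#' @export
applyKR <- function(raw, kr) {
  stopifnot(is(raw, "ContactMatrix"))
  if (length(kr) != nBins(raw)) {
    stop("KR vector length (", length(kr), ") does not match n_bins (",
         nBins(raw), ")", call. = FALSE)
  }
  kr <- as.numeric(kr)
  nonpos <- !is.na(kr) & kr <= 0
  if (any(nonpos)) {
    warning(sum(nonpos), " non-positive KR score(s); bin(s) masked")
    kr[nonpos] <- NA_real_
  }
  mask <- binMask(raw) | is.na(kr)
  v <- contactValues(raw) / outer(kr, kr)
  v[mask, ] <- NA_real_
  v[, mask] <- NA_real_
  ContactMatrix(chromName(raw), binSize(raw), v, mask = mask)
}

#' Iterative-correction (ICE) balancing of a contact matrix
#'
#' Alternating row/column correction until the unmasked row sums agree to
#' within `tol` (coefficient of variation). Bins with an all-zero row are
#' auto-masked before balancing. Returns the balanced matrix together with
#' the bias vector \code{b} such that \code{out[i,j] = raw[i,j]/(b[i]*b[j])}.
#'
#' @param raw A \linkS4class{ContactMatrix}.
#' @param maxIter Maximum iterations.
#' @param tol Convergence tolerance on the row-sum coefficient of variation.
#' @return A list with elements `matrix` (balanced
#'   \linkS4class{ContactMatrix}), `bias` (numeric, NA at masked bins) and
#'   `converged` (logical).
#' @examples
#' m <- matrix(c(4, 2, 2, 2, 1, 1, 2, 1, 1), 3, 3)
#' res <- iceNormalize(ContactMatrix("chr1", 25000, m))
#' res$converged
#' @export
iceNormalize <- function(raw, maxIter = 200L, tol = 1e-5) {
  stopifnot(is(raw, "ContactMatrix"))
  v0 <- contactValues(raw)
  if (all(is.na(v0) | v0 == 0)) {
    stop("cannot balance an all-zero matrix", call. = FALSE)
  }
  mask <- binMask(raw)
  ok <- which(!mask)
  if (length(ok) < 2L) {
    stop("need at least 2 unmasked bins to balance", call. = FALSE)
  }
  w <- v0[ok, ok, drop = FALSE]
  w[is.na(w)] <- 0
  bias <- rep(1, length(ok))
  converged <- FALSE
  for (iter in seq_len(maxIter)) {
    s <- rowSums(w)
    cv <- sd(s) / mean(s)
    if (is.na(cv)) break
    if (cv <= tol) {
      converged <- TRUE
      break
    }
    s <- s / mean(s)
    bias <- bias * s
    w <- w / outer(s, s)
  }
  if (!converged) warning("ICE did not converge in ", maxIter, " iterations")
  biasFull <- rep(NA_real_, nBins(raw))
  biasFull[ok] <- bias
  out <- v0 / outer(biasFull, biasFull)
  out[mask, ] <- NA_real_
  out[, mask] <- NA_real_
  list(matrix = ContactMatrix(chromName(raw), binSize(raw), out, mask = mask),
       bias = biasFull, converged = converged)
}

#' Per-bin TAD signal along the matrix diagonal
#'
#' For each bin i, sums contacts to unmasked partners within `window` bp
#' (excluding the diagonal), then reports the log2 ratio of that sum to the
#' mean sum over bins within `window` of i. The track is truncated at
#' chromosome ends (sums use whatever part of the band exists); masked bins
#' and bins whose local mean is zero are NA.
#'
#' @param mat A \linkS4class{ContactMatrix}.
#' @param window Flank width in bp (default 2 Mb); multiple of the bin size.
#' @return Numeric per-bin vector.
#' @export
tadSignal <- function(mat, window = 2e6) {
  stopifnot(is(mat, "ContactMatrix"))
  bs <- binSize(mat)
  if (window %% bs != 0) {
    stop("'window' must be a multiple of the bin size", call. = FALSE)
  }
  w <- as.integer(window / bs)
  n <- nBins(mat)
  v <- contactValues(mat)
  v0 <- v
  v0[is.na(v0)] <- 0
  S <- numeric(n)
  for (i in seq_len(n)) {
    jj <- max(1L, i - w):min(n, i + w)
    S[i] <- sum(v0[i, jj]) - v0[i, i]
  }
  S[binMask(mat)] <- NA_real_
  sig <- numeric(n)
  for (i in seq_len(n)) {
    jj <- max(1L, i - w):min(n, i + w)
    m <- mean(S[jj], na.rm = TRUE)
    sig[i] <- if (is.na(S[i]) || is.na(m) || m <= 0) NA_real_
    else log2(S[i] / m)
  }
  sig
}

#' Insulation profile of a contact matrix
#'
#' Raw insulation I(i) is the mean contact over the square window
#' \code{(i-s..i-1) x (i+1..i+s)} with \code{s = insulationSquare/binSize}
#' (40 bins for 1 Mb at 25 kb), using unmasked entries only; a square with
#' fewer than 25% unmasked entries is NA, as are bins within `s` of either
#' chromosome end. The score is \code{log2(I / mean(I))}, normalized per
#' chromosome. The delta track is the mean score over the `d` bins
#' downstream minus the mean over the `d` bins upstream, with
#' \code{d = deltaSpan/binSize} (8 bins for 200 kb).
#'
#' @param mat A \linkS4class{ContactMatrix}.
#' @param cfg A \code{\link{pipelineConfig}}.
#' @return An \linkS4class{InsulationProfile}.
#' @export
insulationProfile <- function(mat, cfg = pipelineConfig()) {
  stopifnot(is(mat, "ContactMatrix"))
  bs <- binSize(mat)
  s <- as.integer(cfg$insulationSquare / bs)
  d <- as.integer(cfg$deltaSpan / bs)
  n <- nBins(mat)
  mkProfile <- function(score, delta) {
    new("InsulationProfile", chrom = chromName(mat), binSize = bs,
        score = score, delta = delta, squareBins = s, deltaBins = d)
  }
  if (n * bs < 2 * cfg$insulationSquare) {
    warning("chromosome shorter than twice the insulation square; ",
            "empty profile")
    return(mkProfile(rep(NA_real_, n), rep(NA_real_, n)))
  }
  v <- contactValues(mat)
  rawIns <- rep(NA_real_, n)
  for (i in (s + 1L):(n - s)) {
    block <- v[(i - s):(i - 1L), (i + 1L):(i + s), drop = FALSE]
    frac <- mean(!is.na(block))
    if (frac >= 0.25) rawIns[i] <- mean(block, na.rm = TRUE)
  }
  rawIns[binMask(mat)] <- NA_real_
  chromMean <- mean(rawIns, na.rm = TRUE)
  score <- if (is.na(chromMean) || chromMean <= 0) {
    rep(NA_real_, n)
  } else {
    suppressWarnings(log2(rawIns / chromMean))
  }
  score[!is.finite(score)] <- NA_real_
  delta <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    up <- score[max(1L, i - d):max(1L, i - 1L)]
    dn <- score[min(n, i + 1L):min(n, i + d)]
    if (i == 1L || i == n) next
    mu <- mean(up, na.rm = TRUE)
    md <- mean(dn, na.rm = TRUE)
    if (is.finite(mu) && is.finite(md)) delta[i] <- md - mu
  }
  mkProfile(score, delta)
}

#' Call TAD boundaries from an insulation profile
#'
#' Candidate boundaries sit where the delta track crosses zero from below
#' (insulation local minima). Each candidate's strength is the delta at the
#' nearest following local maximum minus the delta at the nearest preceding
#' local minimum; candidates weaker than the noise threshold are dropped,
#' and candidates within `boundaryMargin` bins of each other are merged
#' keeping the stronger (ties: lower coordinate). Each call is emitted as a
#' 3-bin (75-kb) interval centered on the minimum bin.
#'
#' @param prof An \linkS4class{InsulationProfile}.
#' @param cfg A \code{\link{pipelineConfig}}.
#' @param source Label recorded in the `source` metadata column.
#' @return GRanges of boundaries with `strength` and `source` metadata.
#' @export
callBoundaries <- function(prof, cfg = pipelineConfig(), source = "hic") {
  stopifnot(is(prof, "InsulationProfile"))
  delta <- insulationDelta(prof)
  score <- insulationScore(prof)
  n <- length(delta)
  bs <- binSize(prof)
  emptySet <- function() {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$strength <- numeric(0)
    S4Vectors::mcols(gr)$source <- character(0)
    gr
  }
  if (!n || all(is.na(delta))) return(emptySet())

  # upward zero crossings of delta over runs of defined values
  idx <- which(!is.na(delta))
  cand <- integer(0)
  strength <- numeric(0)
  for (k in seq_len(length(idx) - 1L)) {
    i <- idx[k]
    j <- idx[k + 1L]
    if (j != i + 1L) next
    if (delta[i] < 0 && delta[j] >= 0) {
      # boundary bin: the one with the lower insulation score
      b <- if (!is.na(score[i]) && !is.na(score[j]) &&
               score[i] <= score[j]) i else j
      # preceding local minimum of delta
      lo <- i
      while (lo - 1L >= 1L && !is.na(delta[lo - 1L]) &&
             delta[lo - 1L] <= delta[lo]) lo <- lo - 1L
      # following local maximum of delta
      hi <- j
      while (hi + 1L <= n && !is.na(delta[hi + 1L]) &&
             delta[hi + 1L] >= delta[hi]) hi <- hi + 1L
      cand <- c(cand, b)
      strength <- c(strength, delta[hi] - delta[lo])
    }
  }
  keep <- strength >= cfg$noiseThreshold
  cand <- cand[keep]
  strength <- strength[keep]
  if (!length(cand)) return(emptySet())

  # merge candidates within the margin, stronger (then leftmost) wins
  ord <- order(cand)
  cand <- cand[ord]
  strength <- strength[ord]
  repeat {
    gaps <- diff(cand)
    close <- which(gaps <= cfg$boundaryMargin)
    if (!length(close)) break
    k <- close[1L]
    drop <- if (strength[k] > strength[k + 1L]) k + 1L
    else if (strength[k] < strength[k + 1L]) k
    else k + 1L  # tie: keep the smaller coordinate
    cand <- cand[-drop]
    strength <- strength[-drop]
  }
  halfW <- as.integer(cfg$boundaryWidth / bs) %/% 2L
  startBin <- pmax(1L, cand - halfW)
  endBin <- pmin(n, cand + halfW)
  gr <- GenomicRanges::GRanges(
    chromName(prof),
    IRanges::IRanges((startBin - 1L) * bs + 1L, endBin * bs))
  S4Vectors::mcols(gr)$strength <- strength
  S4Vectors::mcols(gr)$source <- source
  gr
}

#' Call boundaries for one chromosome in a single step
#'
#' Convenience wrapper: insulation profile then boundary calling.
#' @param mat A \linkS4class{ContactMatrix}.
#' @param cfg A \code{\link{pipelineConfig}}.
#' @param source Source label for the calls.
#' @return GRanges of boundaries.
#' @export
callBoundariesFromMatrix <- function(mat, cfg = pipelineConfig(),
                                     source = "hic") {
  callBoundaries(insulationProfile(mat, cfg), cfg, source = source)
}
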