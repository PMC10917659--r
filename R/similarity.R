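#' @include flip-run.R
NULL

# run expr with a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# valid-region 2D correlation of X with kernel w (odd square)
.filter2_valid <- function(X, w) {
  k <- nrow(w)
  nr <- nrow(X) - k + 1L
  nc <- ncol(X) - k + 1L
  out <- matrix(0, nr, nc)
  for (i in seq_len(k))
    for (j in seq_len(k))
      out <- out + w[i, j] * X[i:(i + nr - 1L), j:(j + nc - 1L)]
  out
}

.gaussian_kernel <- function(k, sigma) {
  half <- (k - 1) / 2
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

.ssim <- function(A, B, dataRange = 1, winSize = 11L, sigma = 1.5,
                  K1 = 0.01, K2 = 0.03) {
  k <- min(winSize, nrow(A), ncol(A))
  if (k %% 2L == 0L) k <- k - 1L
  if (k < 3L) stop("maps are too small for the SSIM window")
  w <- .gaussian_kernel(k, sigma)
  C1 <- (K1 * dataRange)^2
  C2 <- (K2 * dataRange)^2
  mu1 <- .filter2_valid(A, w)
  mu2 <- .filter2_valid(B, w)
  s1 <- .filter2_valid(A * A, w) - mu1^2
  s2 <- .filter2_valid(B * B, w) - mu2^2
  s12 <- .filter2_valid(A * B, w) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s1 + s2 + C2)
  min(max(mean(num / den), 0), 1)
}

#' Image similarity (IS) of two relative power maps
#'
#' Structural similarity index (SSIM) between two maps of identical
#' dimensions treated as images, with the dynamic range pinned to 1
#' (relative power maps are normalized to [0, 1]). Uses the standard
#' constants K1 = 0.01, K2 = 0.03 and an 11x11 Gaussian weighting window
#' (sigma = 1.5) over the valid image region. Returns a single scalar in
#' [0, 1]: 1 for identical maps, near 0 for completely dissimilar ones.
#'
#' @param mapA,mapB \code{\linkS4class{RelativePowerMap}}s (or plain
#'   matrices in [0, 1]) of identical dimensions; standardize the depth
#'   axis and match the frequency bins first.
#' @return IS value in [0, 1].
#' @examples
#' m <- matrix(runif(24 * 150), 24, 150)
#' imageSimilarity(m, m)  # 1
#' @export
imageSimilarity <- function(mapA, mapB) {
  A <- if (is(mapA, "RelativePowerMap")) mapA@relPower else as.matrix(mapA)
  B <- if (is(mapB, "RelativePowerMap")) mapB@relPower else as.matrix(mapB)
  if (!all(dim(A) == dim(B)))
    stop("maps have different dimensions (", paste(dim(A), collapse = "x"),
         " vs ", paste(dim(B), collapse = "x"),
         "); standardize depth and match frequency bins first")
  .ssim(A, B)
}

# shift map rows so its crossover lands on `ref`; rows shifted out are
# truncated, vacated rows become NA (no wraparound)
.align_rows <- function(vals, crossover, ref) {
  n <- nrow(vals)
  out <- matrix(NA_real_, n, ncol(vals))
  shift <- ref - crossover
  src <- seq_len(n)
  dst <- src + shift
  ok <- dst >= 1L & dst <= n
  out[dst[ok], ] <- vals[src[ok], ]
  out
}

.na_mean <- function(mats) {
  acc <- matrix(0, nrow(mats[[1L]]), ncol(mats[[1L]]))
  cnt <- acc
  for (m in mats) {
    ok <- !is.na(m)
    acc[ok] <- acc[ok] + m[ok]
    cnt <- cnt + ok
  }
  acc / ifelse(cnt > 0, cnt, NA)
}

#' Within- versus between-group image similarity of power map populations
#'
#' Implements the grouped IS procedure: per repetition, the probes of each
#' group are randomly split into two equally sized halves (odd groups drop
#' one random probe), each half's maps are averaged, and IS is computed
#' between the two half-averages within each group (one within-IS per
#' group) and between the four cross-group pairings of half-averages (four
#' between-IS). With the default 5 repetitions this yields 5 within values
#' per group and 20 between values; their means are the grand within- and
#' between-area IS.
#'
#' Maps are aligned by their alpha-beta/gamma crossover channel (row
#' shifting with edge truncation) before averaging; probes whose crossover
#' cannot be identified by FLIP are dropped with a warning. Comparisons are
#' restricted to the depth rows defined in all four half-averages of a
#' repetition.
#'
#' @param groupA,groupB lists of \code{\linkS4class{RelativePowerMap}}s
#'   with identical dimensions (>= 4 identifiable probes each).
#' @param nReps number of random halving repetitions (default 5).
#' @param seed RNG seed for the partitions.
#' @param align \code{"crossover"} (default) or \code{"none"}.
#' @param crossoverMethod \code{"flip"} (default) or \code{"vflip"}; use
#'   vFLIP when the populations' gradients may lie outside the fixed FLIP
#'   bands.
#' @param cfg \code{\link{analysisConfig}} used for the crossovers.
#' @return a \code{\linkS4class{SimilarityResult}}.
#' @export
groupIS <- function(groupA, groupB, nReps = 5L, seed = NULL,
                    align = c("crossover", "none"),
                    crossoverMethod = c("flip", "vflip"),
                    cfg = analysisConfig()) {
  align <- match.arg(align)
  crossoverMethod <- match.arg(crossoverMethod)
  prep <- function(group, label) {
    vals <- lapply(group, function(m) {
      stopifnot(is(m, "RelativePowerMap"))
      m@relPower
    })
    if (align == "crossover") {
      cross <- vapply(group, function(m) {
        fr <- if (crossoverMethod == "flip") flip(m, cfg) else vflip(m, cfg)
        if (fr@identifiable) fr@crossoverChannel else NA_integer_
      }, integer(1))
      drop <- is.na(cross)
      if (any(drop)) {
        warning(sum(drop), " probe(s) in group ", label,
                " had no identifiable crossover and were dropped")
        vals <- vals[!drop]; cross <- cross[!drop]
      }
      list(vals = vals, cross = cross)
    } else list(vals = vals, cross = rep(NA_integer_, length(vals)))
  }
  pa <- prep(groupA, "A")
  pb <- prep(groupB, "B")
  if (length(pa$vals) < 4L || length(pb$vals) < 4L)
    stop("each group needs at least 4 usable probes to halve")
  if (align == "crossover") {
    ref <- as.integer(round(stats::median(c(pa$cross, pb$cross))))
    pa$vals <- Map(.align_rows, pa$vals, pa$cross, ref)
    pb$vals <- Map(.align_rows, pb$vals, pb$cross, ref)
  }
  .with_seed(seed, {
    withinA <- withinB <- numeric(nReps)
    between <- numeric(0)
    for (r in seq_len(nReps)) {
      halves <- function(vals) {
        n <- length(vals)
        idx <- sample(n)
        if (n %% 2L == 1L) idx <- idx[-1L]   # drop one probe at random
        h <- length(idx) %/% 2L
        list(.na_mean(vals[idx[seq_len(h)]]),
             .na_mean(vals[idx[(h + 1L):(2L * h)]]))
      }
      ha <- halves(pa$vals)
      hb <- halves(pb$vals)
      all4 <- c(ha, hb)
      rows <- Reduce(`&`, lapply(all4, function(m) !apply(is.na(m), 1L, any)))
      if (sum(rows) < 3L)
        stop("fewer than 3 complete depth rows remain after alignment")
      crop <- lapply(all4, function(m) m[rows, , drop = FALSE])
      withinA[r] <- .ssim(crop[[1L]], crop[[2L]])
      withinB[r] <- .ssim(crop[[3L]], crop[[4L]])
      between <- c(between,
                   .ssim(crop[[1L]], crop[[3L]]),
                   .ssim(crop[[1L]], crop[[4L]]),
                   .ssim(crop[[2L]], crop[[3L]]),
                   .ssim(crop[[2L]], crop[[4L]]))
    }
    new("SimilarityResult",
        grandWithinA = mean(withinA), grandWithinB = mean(withinB),
        grandBetween = mean(between),
        withinA = withinA, withinB = withinB, between = between,
        nRepetitions = as.integer(nReps))
  })
}

#' Channel-shuffle identifiability null
#'
#' Randomizes the laminar position of channels in each map
#' \code{nShuffles} times, reruns FLIP (or vFLIP) on every shuffle, and
#' returns the identifiable fraction across shuffles — the permutation
#' null that destroying laminar structure should destroy identifiability.
#'
#' @param maps list of \code{\linkS4class{RelativePowerMap}}s (or
#'   \code{\linkS4class{PowerMap}}s).
#' @param nShuffles shuffles per probe (default 100).
#' @param method \code{"flip"} or \code{"vflip"}.
#' @param seed RNG seed.
#' @param cfg an \code{\link{analysisConfig}}.
#' @return \code{list(fraction, perProbe, unshuffledFraction)}.
#' @export
shuffleIdentifiability <- function(maps, nShuffles = 100L,
                                   method = c("flip", "vflip"),
                                   seed = NULL, cfg = analysisConfig()) {
  method <- match.arg(method)
  run <- function(m) {
    r <- if (method == "flip") flip(m, cfg) else vflip(m, cfg)
    r@identifiable
  }
  shuffle_map <- function(m) {
    perm <- sample(nChannels(m))
    if (is(m, "RelativePowerMap"))
      relativePowerMap(m@relPower[perm, , drop = FALSE], m@freqs,
                       channelSpacing = m@channelSpacing)
    else
      powerMap(m@power[perm, , drop = FALSE], m@freqs,
               m@nTrialsAveraged, m@channelSpacing)
  }
  unshuffled <- mean(vapply(maps, run, logical(1)))
  .with_seed(seed, {
    perProbe <- vapply(maps, function(m)
      mean(vapply(seq_len(nShuffles),
                  function(i) run(shuffle_map(m)), logical(1))),
      numeric(1))
    list(fraction = mean(perProbe), perProbe = perProbe,
         unshuffledFraction = unshuffled)
  })
}
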