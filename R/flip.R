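#' @include spectral.R
NULL

.prof_values <- function(x) {
  if (is(x, "BandProfile")) x@values else as.numeric(x)
}

# closed-form OLS of y against 1..n restricted to channels a..b:
# slope sign, R^2 and two-sided slope t-test p-value.
.ols_range <- function(y, a, b) {
  idx <- a:b
  yy <- y[idx]
  n <- length(idx)
  x <- as.numeric(idx)
  sxx <- sum((x - mean(x))^2)
  syy <- sum((yy - mean(yy))^2)
  if (syy <= .Machine$double.eps * max(1, sum(yy^2)))
    return(list(sign = 0, r2 = 0, p = 1))
  sxy <- sum((x - mean(x)) * (yy - mean(yy)))
  r2 <- sxy^2 / (sxx * syy)
  r2 <- min(r2, 1)
  tt <- sqrt(r2) * sqrt((n - 2) / max(1 - r2, .Machine$double.eps))
  list(sign = sign(sxy), r2 = r2,
       p = 2 * stats::pt(-abs(tt), df = n - 2))
}

.f_reg <- function(Di, Df) 0.04 * (Df - Di) + 0.72

# Signed goodness of fit. The sign factor (s_ab - s_g)/2 is +1 for the
# upright motif (alpha-beta slope +, gamma slope - on a superficial->deep
# axis), -1 for the inverted motif, and 0 for parallel gradients, so the
# sign encodes insertion orientation and reversing the depth axis of both
# profiles flips the sign of G while preserving |G|.
.g_value <- function(sA, sG, r2A, r2G, f) {
  ((sA - sG) / 2) * r2A * r2G * f
}

.make_range_fit <- function(pA, pG, Di, Df) {
  fa <- .ols_range(pA, Di, Df)
  fg <- .ols_range(pG, Di, Df)
  f <- .f_reg(Di, Df)
  G <- .g_value(fa$sign, fg$sign, fa$r2, fg$r2, f)
  new("RangeFit", Di = as.integer(Di), Df = as.integer(Df),
      G = G, fReg = f,
      r2AlphaBeta = fa$r2, r2Gamma = fg$r2,
      slopeSignAlphaBeta = fa$sign, slopeSignGamma = fg$sign,
      pAlphaBeta = fa$p, pGamma = fg$p)
}

#' Goodness of fit of the spectrolaminar pattern over a fixed depth range
#'
#' Fits ordinary least-squares lines to the alpha-beta and gamma band
#' profiles over channels \code{Di..Df} and combines them into the signed
#' score G = ((s_ab - s_g)/2) * R2_ab * R2_g * f, where s are the slope
#' signs, R2 the coefficients of determination and f = 0.04*(Df - Di) +
#' 0.72 the span regularizer. The sign factor is +1 when the slopes oppose
#' in the upright sense (alpha-beta rising, gamma falling with depth), -1
#' for the inverted pattern and 0 for parallel slopes; thus a perfect
#' upright motif over a span of 7 channels gives G = +1 and G > 0
#' indicates a superficial-to-deep (upright) insertion. A profile with no
#' variance over the range yields a non-significant fit with G = 0.
#'
#' @param pAlphaBeta,pGamma \code{\linkS4class{BandProfile}}s or numeric
#'   depth profiles (superficial to deep).
#' @param Di,Df superficial and deep channel limits; \code{Df - Di} must be
#'   at least \code{minSpan}.
#' @param minSpan minimum allowed span (default 7 channels).
#' @return a \code{\linkS4class{RangeFit}}.
#' @examples
#' goodnessOfFit(seq(0, 1, length.out = 8), seq(1, 0, length.out = 8), 1, 8)
#' @export
goodnessOfFit <- function(pAlphaBeta, pGamma, Di, Df, minSpan = 7L) {
  pA <- .prof_values(pAlphaBeta); pG <- .prof_values(pGamma)
  stopifnot(length(pA) == length(pG))
  if (Df - Di < minSpan)
    stop("range span |Df - Di| = ", Df - Di, " is below the minimum of ",
         minSpan)
  if (Di < 1L || Df > length(pA))
    stop("range [", Di, ", ", Df, "] falls outside the profiles")
  .make_range_fit(pA, pG, Di, Df)
}

#' Exhaustive optimal depth-range search
#'
#' Iterates over all channel ranges \code{(Di, Df)} with
#' \code{Df - Di >= minSpan} and returns the \code{\linkS4class{RangeFit}}
#' maximizing |G| (the sign of G is preserved in the result). Ties are
#' broken toward the larger span, then toward the more superficial
#' \code{Di}.
#'
#' @inheritParams goodnessOfFit
#' @param minSpan minimum span of the search (default 7).
#' @return the winning \code{\linkS4class{RangeFit}}.
#' @export
findOptimalRange <- function(pAlphaBeta, pGamma, minSpan = 7L) {
  pA <- .prof_values(pAlphaBeta); pG <- .prof_values(pGamma)
  stopifnot(length(pA) == length(pG))
  n <- length(pA)
  if (n < minSpan + 1L)
    stop("profiles have ", n, " channels; the range search needs at least ",
         minSpan + 1L)
  best <- NULL
  for (Di in seq_len(n - minSpan)) {
    for (Df in seq.int(Di + minSpan, n)) {
      fit <- .make_range_fit(pA, pG, Di, Df)
      if (.better_fit(fit, best)) best <- fit
    }
  }
  best
}

# strictly-better comparison implementing |G| max with ties toward larger
# span, then more superficial Di
.better_fit <- function(fit, best) {
  if (is.null(best)) return(TRUE)
  ga <- abs(fit@G); gb <- abs(best@G)
  if (ga > gb + 1e-12) return(TRUE)
  if (ga < gb - 1e-12) return(FALSE)
  sa <- fit@Df - fit@Di; sb <- best@Df - best@Di
  if (sa != sb) return(sa > sb)
  fit@Di < best@Di
}

# For a fixed superficial limit Di: band-profile matrix P[c, j] = profile of
# channel Di+c-1 for the range (Di, Di+j-1) under within-range column
# renormalization. Computed for all deep limits at once: the running column
# maxima over rows Di..Df give per-range weights 1/max, and one matrix
# product assembles every profile.
.range_profiles_from <- function(vals, Di) {
  n <- nrow(vals)
  m <- n - Di + 1L
  sub <- vals[Di:n, , drop = FALSE]
  cm <- sub
  if (m > 1L)
    for (i in 2:m) cm[i, ] <- pmax(cm[i - 1L, ], sub[i, ])
  w <- ifelse(cm > 0, 1 / cm, 0)
  (sub %*% t(w)) / ncol(vals)
}

# Per-column prefix regression statistics: for profile matrix P (rows are
# in-range channels 1..m, columns deep limits), OLS of P[1:m, j] against
# 1..m for every (m, j) via triangular prefix sums.
.prefix_ols <- function(P) {
  m <- nrow(P)
  x <- seq_len(m)
  L <- lower.tri(matrix(0, m, m), diag = TRUE) * 1
  Sy <- L %*% P
  Sy2 <- L %*% (P * P)
  Sxy <- L %*% (x * P)
  nn <- x
  Sx <- cumsum(x)
  Sx2 <- cumsum(x^2)
  sxx <- Sx2 - Sx^2 / nn
  syy <- Sy2 - Sy^2 / nn
  sxy <- Sxy - (Sx / nn) * Sy
  list(sxx = sxx, syy = syy, sxy = sxy)
}

# range search with per-range map renormalization: at each candidate range
# the map columns (restricted to the range) are divided by their maximum
# within the range before band averaging, as the published procedure
# specifies. `lowVals`/`highVals` are the channels x bins submatrices of the
# two bands.
.search_map_ranges <- function(lowVals, highVals, minSpan) {
  n <- nrow(lowVals)
  if (n < minSpan + 1L)
    stop("map has ", n, " channels; the range search needs at least ",
         minSpan + 1L)
  eps <- .Machine$double.eps
  best <- NULL
  for (Di in seq_len(n - minSpan)) {
    PA <- .range_profiles_from(lowVals, Di)
    PG <- .range_profiles_from(highVals, Di)
    sa <- .prefix_ols(PA)
    sg <- .prefix_ols(PG)
    m <- nrow(PA)
    rows <- (minSpan + 1L):m           # range sizes with span >= minSpan
    for (k in rows) {
      Df <- Di + k - 1L
      sxx <- sa$sxx[k]
      syyA <- sa$syy[k, k]; sxyA <- sa$sxy[k, k]
      syyG <- sg$syy[k, k]; sxyG <- sg$sxy[k, k]
      tol <- 1e-13
      r2A <- if (syyA > tol) min(sxyA^2 / (sxx * syyA), 1) else 0
      r2G <- if (syyG > tol) min(sxyG^2 / (sxx * syyG), 1) else 0
      sA <- if (syyA > tol) sign(sxyA) else 0
      sG <- if (syyG > tol) sign(sxyG) else 0
      f <- .f_reg(Di, Df)
      G <- .g_value(sA, sG, r2A, r2G, f)
      if (!is.null(best)) {
        ga <- abs(G); gb <- abs(best@G)
        if (ga < gb - 1e-12) next
        if (ga <= gb + 1e-12) {
          spanNew <- Df - Di; spanBest <- best@Df - best@Di
          if (spanNew < spanBest ||
              (spanNew == spanBest && Di >= best@Di)) next
        }
      }
      pA <- if (sA == 0) 1 else {
        tt <- sqrt(r2A) * sqrt((k - 2) / max(1 - r2A, eps))
        2 * stats::pt(-abs(tt), df = k - 2)
      }
      pG <- if (sG == 0) 1 else {
        tt <- sqrt(r2G) * sqrt((k - 2) / max(1 - r2G, eps))
        2 * stats::pt(-abs(tt), df = k - 2)
      }
      best <- new("RangeFit", Di = as.integer(Di), Df = as.integer(Df),
                  G = G, fReg = f, r2AlphaBeta = r2A, r2Gamma = r2G,
                  slopeSignAlphaBeta = sA, slopeSignGamma = sG,
                  pAlphaBeta = pA, pGamma = pG)
    }
  }
  best
}

#' Select the alpha-beta/gamma crossover channel within a fitted range
#'
#' Candidate crossovers are the channels inside \code{[Di, Df]} where the
#' sign of \code{P_gamma - P_alphabeta} changes (an exact zero is its own
#' candidate; otherwise the endpoint of the sign-changing pair with the
#' smaller absolute difference, ties toward the superficial side). With
#' several candidates, the one maximizing the power difference
#' \code{deltaP = sum_superficial(P_g - P_ab) + sum_deep(P_ab - P_g)} is
#' chosen; the canonical upright motif (gamma dominant superficially,
#' alpha-beta dominant deep) yields positive deltaP. For inverted probes
#' pass \code{orientation = "inverted"}, which mirrors the dominance sides.
#'
#' @inheritParams goodnessOfFit
#' @param fit a \code{\linkS4class{RangeFit}} delimiting the search range.
#' @param orientation \code{"upright"} or \code{"inverted"}.
#' @return \code{list(channel, deltaP)}.
#' @export
selectCrossover <- function(pAlphaBeta, pGamma, fit,
                            orientation = "upright") {
  pA <- .prof_values(pAlphaBeta); pG <- .prof_values(pGamma)
  stopifnot(length(pA) == length(pG))
  Di <- fit@Di; Df <- fit@Df
  d <- pG - pA
  if (identical(orientation, "inverted")) d <- -d
  cand <- integer(0)
  for (c0 in seq.int(Di, Df - 1L)) {
    if (d[c0] == 0) { cand <- c(cand, c0); next }
    if (sign(d[c0]) != sign(d[c0 + 1L]) && d[c0 + 1L] != 0) {
      pick <- if (abs(d[c0]) <= abs(d[c0 + 1L])) c0 else c0 + 1L
      cand <- c(cand, pick)
    }
  }
  if (d[Df] == 0) cand <- c(cand, Df)
  cand <- unique(cand)
  if (!length(cand))
    stop("no alpha-beta/gamma crossover found within the selected range")
  dp <- vapply(cand, function(c0)
    sum(d[Di:c0]) + sum(-d[c0:Df]), numeric(1))
  best <- cand[order(-dp, cand)][1L]
  list(channel = best, deltaP = dp[match(best, cand)])
}

# collapse y into plateau runs and return candidate peak channels:
# runs strictly greater than every adjacent run; boundary runs count.
# Plateaus collapse to their centre channel (ties toward `towards`).
.peak_candidates <- function(y, towards) {
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  out <- integer(0); boundary <- logical(0)
  for (i in seq_len(k)) {
    left_ok <- i == 1L || r$values[i] > r$values[i - 1L]
    right_ok <- i == k || r$values[i] > r$values[i + 1L]
    if (left_ok && right_ok) {
      mid <- (starts[i] + ends[i]) / 2
      ch <- if (mid == floor(mid)) as.integer(mid)
            else if (towards >= mid) as.integer(ceiling(mid))
            else as.integer(floor(mid))
      out <- c(out, ch)
      boundary <- c(boundary, i == 1L || i == k)
    }
  }
  list(channels = out, boundary = boundary)
}

#' Select the gamma and alpha-beta peak channels
#'
#' Among the local maxima of the full-probe gamma profile, returns the one
#' nearest the superficial limit \code{Di} of the fitted range; among the
#' local maxima of the alpha-beta profile, the one nearest the deep limit
#' \code{Df} (either inside or outside the range). Plateaus collapse to
#' their centre channel and distance ties are broken toward the range
#' interior. A monotone profile has only a boundary maximum; that channel
#' is returned with its boundary flag set.
#'
#' @inheritParams selectCrossover
#' @return \code{list(gammaPeak, alphabetaPeak, gammaBoundary,
#'   alphabetaBoundary)}.
#' @export
selectPeaks <- function(pAlphaBeta, pGamma, fit) {
  pA <- .prof_values(pAlphaBeta); pG <- .prof_values(pGamma)
  Di <- fit@Di; Df <- fit@Df
  pick <- function(y, target, interior) {
    cand <- .peak_candidates(y, towards = target)
    ch <- cand$channels
    dist <- abs(ch - target)
    # ties toward the range interior
    tow <- if (interior > target) ch else -ch
    o <- order(dist, -tow)
    list(channel = ch[o[1L]], boundary = cand$boundary[o[1L]])
  }
  g <- pick(pG, Di, interior = Df)
  a <- pick(pA, Df, interior = Di)
  list(gammaPeak = g$channel, alphabetaPeak = a$channel,
       gammaBoundary = g$boundary, alphabetaBoundary = a$boundary)
}
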