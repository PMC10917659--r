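# Shared fixtures, built lazily and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]]))
    .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# a default synthetic probe and its derived maps
canonical_probe <- function(seed = 42L) {
  fixture(paste0("probe_", seed), function() {
    gp <- generateProbe(syntheticProbeSpec(seed = seed))
    pm <- computePowerMap(gp$recording)
    rel <- standardizeDepth(relativePower(pm), 24L)
    list(gp = gp, pm = pm, rel = rel)
  })
}

# a small default population with standardized relative maps
canonical_population <- function(n = 8L, seed = 21L, spec = NULL) {
  key <- paste0("pop_", n, "_", seed, "_", is.null(spec))
  fixture(key, function() {
    if (is.null(spec)) spec <- syntheticProbeSpec()
    pop <- generatePopulation(n, spec, seed = seed)
    maps <- lapply(pop, function(p)
      standardizeDepth(relativePower(computePowerMap(p$recording)), 24L))
    list(pop = pop, maps = maps)
  })
}

# perfect opposing linear profiles over nch channels
opposing_profiles <- function(nch = 24L) {
  list(alphabeta = seq(0.1, 1, length.out = nch),
       gamma = seq(1, 0.1, length.out = nch))
}

# independent reimplementation of the range scorer and exhaustive scan,
# built on stats::lm, used as the oracle for findOptimalRange
oracle_range_scan <- function(pA, pG, minSpan = 7L) {
  n <- length(pA)
  best <- NULL
  score <- function(Di, Df) {
    x <- Di:Df
    fa <- stats::lm(pA[x] ~ x)
    fg <- stats::lm(pG[x] ~ x)
    # flat windows trigger perfect-fit warnings from summary.lm
    sa <- suppressWarnings(summary(fa)); sg <- suppressWarnings(summary(fg))
    sA <- unname(sign(stats::coef(fa)[2L]))
    sG <- unname(sign(stats::coef(fg)[2L]))
    f <- 0.04 * (Df - Di) + 0.72
    list(G = ((sA - sG) / 2) * sa$r.squared * sg$r.squared * f,
         pA = stats::coef(sa)[2L, 4L], pG = stats::coef(sg)[2L, 4L])
  }
  for (Di in seq_len(n - minSpan)) {
    for (Df in seq.int(Di + minSpan, n)) {
      s <- score(Di, Df)
      cand <- list(Di = Di, Df = Df, G = s$G)
      if (is.null(best)) { best <- cand; next }
      ga <- abs(cand$G); gb <- abs(best$G)
      take <- if (ga > gb + 1e-12) TRUE
              else if (ga < gb - 1e-12) FALSE
              else {
                sp1 <- cand$Df - cand$Di; sp2 <- best$Df - best$Di
                if (sp1 != sp2) sp1 > sp2 else cand$Di < best$Di
              }
      if (take) best <- cand
    }
  }
  best
}
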