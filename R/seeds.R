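# Deterministic sub-seed derivation. One master seed drives the whole cohort;
# per-dog / per-frame seeds are derived by a fixed integer hash so that adding
# dogs or weeks never perturbs existing records.

#' Derive a reproducible sub-seed from a master seed
#'
#' Chains its integer (or string) arguments through a fixed multiplicative
#' hash modulo 2^31 - 1. Strings are folded to integers position-wise, so
#' `sub_seed(1, "dog3", 12)` is stable across platforms and R sessions.
#'
#' @param ... integers or character scalars to fold into the seed, the first
#'   usually being the master seed.
#' @return a single integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' sub_seed(1, "dog3", 12)
sub_seed <- function(...) {
  parts <- list(...)
  h <- 104729
  for (p in parts) {
    if (is.character(p)) {
      p <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) %% 2147483647
    }
    for (x in p) {
      h <- (h * 69069 + (as.numeric(x) %% 2147483647) + 1) %% 2147483647
    }
  }
  as.integer(h %% 2147483645 + 1)
}

# Evaluate `code` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Per-dog latent maturity structure, recomputable from the profile seed alone:
# a persistent dog factor `u` and an AR(1) exam-to-exam latent `z` defined on
# the canonical biweekly grid. Both feed the parenchymal grayscale intensity
# and (scaled) the log total sperm count, which is what couples echotexture to
# semen output in the generator.
exam_latents <- function(profile, weeks) {
  grid <- seq(4, max(40, max(weeks)), by = 2)
  u <- with_seed(sub_seed(profile$seed, 101), rnorm(1))
  eta <- vapply(seq_along(grid), function(i) {
    with_seed(sub_seed(profile$seed, 211, i), rnorm(1))
  }, numeric(1))
  phi <- 0.5
  z <- numeric(length(grid))
  z[1] <- eta[1]
  for (i in seq_along(grid)[-1]) {
    z[i] <- phi * z[i - 1] + sqrt(1 - phi^2) * eta[i]
  }
  idx <- match(weeks, grid)
  if (anyNA(idx)) {
    stop("exam weeks must lie on the biweekly grid starting at week 4")
  }
  list(u = u, z = z[idx])
}
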