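#' @importFrom methods new validObject is slot
#' @importFrom stats dist ks.test median p.adjust rbinom rnbinom rnorm rpois
#'   runif sd setNames wilcox.test cor
#' @importFrom utils read.delim write.table head
NULL

# Derive a reproducible per-stage seed (< 2^31) from a master seed and a
# stage name, so that adding cells to one generator stage does not perturb
# the draws of another.
stageSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 2166136261
  for (b in utf8ToInt(stage)) h <- ((h * 16777619) + b) %% 2147483629
  as.integer(((abs(seed) %% 1000003) * 2099 + h) %% 2147483629)
}

# Evaluate expr under a local RNG state; NULL seed leaves the global
# stream untouched (still consumed).
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- NULL
  } else {
    old <- get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# FNV-1a hash of a serialized R object, reported as hex; used for run
# metadata (config fingerprints), not for cryptography.
objectHash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(raw)) h <- ((h %% 2^24) * 16777619 + b) %% 4294967291
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Log-transform counts with a pseudo-count
#'
#' Applies \code{log(count + pseudocount)}, the transform used before
#' visualising and testing per-ROI cell counts.
#'
#' @param counts non-negative numeric vector.
#' @param pseudocount value added before taking the log (default 1).
#' @param base logarithm base (default natural log).
#' @return numeric vector of transformed values, with the base recorded in
#'   attribute \code{"base"}.
#' @examples
#' logTransformCounts(c(0, 10, 100))
#' @export
logTransformCounts <- function(counts, pseudocount = 1, base = exp(1)) {
  if (!is.numeric(counts)) stop("'counts' must be numeric")
  if (anyNA(counts)) stop("'counts' contains NA")
  if (any(counts < 0)) stop("negative counts are not allowed")
  out <- log(counts + pseudocount, base = base)
  attr(out, "base") <- base
  out
}
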