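# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Every generator in the package is a pure function of (arguments, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Dirichlet sampler via gamma normalization; rows on the probability simplex.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

site_ids <- function(sites) paste0(sites$chrom, ":", sites$pos)

#' Read-depth model specification
#'
#' Sequencing depth in targeted bisulfite capture is over-dispersed relative to
#' Poisson (coverage SD typically exceeds the mean), so the default depth model
#' is negative binomial with dispersion 0.3 (variance = mu + 0.3 * mu^2).
#' A `dispersion` of 0 gives constant depth equal to `mean`; generator
#' arguments also accept a bare number as shorthand for constant depth.
#'
#' @param mean Mean read depth per CpG (reads).
#' @param dispersion Negative-binomial dispersion; 0 for constant depth.
#' @return A `depth_spec` object.
#' @export
depth_spec <- function(mean = 100, dispersion = 0.3) {
  stopifnot(is.numeric(mean), mean > 0, is.numeric(dispersion), dispersion >= 0)
  structure(list(mean = mean, dispersion = dispersion), class = "depth_spec")
}

draw_depths <- function(model, n) {
  if (is.numeric(model) && length(model) == 1L) {
    stopifnot(model >= 0)
    return(rep(as.integer(round(model)), n))
  }
  stopifnot(inherits(model, "depth_spec"))
  if (model$dispersion <= 0) {
    return(rep(as.integer(round(model$mean)), n))
  }
  stats::rnbinom(n, mu = model$mean, size = 1 / model$dispersion)
}
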