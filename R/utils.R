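#' @import data.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- colData
#' @importFrom S4Vectors DataFrame
#' @importFrom methods new validObject is slot
#' @importFrom stats median sd cor rnorm runif rpois rlnorm rexp lm coef residuals dist hclust cutree quantile setNames predict complete.cases
#' @importFrom utils head read.delim write.table
NULL

.MOD31 <- 2147483647L

# stable 31-bit string hash (polynomial, order-independent of platform)
stableHash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (code in utf8ToInt(x)) h <- (h * 31 + code) %% .MOD31
  as.integer(h)
}

# derive a substream seed from a master seed and one or more string labels
deriveSeed <- function(seed, ...) {
  h <- as.double(seed %% .MOD31)
  for (lab in as.character(c(...))) h <- (h * 69069 + stableHash(lab)) %% .MOD31
  as.integer(h)
}

# evaluate expr under a local RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

geomMean <- function(x) exp(mean(log(x)))

# lognormal sdlog giving a target coefficient of variation on the linear scale
sdlogFromCV <- function(cv) sqrt(log(1 + cv^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
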