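#' @importFrom methods new validObject is slot
#' @importFrom stats pt cor quantile sd median rnorm runif rbinom rnbinom
#'   mad fisher.test wilcox.test complete.cases setNames smooth.spline
#'   predict power.t.test dist
#' @importFrom utils read.delim write.table head
NULL

## Chromosome labels used throughout: mouse autosomes plus X.
chromLevels <- function() c(as.character(1:19), "X")

## Order index by chromosome (genomic order, X last) then position.
chromOrder <- function(chr, mb) {
  order(match(as.character(chr), chromLevels()), mb)
}

#' Mouse chromosome sizes
#'
#' Approximate lengths (Mb) of the mouse autosomes and the X chromosome,
#' used as the coordinate frame for the synthetic cohort and for
#' fraction-of-genome-altered summaries when no lengths are supplied.
#'
#' @return A data.frame with columns `chr` and `length_mb`.
#' @export
mouseChromosomes <- function() {
  data.frame(
    chr = chromLevels(),
    length_mb = c(197, 182, 160, 156, 152, 150, 152, 131, 124, 130,
                  122, 120, 120, 125, 103, 98, 95, 91, 61, 166),
    stringsAsFactors = FALSE
  )
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`.
## The caller's RNG stream is restored afterwards, so the same call with the
## same seed is reproducible regardless of surrounding code.
withSeed <- function(seed, expr) {
  env <- parent.frame()
  if (is.null(seed)) return(eval(substitute(expr), env))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval(substitute(expr), env)
}

## Derive a stream of child seeds from one master seed (kept below 2^31).
childSeeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  withSeed(seed, as.list(sample.int(.Machine$integer.max - 1L, n)))
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
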