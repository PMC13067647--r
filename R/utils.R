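#' @importFrom rlang .data
#' @importFrom stats optimize optim pchisq pnorm qnorm rbinom runif rnorm
#'   setNames p.adjust prcomp hclust dist as.dist lm anova model.matrix
#'   complete.cases aggregate
#' @importFrom utils head tail read.table write.table
NULL

# run `code` under a temporarily-seeded RNG stream; restores the caller's seed
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a child seed from the current RNG stream (keeps 32-bit range)
child_seed <- function() sample.int(.Machine$integer.max, 1L)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
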