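#' @keywords internal
"_PACKAGE"

#' Derive a per-stage substream seed from one master seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the master
#' seed and a stage name, so stages stay reproducible and independent of each
#' other's consumption of the random stream. Values stay below 2^31 so they
#' are always representable as R integers.
#'
#' @param master_seed Integer master seed.
#' @param stage Stage name (any string).
#' @return An integer seed.
#' @examples
#' stage_seed(1, "ignition")
#' @export
stage_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  codes <- utf8ToInt(stage)
  h <- as.double(master_seed) %% 2147483647
  for (ch in codes) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded by `seed` (NULL = leave RNG alone).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Population (n-denominator) standard deviation.
pop_sd <- function(x) {
  n <- length(x)
  if (n < 1L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

abort_ignitr <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ignitr_error")))
}
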