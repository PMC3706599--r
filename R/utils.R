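`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded at `seed`, then
#' restores the previous RNG state, so seeded internals never disturb a user's
#' random stream. A `NULL` seed evaluates the code unseeded.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# running-minimum-from-the-bottom monotonization of pfp along the RP ranking,
# clipped at 1; input must be ordered by ascending overall rank
monotonize_pfp <- function(pfp_in_rank_order) {
  pmin(rev(cummin(rev(pfp_in_rank_order))), 1)
}
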