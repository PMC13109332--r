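`%||%` <- function(a, b) if (is.null(a)) b else a

stop_trayphen <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "trayphen_error")))
}

#' Run code with a private RNG state
#'
#' Evaluates `expr` after `set.seed(seed)` and restores the caller's
#' `.Random.seed` afterwards, so deterministic generators do not disturb user
#' code.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## unique-row counter for integer grids; exact for |codes| < 2^53
count_unique_cells <- function(idx) {
  if (nrow(idx) == 0L) return(0L)
  code <- rep(0, nrow(idx))
  mult <- 1
  for (j in seq_len(ncol(idx))) {
    v <- idx[, j]
    v <- v - min(v)
    code <- code + v * mult
    mult <- mult * (max(v) + 1)
  }
  length(unique(code))
}
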