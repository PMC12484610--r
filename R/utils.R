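# Internal helpers shared across modules. Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

gm_stop <- function(...) stop(..., call. = FALSE)

gm_warn <- function(...) warning(..., call. = FALSE)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All generators route their randomness through this so that they are pure
# functions of their configuration (seed included).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# scalar checks; `what` names the argument in error messages
check_scalar <- function(x, what, positive = FALSE, nonneg = FALSE,
                         finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    gm_stop(what, " must be a single finite number")
  }
  if (positive && x <= 0) gm_stop(what, " must be > 0")
  if (nonneg && x < 0) gm_stop(what, " must be >= 0")
  invisible(x)
}

check_columns <- function(df, cols, file = NULL) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    where <- if (is.null(file)) "" else paste0(" in '", file, "'")
    gm_stop("missing required column(s)", where, ": ",
            paste(missing, collapse = ", "))
  }
  invisible(df)
}

# All n! permutations of 1..n as an (n! x n) integer matrix, memoised.
# Only used for exact Spearman p-values (n <= 8) and enumeration oracles.
.perm_cache <- new.env(parent = emptyenv())

permutations_of <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  if (n > 9L) gm_stop("refusing to enumerate permutations for n > 9")
  rec <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1L, 1L))
    do.call(rbind, lapply(seq_along(v), function(i) {
      cbind(v[i], rec(v[-i]), deparse.level = 0)
    }))
  }
  out <- rec(seq_len(n))
  storage.mode(out) <- "integer"
  .perm_cache[[key]] <- out
  out
}
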