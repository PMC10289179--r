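# shared internal helpers

assert_volume <- function(x, name = deparse(substitute(x))) {
  if (!is.array(x) || length(dim(x)) != 3L || !is.numeric(x))
    stop(sprintf("`%s` must be a 3D numeric array (z, y, x)", name), call. = FALSE)
  if (any(!is.finite(x)))
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  invisible(x)
}

assert_mask <- function(x, name = deparse(substitute(x))) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(sprintf("`%s` must be a 3D logical array", name), call. = FALSE)
  if (!is.logical(x)) {
    vals <- unique(as.vector(x))
    if (!all(vals %in% c(0, 1)))
      stop(sprintf("`%s` must be binary", name), call. = FALSE)
  }
  invisible(x)
}

as_mask <- function(x) {
  d <- dim(x)
  m <- as.logical(x != 0)
  dim(m) <- d
  m
}

same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s must share the same shape", what), call. = FALSE)
  invisible(TRUE)
}

# evaluate `expr` under a fixed seed without disturbing the caller's RNG state
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
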