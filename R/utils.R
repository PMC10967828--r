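# shared validation and RNG helpers (internal)

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

check_scalar_number <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config(field, "must be a single finite number")
  x
}

#' @noRd
clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Evaluate `expr` under a private, deterministically seeded RNG stream and
# restore the caller's RNG state afterwards.  Derived seeds are kept below
# 2^31 - 1.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

derive_seed <- function(seed, index, salt = 0L) {
  as.integer((as.double(seed) * 1000003 + as.double(index) * 7919 +
                as.double(salt) * 104729) %% 2147483647)
}

# coerce a matrix / HxWxC / HxWxCxN array to the internal 4D layout
as_tensor4 <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) == 2L) {
    array(x, c(dim(as.matrix(x)), 1L, 1L))
  } else if (length(d) == 3L) {
    array(x, c(d, 1L))
  } else if (length(d) == 4L) {
    x
  } else stop("expected a 2D, 3D or 4D array", call. = FALSE)
}

# undo as_tensor4 given the original dim
restore_dim <- function(x, d) {
  if (is.null(d) || length(d) == 2L) matrix(x, dim(x)[1], dim(x)[2])
  else if (length(d) == 3L) array(x, dim(x)[1:3])
  else x
}
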