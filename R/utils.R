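# internal helpers: seeded evaluation, seed derivation, size strings

# run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code never perturbs user randomness
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# derive `n` child seeds from a parent seed (kept below 2^31)
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Parse a printed image size
#'
#' Image sizes are printed width-first ("75x64" means 75 px wide, 64 px
#' tall); matrices in this package are `height x width`. This helper is the
#' single place where the convention is decoded.
#'
#' @param size a string like `"75x64"`, or a length-2 numeric
#'   `c(width, height)`.
#' @return named integer vector with elements `width` and `height`.
#' @examples
#' parse_size("75x64")
#' @export
parse_size <- function(size) {
  if (is.character(size)) {
    parts <- as.integer(strsplit(tolower(size), "x")[[1]])
    if (length(parts) != 2L || anyNA(parts))
      stop("size must look like '75x64' (width x height)")
  } else {
    parts <- as.integer(size)
    if (length(parts) != 2L || anyNA(parts)) stop("size must have two elements")
  }
  if (any(parts <= 0L)) stop("size must be positive")
  c(width = parts[1L], height = parts[2L])
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_u8_image <- function(img) {
  is.matrix(img) && is.numeric(img) && all(img >= 0 & img <= 255)
}
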