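deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (!is.finite(n) || n == 0) stop("cannot normalize a zero vector")
  v / n
}

## Evaluate `code` under a fixed RNG seed without disturbing the caller's
## RNG stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## Content hash for the render cache (md5 of a serialized object).
content_hash <- function(...) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(list(...), f, version = 2)
  unname(tools::md5sum(f))
}
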