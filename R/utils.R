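#' @keywords internal
"_PACKAGE"

## Collapse runs of whitespace and trim ends; NA -> "".
squish <- function(x) {
  x[is.na(x)] <- ""
  gsub("^\\s+|\\s+$", "", gsub("\\s+", " ", x))
}

## Evaluate `code` under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## round() in R is already half-even (IEC 60559), but guard against
## representation error at the .xx5 boundary before rounding to 2 dp.
round2 <- function(x) round(x + sign(x) * 1e-12, 2)

`%||%` <- function(a, b) if (is.null(a)) b else a
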