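#' @keywords internal
"_PACKAGE"

## Deterministic seed derivation: one master seed spawns named substreams so
## stages (phantom generation, CV folds, ...) can be rerun independently.
## Polynomial string hash folded into [1, 2^31 - 2].
derive_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  h <- as.double(master %% 2147483647)
  for (cp in utf8ToInt(paste0("#", key))) {
    h <- (h * 31 + cp) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

## Run an expression under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Pixel spacing of an image or mask
#'
#' Images and masks in this package are plain matrices carrying their pixel
#' spacing (mm, isotropic) in the `"spacing"` attribute.
#'
#' @param x A matrix with a `"spacing"` attribute.
#' @return Pixel spacing in mm (scalar).
#' @export
pixel_spacing <- function(x) {
  sp <- attr(x, "spacing")
  if (is.null(sp) || !is.numeric(sp) || any(sp <= 0)) {
    stop("pixel spacing metadata is missing or invalid", call. = FALSE)
  }
  sp[[1L]]
}

`pixel_spacing<-` <- function(x, value) {
  attr(x, "spacing") <- value
  x
}

set_spacing <- function(x, sp) {
  attr(x, "spacing") <- sp
  x
}

stop_if_not_congruent <- function(a, b, what = "masks") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s are not congruent: %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
         call. = FALSE)
  }
  invisible(TRUE)
}
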