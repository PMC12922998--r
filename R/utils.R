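# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clamp values to the unit interval
#'
#' All image planes in this package live in `[0, 1]`; compositions clamp after
#' arithmetic, never inside accumulators.
#'
#' @param x numeric vector, matrix or array.
#' @return `x` with every value clamped to `[0, 1]`.
#' @export
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

# Boxes are length-4 numeric c(x0, y0, x1, y1), pixel units, origin top-left,
# half-open [x0, x1) x [y0, y1).
box_valid <- function(b) {
  is.numeric(b) && length(b) == 4L && !anyNA(b) && b[1] < b[3] && b[2] < b[4]
}

box_area <- function(b) (b[3] - b[1]) * (b[4] - b[2])

box_centroid <- function(b) c((b[1] + b[3]) / 2, (b[2] + b[4]) / 2)

box_diag <- function(b) sqrt((b[3] - b[1])^2 + (b[4] - b[2])^2)

box_union <- function(a, b) {
  c(min(a[1], b[1]), min(a[2], b[2]), max(a[3], b[3]), max(a[4], b[4]))
}

# Clip a box to frame bounds; returns NULL when nothing remains.
box_clip <- function(b, width, height) {
  out <- c(max(b[1], 0), max(b[2], 0), min(b[3], width), min(b[4], height))
  if (out[1] >= out[3] || out[2] >= out[4]) return(NULL)
  out
}

# Integer pixel index range covered by a half-open box along one axis
# (1-based, inclusive), already clipped to [1, n].
box_px_range <- function(lo, hi, n) {
  i0 <- max(1L, as.integer(floor(lo)) + 1L)
  i1 <- min(n, as.integer(ceiling(hi)))
  if (i0 > i1) return(integer(0))
  i0:i1
}

#' Deterministic SHA-256 hash of an R object
#'
#' Used for encoder-configuration fingerprints and hash-based train/validation
#' splitting. Objects are serialized to a canonical character form first so
#' the hash is stable across sessions and platforms.
#'
#' @param x an R object (coerced through a canonical character representation).
#' @return lowercase hex string of length 64.
#' @export
stable_hash <- function(x) {
  digest::digest(paste(deparse(x, control = c("keepNA", "keepInteger")),
                       collapse = "\n"),
                 algo = "sha256", serialize = FALSE)
}

# Map a character key to a deterministic uniform deviate in [0, 1) using the
# first 13 hex digits (52 bits) of its SHA-256 — independent of R's RNG.
hash_unit <- function(key) {
  h <- vapply(key, function(k) {
    digest::digest(k, algo = "sha256", serialize = FALSE)
  }, character(1), USE.NAMES = FALSE)
  strtoi_frac(substr(h, 1L, 13L))
}

strtoi_frac <- function(hex13) {
  # 13 hex digits fit exactly in a double's 52-bit mantissa
  vapply(hex13, function(h) {
    digits <- strtoi(strsplit(h, "")[[1]], base = 16L)
    sum(digits * 16^(12:0)) / 16^13
  }, numeric(1), USE.NAMES = FALSE)
}

# Counter-based seed derivation: independent RNG substreams keyed by strings,
# so adding one randomized element never perturbs another's draws.
derive_seed <- function(...) {
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "|")
  h <- digest::digest(key, algo = "sha256", serialize = FALSE)
  as.integer(strtoi(substr(h, 1L, 7L), base = 16L) %% .Machine$integer.max)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
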