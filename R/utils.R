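# Internal helpers shared across modules.

# Deterministic child seed derivation (counter-based splitting): cell/stream k
# of master seed s always gets the same stream, independent of how many other
# streams exist. Keeps results < 2^31 so set.seed() is safe.
seed_child <- function(seed, tag) {
  s <- (as.double(seed) %% 2147483647)
  for (t in tag) {
    s <- (s * 48271 + as.double(t) * 16807 + 12345) %% 2147483647
  }
  as.integer(s)
}

# Evaluate fn under a temporary RNG state seeded from `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

stop_cv <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cognatevid_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x == round(x) && x > 0

# Gaussian blur of a numeric matrix (replicate-edge padding).
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  .cpp_gaussian_blur(img, sigma)
}

# 256-bin histogram of intensities clamped to [0, 255]; bin i (1-based) holds
# counts of floor(value) == i - 1.
intensity_hist <- function(values) {
  v <- floor(pmin(pmax(as.numeric(values), 0), 255))
  tabulate(v + 1L, nbins = 256L)
}
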