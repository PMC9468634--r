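# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's stream.
# seed = NULL draws from the ambient stream (documented behaviour of the
# low-level stochastic operations).
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

is_volume <- function(x) is.array(x) && length(dim(x)) == 3L && is.numeric(x)

check_volume <- function(x, cubic = FALSE, arg = "vol") {
  if (!is_volume(x)) {
    abort(sprintf("`%s` must be a numeric 3-d array", arg))
  }
  if (cubic && length(unique(dim(x))) != 1L) {
    abort(sprintf("`%s` must be cubic (got %s)", arg,
                  paste(dim(x), collapse = "x")))
  }
  invisible(x)
}

check_finite <- function(x, arg = "vol") {
  if (!all(is.finite(x))) abort(sprintf("`%s` contains NaN or Inf", arg))
  invisible(x)
}

# Uniform random proper rotation from the ambient RNG stream (quaternion draw).
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

rotation_z <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), -sin(a), 0,
           sin(a),  cos(a), 0,
           0,       0,      1), nrow = 3, byrow = TRUE)
}

# Stack a list of 3-d volumes into the (side, side, side, 1, N) batch layout
# consumed by the encoder.
stack_volumes <- function(vols) {
  d <- dim(vols[[1]])
  out <- array(0, c(d, 1L, length(vols)))
  for (i in seq_along(vols)) out[, , , 1L, i] <- vols[[i]]
  out
}

row_norms <- function(m) sqrt(rowSums(m^2))

l2_normalize_rows <- function(m) {
  n <- row_norms(m)
  n[n == 0] <- 1
  m / n
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}
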