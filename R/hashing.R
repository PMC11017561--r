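# Deterministic string hashing and MinHash machinery shared by the hashed
# fingerprints. Everything is done in doubles below 2^53 so results are
# bit-identical across platforms; no dependence on R's RNG state.

# Large Mersenne prime; all hash arithmetic is carried out modulo this.
.hash_prime <- 2147483647 # 2^31 - 1
.hash_base <- 131

# Polynomial rolling hash of a single string, fully vectorised over its
# bytes: h = sum(byte_i * base^(n-i)) mod p. Products stay below
# 255 * 2^31 and the sum below 2^53 for strings up to ~8000 bytes.
.hash_string <- function(s) {
  bytes <- utf8ToInt(s)
  n <- length(bytes)
  if (n == 0L) return(0)
  pows <- .hash_pows(n)
  sum((bytes * pows[n:1L]) %% .hash_prime) %% .hash_prime
}

# Cache of base powers mod p, grown on demand.
.hash_env <- new.env(parent = emptyenv())

.hash_pows <- function(n) {
  pows <- .hash_env$pows
  if (is.null(pows) || length(pows) < n) {
    m <- max(n, 512L)
    pows <- numeric(m)
    pows[1L] <- 1
    for (i in seq_len(m - 1L)) pows[i + 1L] <- (pows[i] * .hash_base) %% .hash_prime
    .hash_env$pows <- pows
  }
  pows[seq_len(n)]
}

.hash_strings <- function(strings) {
  vapply(strings, .hash_string, numeric(1), USE.NAMES = FALSE)
}

# Fixed universal-hash family for MinHash signatures: h_k(x) = (a_k x + b_k)
# mod p with a_k < 2^20 so a_k * x < 2^51. The coefficients are derived from
# an internal constant seed (independent of the caller's RNG) and cached per
# signature length, so signatures are reproducible across sessions.
.minhash_coeffs <- function(dims) {
  key <- paste0("mh", dims)
  co <- .hash_env[[key]]
  if (is.null(co)) {
    rng <- .lcg_stream(982451653, 2L * dims)
    co <- list(
      a = 1 + floor(rng[seq_len(dims)] * (2^20 - 1)),
      b = floor(rng[dims + seq_len(dims)] * (.hash_prime - 1))
    )
    .hash_env[[key]] <- co
  }
  co
}

# Minimal deterministic uniform stream (Lehmer generator, Park-Miller
# constants) used only to derive hash coefficients; keeps fingerprinting
# independent of set.seed().
.lcg_stream <- function(seed, n) {
  out <- numeric(n)
  state <- seed %% 2147483647
  if (state == 0) state <- 1
  for (i in seq_len(n)) {
    state <- (state * 48271) %% 2147483647
    out[i] <- state / 2147483647
  }
  out
}

# MinHash signature of a set of pre-hashed shingles (values in [0, p)).
.minhash_signature <- function(hashes, dims) {
  co <- .minhash_coeffs(dims)
  n <- length(hashes)
  if (n == 0L) return(rep(NA_real_, dims))
  # dims x n matrix of h_k(x); row-wise minimum via max.col on the negation.
  m <- (outer(co$a, hashes) + co$b) %% .hash_prime
  idx <- max.col(-m, ties.method = "first")
  m[cbind(seq_len(dims), idx)]
}
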