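# Permutation ciphers on square images: the discretized generalized
# baker map and the Arnold cat map. Both are bijections on the N x N
# pixel grid, so encryption relocates pixel values without changing the
# value multiset. Coordinates are 0-based (column r, row s) with the
# origin at the bottom-left; conversion to R's matrix layout happens only
# at the image boundary.

#' Baker-map encryption key
#'
#' The generalized baker map partitions an `N x N` image into vertical
#' rectangles of widths `n_1, ..., n_k` with `sum(n_i) = N`; each
#' rectangle is cut into `n_i` boxes of `N` pixels and every box is laid
#' out as a row, the left box at the bottom. For the discretized map to
#' be a bijection each `n_i` must also divide `N` (enforced here, beyond
#' the sum constraint).
#'
#' @param side Image side `N` (>= 2).
#' @param partition Integer vector `n_1..n_k`, each >= 1, each dividing
#'   `side`, summing to `side`.
#' @param iterations Number of times the map is applied (>= 1).
#' @return A `baker_key`.
#' @export
baker_key <- function(side, partition, iterations = 1L) {
  assert_scalar_number(side, "side", 2)
  assert_scalar_number(iterations, "iterations", 1)
  side <- as.integer(side)
  partition <- as.integer(partition)
  if (length(partition) < 1L || any(partition < 1L)) {
    stop("baker key: partition entries must be positive integers", call. = FALSE)
  }
  if (sum(partition) != side) {
    stop("baker key: partition must sum to the image side (", side, ")",
         call. = FALSE)
  }
  if (any(side %% partition != 0L)) {
    stop("baker key: every partition entry must divide the image side",
         call. = FALSE)
  }
  structure(list(type = "baker", side = side, partition = partition,
                 iterations = as.integer(iterations)),
            class = c("baker_key", "chaos_key"))
}

#' Arnold cat-map encryption key
#'
#' @param side Image side `N` (>= 2).
#' @param iterations Number of times the map is applied (>= 1).
#' @return An `arnold_key`.
#' @export
arnold_key <- function(side, iterations = 1L) {
  assert_scalar_number(side, "side", 2)
  assert_scalar_number(iterations, "iterations", 1)
  structure(list(type = "arnold", side = as.integer(side),
                 iterations = as.integer(iterations)),
            class = c("arnold_key", "chaos_key"))
}

#' Continuous baker map on the unit square
#'
#' `B(x, y) = (2x, y/2)` for `x < 1/2` and `(2x - 1, y/2 + 1/2)`
#' otherwise: the square is stretched horizontally, halved and restacked.
#'
#' @param x Coordinate in \[0, 1).
#' @param y Coordinate in \[0, 1\].
#' @return Numeric vector `c(x', y')`.
#' @export
baker_continuous <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != 1L || length(y) != 1L ||
      x < 0 || x >= 1 || y < 0 || y > 1) {
    stop("baker_continuous: need 0 <= x < 1 and 0 <= y <= 1", call. = FALSE)
  }
  if (x < 0.5) c(2 * x, y / 2) else c(2 * x - 1, y / 2 + 0.5)
}

# Vectorized single application of the discretized baker map.
baker_step <- function(r, s, key) {
  N <- key$side
  offsets <- c(0L, cumsum(key$partition))
  band <- findInterval(r, offsets, rightmost.closed = FALSE)  # 1..k
  ni <- key$partition[band]
  Ni <- offsets[band]
  q <- N %/% ni
  list(r = q * (r - Ni) + s %% q,
       s = (s - s %% q) %/% q + Ni)
}

#' Discretized generalized baker map of a single pixel
#'
#' For the vertical rectangle `[N_i, N_i + n_i)` containing column `r`
#' (with `N_i = n_1 + ... + n_{i-1}` and `q = N / n_i`):
#' `r' = q (r - N_i) + (s mod q)` and `s' = (s - s mod q) / q + N_i`.
#'
#' @param r Column index, 0-based, in \[0, N).
#' @param s Row index, 0-based, in \[0, N), origin at the bottom.
#' @param key A [baker_key()].
#' @return Integer vector `c(r', s')`.
#' @export
baker_discrete <- function(r, s, key) {
  stopifnot(inherits(key, "baker_key"))
  if (r < 0 || r >= key$side || s < 0 || s >= key$side) {
    stop("baker_discrete: indices out of range [0, N)", call. = FALSE)
  }
  st <- baker_step(as.integer(r), as.integer(s), key)
  c(as.integer(st$r), as.integer(st$s))
}

#' Arnold cat map of a single pixel
#'
#' The standard area-preserving torus map
#' `(x, y) -> ((x + y) mod N, (x + 2y) mod N)`; on a finite grid its
#' iterates form a permutation with a finite period.
#'
#' @param x,y 0-based indices in \[0, N).
#' @param side Grid side `N` (>= 2).
#' @return Integer vector `c(x', y')`.
#' @export
arnold_map <- function(x, y, side) {
  assert_scalar_number(side, "side", 2)
  if (x < 0 || x >= side || y < 0 || y >= side) {
    stop("arnold_map: indices out of range [0, N)", call. = FALSE)
  }
  c(as.integer((x + y) %% side), as.integer((x + 2 * y) %% side))
}

# One full-grid application of a key's map. `r` and `s` are vectors over
# all N^2 cells; returns the mapped vectors.
grid_step <- function(r, s, key) {
  if (inherits(key, "baker_key")) {
    baker_step(r, s, key)
  } else {
    list(r = (r + s) %% key$side, s = (r + 2 * s) %% key$side)
  }
}

#' Build the pixel permutation induced by one or more chaotic keys
#'
#' Composes the key's single-step map `iterations` times (keys given as a
#' list are composed left to right, each with its own iteration count).
#' The result records both the forward mapping and its exact inverse.
#'
#' @param key A [baker_key()], [arnold_key()], or list of keys sharing
#'   one side.
#' @return A `pixel_permutation`: list with `side`, `mapping` and
#'   `inverse` (integer vectors of length `N^2`; `mapping[i]` is the
#'   1-based destination cell of source cell `i`, cells enumerated with
#'   `r` fastest from the bottom-left).
#' @export
build_permutation <- function(key) {
  keys <- if (inherits(key, "chaos_key")) list(key) else key
  if (length(keys) == 0L || !all(vapply(keys, inherits, logical(1), "chaos_key"))) {
    stop("`key` must be a chaos key or a non-empty list of them", call. = FALSE)
  }
  N <- keys[[1]]$side
  if (!all(vapply(keys, `[[`, integer(1), "side") == N)) {
    stop("all keys must share the same side", call. = FALSE)
  }
  cells <- 0:(N * N - 1L)
  r <- cells %% N
  s <- cells %/% N
  for (k in keys) {
    for (it in seq_len(k$iterations)) {
      st <- grid_step(r, s, k)
      r <- st$r
      s <- st$s
    }
  }
  mapping <- as.integer(s * N + r + 1L)
  if (anyDuplicated(mapping)) {
    stop("internal error: induced map is not a bijection", call. = FALSE)
  }
  inverse <- integer(length(mapping))
  inverse[mapping] <- seq_along(mapping)
  structure(list(side = N, mapping = mapping, inverse = inverse),
            class = "pixel_permutation")
}

#' Period of the Arnold cat map on an N x N grid
#'
#' Brute force: iterate the full-grid permutation until it returns to the
#' identity.
#'
#' @param side Grid side `N` (>= 2).
#' @param max_period Safety cap on the search.
#' @return The period as an integer.
#' @export
arnold_period <- function(side, max_period = 10000L) {
  one <- build_permutation(arnold_key(side, 1L))$mapping
  ident <- seq_along(one)
  cur <- one
  for (p in seq_len(max_period)) {
    if (all(cur == ident)) return(p)
    cur <- one[cur]
  }
  stop("arnold_period: period exceeds max_period = ", max_period, call. = FALSE)
}

# (r, s) cell enumeration <-> R matrix layout (row 1 = top of the image).
perm_of_matrix <- function(px, perm, forward = TRUE) {
  N <- perm$side
  if (nrow(px) != N || ncol(px) != N) {
    stop("image side (", nrow(px), "x", ncol(px),
         ") does not match key side ", N, call. = FALSE)
  }
  # matrix -> cell vector: cell index s*N + r + 1 with r fastest.
  # px[N:1, ] flips rows so row index counts from the bottom; as.vector is
  # column-major, i.e. s fastest -- transpose first to make r fastest.
  v <- as.vector(t(px[N:1, , drop = FALSE]))
  out <- integer(length(v))
  if (forward) out[perm$mapping] <- v else out[perm$inverse] <- v
  m <- matrix(out, nrow = N, byrow = TRUE)  # rows = s from bottom
  m[N:1, , drop = FALSE]
}

#' Encrypt a spectrogram image with a pixel permutation
#'
#' Pixels are relocated, never altered: the output histogram equals the
#' input histogram exactly, and [decrypt_image()] restores the original
#' bit-for-bit.
#'
#' @param image A square `spectrogram_image` whose side matches the
#'   permutation's.
#' @param permutation A [build_permutation()] result.
#' @return The encrypted `spectrogram_image`.
#' @export
encrypt_image <- function(image, permutation) {
  stopifnot(inherits(image, "spectrogram_image"),
            inherits(permutation, "pixel_permutation"))
  out <- image
  out$pixels <- perm_of_matrix(image$pixels, permutation, forward = TRUE)
  out
}

#' Decrypt a spectrogram image (inverse of [encrypt_image()])
#'
#' @inheritParams encrypt_image
#' @return The decrypted `spectrogram_image`.
#' @export
decrypt_image <- function(image, permutation) {
  stopifnot(inherits(image, "spectrogram_image"),
            inherits(permutation, "pixel_permutation"))
  out <- image
  out$pixels <- perm_of_matrix(image$pixels, permutation, forward = FALSE)
  out
}

#' Serialize a chaotic key to JSON
#'
#' @param key A chaos key.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_key <- function(key, path) {
  stopifnot(inherits(key, "chaos_key"))
  jsonlite::write_json(
    list(type = key$type, N = key$side,
         partition = key$partition, iterations = key$iterations),
    path, auto_unbox = TRUE, null = "null"
  )
  invisible(path)
}

#' Read a chaotic key from JSON
#'
#' @param path JSON path written by [write_key()].
#' @return A chaos key.
#' @export
read_key <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(j$type,
    baker = baker_key(j$N, j$partition, j$iterations),
    arnold = arnold_key(j$N, j$iterations),
    stop("unknown key type: ", j$type, call. = FALSE)
  )
}
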