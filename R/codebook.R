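#' Circular coded-target ring codes
#'
#' Targets carry a 12-bit cyclic code in an annular ring around the central
#' disc. A target ID names an equivalence class of cyclic rotations of the
#' 12-bit word, so decoding is invariant to the in-plane orientation of the
#' target. The code book is built greedily over candidate words ordered by
#' value, keeping a word only if its minimum cyclic Hamming distance to every
#' word already kept is at least 3; the all-zero and all-one words are
#' reserved invalid. Distance 3 guarantees that any single-bit corruption is
#' rejected rather than mis-decoded (exact-match decoding).
#'
#' @name ring_codes
NULL

RING_BITS <- 12L

rotate_bits <- function(bits, k) {
  n <- length(bits)
  k <- k %% n
  if (k == 0) return(bits)
  c(bits[(k + 1):n], bits[1:k])
}

bits_to_int <- function(bits) sum(bits * 2^(seq_along(bits) - 1))

int_to_bits <- function(x, n = RING_BITS) as.integer(intToBits(x)[1:n])

#' Canonical form of a ring word: the rotation with the smallest integer value
#' @param bits integer 0/1 vector of length 12
#' @keywords internal
canonical_ring <- function(bits) {
  vals <- vapply(seq_along(bits) - 1L,
                 function(k) bits_to_int(rotate_bits(bits, k)), numeric(1))
  int_to_bits(min(vals))
}

cyclic_hamming <- function(a, b) {
  min(vapply(seq_along(a) - 1L,
             function(k) sum(rotate_bits(a, k) != b), numeric(1)))
}

# A ring read in the mirrored direction (target seen through a reflected
# affine frame) reverses the cyclic order; the book keeps a word only if its
# reversal is also >= min_dist from every other kept word, so a mirrored read
# can only ever match the word's own ID.
build_code_book <- function(n_bits = RING_BITS, min_dist = 3L) {
  words <- list()
  seen <- integer(0)
  for (v in 1:(2^n_bits - 2)) {
    bits <- int_to_bits(v, n_bits)
    cv <- bits_to_int(canonical_ring(bits))
    if (cv != v || cv %in% seen) next
    rbits <- rev(bits)
    self_sym <- cyclic_hamming(bits, rbits) == 0
    ok <- TRUE
    for (w in words) {
      if (cyclic_hamming(bits, w) < min_dist ||
          cyclic_hamming(rbits, w) < min_dist) { ok <- FALSE; break }
    }
    if (ok && !self_sym && cyclic_hamming(bits, rbits) < min_dist)
      ok <- FALSE
    if (ok) {
      words[[length(words) + 1L]] <- bits
      seen <- c(seen, cv)
    }
  }
  words
}

.codebook_env <- new.env(parent = emptyenv())

#' The ring code book
#'
#' @return list of 12-bit words (integer vectors), indexed by target ID
#' @export
ring_code_book <- function() {
  if (is.null(.codebook_env$book)) {
    .codebook_env$book <- build_code_book()
    .codebook_env$lookup <- vapply(.codebook_env$book, bits_to_int, numeric(1))
  }
  .codebook_env$book
}

#' Encode a target ID as its ring word
#' @param id integer target ID (1-based index into the code book)
#' @return integer 0/1 vector of length 12
#' @export
encode_ring_code <- function(id) {
  book <- ring_code_book()
  if (id < 1 || id > length(book)) stop("target ID outside the code book")
  book[[id]]
}

#' Decode a sampled bit ring to a target ID
#'
#' Exact-match decoding over cyclic rotations: the canonical rotation of the
#' sampled word is looked up in the code book; any word not in the book
#' (including every single-bit corruption of a valid word, and the reserved
#' all-zero/all-one words) is rejected.
#'
#' @param bits integer 0/1 vector of length 12
#' @return the target ID, or `NA_integer_` on rejection
#' @export
decode_ring_code <- function(bits) {
  if (length(bits) != RING_BITS || !all(bits %in% c(0L, 1L)))
    return(NA_integer_)
  if (all(bits == 0L) || all(bits == 1L)) return(NA_integer_)
  ring_code_book()
  bits <- as.integer(bits)
  v <- bits_to_int(canonical_ring(bits))
  hit <- match(v, .codebook_env$lookup)
  if (!is.na(hit)) return(as.integer(hit))
  # mirrored read direction
  vr <- bits_to_int(canonical_ring(rev(bits)))
  hit <- match(vr, .codebook_env$lookup)
  if (is.na(hit)) NA_integer_ else as.integer(hit)
}
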