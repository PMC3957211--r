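#' k-of-n constant-weight address code specification
#'
#' An AER (address-event representation) bus of `width` wires signals an
#' address by driving exactly `weight` wires HIGH.  The number of distinct
#' addresses is the binomial coefficient `choose(width, weight)`: 56 for the
#' 3-of-8 neuron bus, 126 for the 4-of-9 axon bus.
#'
#' @param width Number of address wires on the bus (M).
#' @param weight Number of wires HIGH in a valid address (N), with
#'   `0 < weight < width`.
#' @return A `polysnn_code_spec` object.
#' @examples
#' n_addresses(code_spec(8, 3))  # 56
#' n_addresses(code_spec(9, 4))  # 126
#' @export
code_spec <- function(width, weight) {
  if (length(width) != 1L || length(weight) != 1L ||
      !is.finite(width) || !is.finite(weight) ||
      width != as.integer(width) || weight != as.integer(weight)) {
    abort("`width` and `weight` must be single integers.",
          class = "polysnn_invalid_spec")
  }
  width <- as.integer(width)
  weight <- as.integer(weight)
  if (weight <= 0L || weight >= width) {
    abort(
      sprintf("invalid k-of-n code: need 0 < weight < width, got %d-of-%d",
              weight, width),
      class = "polysnn_invalid_spec"
    )
  }
  structure(list(width = width, weight = weight), class = "polysnn_code_spec")
}

#' Number of valid addresses of a k-of-n code
#'
#' @param spec A [code_spec()].
#' @return `choose(width, weight)` as an integer.
#' @export
n_addresses <- function(spec) {
  stopifnot(inherits(spec, "polysnn_code_spec"))
  as.integer(round(choose(spec$width, spec$weight)))
}

# popcount of non-negative integers below 2^16, vectorised
.popcount <- function(x) {
  n <- integer(length(x))
  x <- as.integer(x)
  while (any(x > 0L)) {
    n <- n + (x %% 2L)
    x <- x %/% 2L
  }
  n
}

#' Build a k-of-n codebook
#'
#' Enumerates every valid codeword of the code and fixes the index/codeword
#' bijection.  Codewords are bit-vectors over wires 1..M; wire 1 is the most
#' significant bit of the integer representation, so lexicographic order of
#' bit-vectors coincides with ascending integer order.  Index 0 maps to the
#' lexicographically smallest codeword.
#'
#' @param spec A [code_spec()].
#' @return A `polysnn_codebook` with elements `spec`, `words` (integer
#'   codewords, index `i` stored at position `i + 1`) and `index_of`
#'   (inverse lookup, `NA` for invalid words).
#' @examples
#' book <- build_codebook(code_spec(4, 2))
#' tidy(book)
#' @export
build_codebook <- function(spec) {
  stopifnot(inherits(spec, "polysnn_code_spec"))
  m <- spec$width
  all_words <- 0:(2L^m - 1L)
  words <- all_words[.popcount(all_words) == spec$weight]
  words <- sort(words)                      # lexicographic order of bit-vectors
  index_of <- rep(NA_integer_, 2L^m)
  index_of[words + 1L] <- seq_along(words) - 1L
  structure(list(spec = spec, words = as.integer(words), index_of = index_of),
            class = "polysnn_codebook")
}

#' @export
print.polysnn_codebook <- function(x, ...) {
  cat(sprintf("<polysnn_codebook> %d-of-%d, %d addresses\n",
              x$spec$weight, x$spec$width, length(x$words)))
  invisible(x)
}

#' @export
tidy.polysnn_codebook <- function(x, ...) {
  m <- x$spec$width
  tibble(
    index = seq_along(x$words) - 1L,
    word = x$words,
    bits = vapply(x$words, function(w) {
      paste(rev(as.integer(intToBits(w)[seq_len(m)])), collapse = "")
    }, character(1))
  )
}

#' Encode an address index as a codeword
#'
#' @param book A [build_codebook()] result.
#' @param index Integer address index in `[0, n_addresses)`.
#' @return Integer codeword (wire 1 = most significant bit).
#' @export
aer_encode <- function(book, index) {
  stopifnot(inherits(book, "polysnn_codebook"))
  index <- as.integer(index)
  if (any(is.na(index)) || any(index < 0L) || any(index >= length(book$words))) {
    abort(sprintf("address index out of range [0, %d)", length(book$words)),
          class = "polysnn_lookup_error")
  }
  book$words[index + 1L]
}

#' Decode a codeword to its address index
#'
#' A word is valid only if exactly `weight` bits are HIGH; anything else
#' (including the all-zeros word) is rejected.
#'
#' @param book A [build_codebook()] result.
#' @param word Integer codeword(s).
#' @return Integer address index in `[0, n_addresses)`.
#' @export
aer_decode <- function(book, word) {
  stopifnot(inherits(book, "polysnn_codebook"))
  word <- as.integer(word)
  bad <- is.na(word) | word < 0L | word >= 2L^book$spec$width |
    .popcount(pmax(word, 0L)) != book$spec$weight
  if (any(bad)) {
    abort(
      sprintf("invalid codeword: popcount != %d for %s", book$spec$weight,
              paste(word[bad], collapse = ", ")),
      class = "polysnn_invalid_codeword"
    )
  }
  book$index_of[word + 1L]
}

# wires (1-based, 1..M) that are HIGH in a codeword
.word_wires <- function(word, m) {
  bits <- as.integer(intToBits(word)[seq_len(m)])  # bit k-1 = wire m-k+1
  which(rev(bits) == 1L)
}
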