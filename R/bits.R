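# Bit-level plumbing. Bit vectors are integer vectors of 0/1, ordered
# most-significant-bit-first within the byte stream (so byte 0xB1 becomes
# 1,0,1,1,0,0,0,1). Kept internal; user-facing code deals in bytes and bases.

bytes_to_bits <- function(bytes) {
  if (length(bytes) == 0L) return(integer(0))
  m <- matrix(as.integer(rawToBits(bytes)), nrow = 8L)  # LSB-first per byte
  as.integer(m[8:1, ])
}

bits_to_bytes <- function(bits) {
  stopifnot(length(bits) %% 8L == 0L)
  if (length(bits) == 0L) return(raw(0))
  m <- matrix(as.integer(bits), nrow = 8L)
  as.raw(colSums(m * c(128L, 64L, 32L, 16L, 8L, 4L, 2L, 1L)))
}

# big-endian fixed-width integer <-> bits
int_to_bits <- function(x, width) {
  stopifnot(x >= 0, x < 2^width)
  as.integer(x %/% 2^((width - 1L):0L)) %% 2L
}

bits_to_int <- function(bits) {
  sum(as.integer(bits) * 2^((length(bits) - 1L):0L))
}
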