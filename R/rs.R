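# Systematic Reed-Solomon over GF(2^8), primitive polynomial x^8+x^4+x^3+x^2+1
# (0x11D), first consecutive root alpha^0. Written here because the parity
# suffix is part of the sequence format: two parity bytes render as 8 nt and
# correct any single corrupted byte of a sequence.

gf_tables <- function() {
  hit <- .oligostore_cache[["gf256"]]
  if (!is.null(hit)) return(hit)
  exp <- integer(512)
  log <- integer(256)
  x <- 1L
  for (i in 0:254) {
    exp[i + 1L] <- x
    log[x + 1L] <- i
    x <- bitwShiftL(x, 1L)
    if (x >= 256L) x <- bitwAnd(bitwXor(x, 285L), 255L)
  }
  exp[256:510] <- exp[1:255]  # wraparound so products index directly
  res <- list(exp = exp, log = log)
  .oligostore_cache[["gf256"]] <- res
  res
}

gf_mul <- function(a, b) {
  t <- gf_tables()
  n <- max(length(a), length(b))
  a <- rep_len(as.integer(a), n)
  b <- rep_len(as.integer(b), n)
  r <- integer(n)
  nz <- a != 0L & b != 0L
  r[nz] <- t$exp[t$log[a[nz] + 1L] + t$log[b[nz] + 1L] + 1L]
  r
}

gf_div <- function(a, b) {
  t <- gf_tables()
  stopifnot(all(b != 0L))
  if (a == 0L) return(0L)
  t$exp[(t$log[a + 1L] - t$log[b + 1L] + 255L) %% 255L + 1L]
}

gf_pow <- function(i) {  # alpha^i, any integer i
  t <- gf_tables()
  t$exp[(i %% 255L) + 1L]
}

# polynomial coefficients highest-degree first
gf_poly_mul <- function(p, q) {
  r <- integer(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    if (p[i] == 0L) next
    r[i:(i + length(q) - 1L)] <- bitwXor(r[i:(i + length(q) - 1L)],
                                         gf_mul(rep(p[i], length(q)), q))
  }
  r
}

gf_poly_eval <- function(p, x) {  # Horner
  y <- 0L
  for (coef in p) y <- bitwXor(gf_mul(y, x), coef)
  y
}

rs_gen_poly <- function(parity) {
  key <- sprintf("rsgen.%d", parity)
  hit <- .oligostore_cache[[key]]
  if (!is.null(hit)) return(hit)
  g <- 1L
  for (i in 0:(parity - 1L)) g <- gf_poly_mul(g, c(1L, gf_pow(i)))
  .oligostore_cache[[key]] <- g
  g
}

#' Append Reed-Solomon parity to a message
#'
#' Systematic encoding over GF(2^8): the message bytes are unchanged and
#' `parity` parity bytes are appended. [rs_recover()] corrects up to
#' `floor(parity / 2)` corrupted bytes anywhere in the codeword.
#'
#' @param message A raw vector; `length(message) + parity` must be <= 255.
#' @param parity Number of parity bytes (>= 1).
#' @return A raw vector of `length(message) + parity` bytes.
#' @export
rs_protect <- function(message, parity = 2L) {
  stopifnot(is.raw(message), parity >= 1L)
  if (length(message) + parity > 255L)
    stop("message + parity exceeds the 255-byte Reed-Solomon block",
         call. = FALSE)
  gen <- rs_gen_poly(parity)
  msg <- as.integer(message)
  rem <- c(msg, integer(parity))
  for (i in seq_along(msg)) {
    coef <- rem[i]
    if (coef != 0L) {
      seg <- i:(i + parity)
      rem[seg] <- bitwXor(rem[seg], gf_mul(rep(coef, parity + 1L), gen))
    }
  }
  as.raw(c(msg, rem[(length(msg) + 1L):(length(msg) + parity)]))
}

#' Recover a message from a Reed-Solomon codeword
#'
#' Syndrome decoding (Berlekamp-Massey, Chien search, Forney) with a final
#' re-check of the corrected word's syndromes. Corrects up to
#' `floor(parity / 2)` byte errors; patterns beyond that are flagged as
#' failures whenever the algebra betrays them (a distance-`parity + 1` code
#' cannot promise detection of every heavier pattern).
#'
#' @param codeword A raw vector as produced by [rs_protect()], possibly
#'   corrupted.
#' @param parity Number of parity bytes used at encode time.
#' @return A list with `message` (raw), `corrected` (number of byte
#'   corrections applied) and `ok` (`FALSE` when decoding failed, in which
#'   case `message` is the uncorrected prefix).
#' @export
rs_recover <- function(codeword, parity = 2L) {
  stopifnot(is.raw(codeword), parity >= 1L, length(codeword) > parity)
  cw <- as.integer(codeword)
  n <- length(cw)
  msg_len <- n - parity
  synd <- vapply(0:(parity - 1L), function(i) gf_poly_eval(cw, gf_pow(i)),
                 integer(1))
  fail <- function() list(message = as.raw(cw[seq_len(msg_len)]),
                          corrected = 0L, ok = FALSE)
  if (all(synd == 0L))
    return(list(message = as.raw(cw[seq_len(msg_len)]), corrected = 0L,
                ok = TRUE))
  # Berlekamp-Massey: error locator sigma, lowest-degree-first coefficients
  sigma <- 1L; B <- 1L; L <- 0L; m <- 1L; b <- 1L
  for (r in seq_len(parity)) {
    d <- synd[r]
    if (L >= 1L) for (i in seq_len(min(L, length(sigma) - 1L, r - 1L))) {
      d <- bitwXor(d, gf_mul(sigma[i + 1L], synd[r - i]))
    }
    if (d == 0L) {
      m <- m + 1L
    } else if (2L * L <= r - 1L) {
      Told <- sigma
      coef <- gf_div(d, b)
      shift <- c(integer(m), gf_mul(rep(coef, length(B)), B))
      len <- max(length(sigma), length(shift))
      sigma <- bitwXor(c(sigma, integer(len - length(sigma))),
                       c(shift, integer(len - length(shift))))
      L <- r - L; B <- Told; b <- d; m <- 1L
    } else {
      coef <- gf_div(d, b)
      shift <- c(integer(m), gf_mul(rep(coef, length(B)), B))
      len <- max(length(sigma), length(shift))
      sigma <- bitwXor(c(sigma, integer(len - length(sigma))),
                       c(shift, integer(len - length(shift))))
      m <- m + 1L
    }
  }
  while (length(sigma) > 1L && sigma[length(sigma)] == 0L)
    sigma <- sigma[-length(sigma)]
  n_err <- length(sigma) - 1L
  if (n_err == 0L || L > parity %/% 2L || n_err != L) return(fail())
  # Chien search over codeword positions: byte j (1-based) carries x^(n-j)
  err_pos <- integer(0)
  for (j in seq_len(n)) {
    xinv <- gf_pow(-(n - j))
    if (gf_poly_eval(rev(sigma), xinv) == 0L) err_pos <- c(err_pos, j)
  }
  if (length(err_pos) != n_err) return(fail())
  # Forney: omega = S(x) * sigma(x) mod x^parity (lowest-first)
  omega_full <- gf_poly_mul(rev(c(synd)), rev(sigma))  # highest-first
  omega <- rev(omega_full)[seq_len(min(parity, length(omega_full)))]
  sigma_deriv <- sigma[seq(2L, length(sigma), by = 2L)]  # odd-degree coeffs
  for (j in err_pos) {
    Xj <- gf_pow(n - j)
    Xinv <- gf_pow(-(n - j))
    num <- 0L
    xp <- 1L
    for (c0 in omega) {
      num <- bitwXor(num, gf_mul(c0, xp))
      xp <- gf_mul(xp, Xinv)
    }
    den <- 0L
    xp <- 1L
    for (c0 in sigma_deriv) {
      den <- bitwXor(den, gf_mul(c0, xp))
      xp <- gf_mul(xp, gf_mul(Xinv, Xinv))
    }
    if (den == 0L) return(fail())
    magnitude <- gf_mul(Xj, gf_div(num, den))
    cw[j] <- bitwXor(cw[j], magnitude)
  }
  synd2 <- vapply(0:(parity - 1L), function(i) gf_poly_eval(cw, gf_pow(i)),
                  integer(1))
  if (any(synd2 != 0L)) return(fail())
  list(message = as.raw(cw[seq_len(msg_len)]), corrected = length(err_pos),
       ok = TRUE)
}
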