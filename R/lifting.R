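# Lifting factorization of the registered wavelets.
#
# The polyphase matrix of the analysis filter bank is factored into
# elementary lifting steps (predict steps updating the odd channel from
# the even one, update steps doing the reverse) followed by a diagonal
# scaling, via the Euclidean algorithm on Laurent polynomials. The
# factorization is computed once per wavelet and cached; applying the
# steps to the even/odd polyphase components of a signal reproduces the
# classical filter-bank subbands exactly, and inverting the steps in
# reverse order gives perfect reconstruction by construction.

# ---- Laurent polynomial arithmetic -----------------------------------
# representation: list(c = coefficient vector, lo = exponent of c[1])

lp <- function(coefs, lo = 0L) lp_trim(list(c = as.numeric(coefs), lo = as.integer(lo)))

lp_trim <- function(p, tol = 1e-12) {
  c <- p$c
  nz <- which(abs(c) > tol)
  if (!length(nz)) return(list(c = numeric(0), lo = 0L))
  list(c = c[nz[1]:nz[length(nz)]], lo = p$lo + nz[1] - 1L)
}

lp_is_zero <- function(p) length(p$c) == 0L

# trim relative to the polynomial's own scale; used where roundoff from
# large intermediate quotients must not survive as spurious degrees
lp_chop <- function(p, rel = 1e-9) {
  if (!length(p$c)) return(p)
  lp_trim(p, tol = max(1e-12, rel * max(abs(p$c))))
}
lp_span <- function(p) length(p$c) - 1L          # degree spread hi - lo
lp_hi <- function(p) p$lo + length(p$c) - 1L

lp_add <- function(a, b, sign = 1) {
  if (lp_is_zero(a)) return(lp_trim(list(c = sign * b$c, lo = b$lo)))
  if (lp_is_zero(b)) return(a)
  lo <- min(a$lo, b$lo)
  hi <- max(lp_hi(a), lp_hi(b))
  c <- numeric(hi - lo + 1L)
  ia <- (a$lo - lo + 1L):(a$lo - lo + length(a$c))
  ib <- (b$lo - lo + 1L):(b$lo - lo + length(b$c))
  c[ia] <- a$c
  c[ib] <- c[ib] + sign * b$c
  lp_trim(list(c = c, lo = lo))
}

lp_sub <- function(a, b) lp_add(a, b, sign = -1)

lp_mul <- function(a, b) {
  if (lp_is_zero(a) || lp_is_zero(b)) return(lp(numeric(0)))
  lp_trim(list(c = as.numeric(stats::convolve(a$c, rev(b$c), type = "open")),
               lo = a$lo + b$lo))
}

lp_scale_mono <- function(p, coef, shift) {
  if (lp_is_zero(p)) return(p)
  list(c = coef * p$c, lo = p$lo + as.integer(shift))
}

# Division with remainder, span(r) < span(b). Laurent division is
# non-unique: terms can be eliminated from the highest degree down
# ("top") or from the lowest degree up ("bottom"). Both are exact; the
# caller picks the variant with the smaller coefficient growth, which is
# what keeps the factorization numerically well behaved.
lp_div <- function(a, b, mode = c("top", "bottom")) {
  mode <- match.arg(mode)
  if (lp_is_zero(b)) stop("division by zero Laurent polynomial")
  q <- lp(numeric(0))
  r <- a
  while (!lp_is_zero(r) && lp_span(r) >= lp_span(b)) {
    if (mode == "top") {
      edge <- lp_hi(r)
      s <- edge - lp_hi(b)
      cc <- r$c[length(r$c)] / b$c[length(b$c)]
    } else {
      edge <- r$lo
      s <- edge - b$lo
      cc <- r$c[1] / b$c[1]
    }
    term <- lp(cc, s)
    q <- lp_add(q, term)
    r <- lp_sub(r, lp_mul(term, b))
    # the coefficient at the eliminated degree is algebraically zero;
    # drop any roundoff residue so the span strictly decreases
    if (!lp_is_zero(r)) {
      pos <- edge - r$lo + 1L
      if (pos >= 1L && pos <= length(r$c)) {
        r$c[pos] <- 0
        r <- lp_trim(r)
      }
    }
  }
  list(q = q, r = r)
}

# pick the division variant with the least coefficient growth
lp_div_best <- function(a, b) {
  top <- lp_div(a, b, "top")
  bot <- lp_div(a, b, "bottom")
  size <- function(d) max(abs(c(d$q$c, d$r$c, 0)))
  if (size(top) <= size(bot)) top else bot
}

# ---- factorization ----------------------------------------------------

.wn_lift_cache <- new.env(parent = emptyenv())

# Split a filter into its even/odd polyphase parts: f[2j] -> z^j etc.
polyphase_split <- function(f) {
  list(even = lp(f[seq(1, length(f), 2)]),
       odd = lp(f[seq(2, length(f), 2)]))
}

# Lifting steps for one wavelet. Returns list(steps, scale) where each
# step is list(target = "o"|"e", q = laurent poly): target "o" means
# xo <- xo + q(xe) (a predict step), target "e" the mirrored update step.
# scale holds the final diagonal monomials for each channel.
lifting_steps <- function(name) {
  if (!is.null(.wn_lift_cache[[name]])) return(.wn_lift_cache[[name]])
  if (name %in% c("haar", "bior1.1")) {
    # canonical Haar lifting: predict d = odd - even, update a = even + d/2
    r <- 0.70710678118654757
    out <- list(
      steps = list(list(target = "o", q = lp(-1)),
                   list(target = "e", q = lp(0.5))),
      scale = list(a = list(coef = 1 / r, shift = 0L),
                   d = list(coef = r, shift = 0L))
    )
    .wn_lift_cache[[name]] <- out
    return(out)
  }
  flt <- wavelet_filters(name)
  h <- polyphase_split(flt$dec_lo)
  g <- polyphase_split(flt$dec_hi)
  M <- list(list(h$even, h$odd), list(g$even, g$odd))
  ops <- list()
  col_op <- function(M, which, q) {
    # which = "c1": col1 <- col1 - q * col2 ; "c2": col2 <- col2 - q * col1
    if (which == "c1") {
      M[[1]][[1]] <- lp_chop(lp_sub(M[[1]][[1]], lp_mul(q, M[[1]][[2]])))
      M[[2]][[1]] <- lp_chop(lp_sub(M[[2]][[1]], lp_mul(q, M[[2]][[2]])))
    } else {
      M[[1]][[2]] <- lp_chop(lp_sub(M[[1]][[2]], lp_mul(q, M[[1]][[1]])))
      M[[2]][[2]] <- lp_chop(lp_sub(M[[2]][[2]], lp_mul(q, M[[2]][[1]])))
    }
    M
  }
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 200L) stop("lifting factorization did not converge for ", name)
    u <- M[[1]][[1]]
    v <- M[[1]][[2]]
    if (lp_is_zero(v)) break
    if (lp_is_zero(u)) {
      # rotate the monomial into the first slot with two shear steps
      M <- col_op(M, "c1", lp(-1))
      ops <- c(ops, list(list(which = "c1", q = lp(-1))))
      M <- col_op(M, "c2", lp(1))
      ops <- c(ops, list(list(which = "c2", q = lp(1))))
      break
    }
    if (lp_span(u) >= lp_span(v)) {
      q <- lp_div_best(u, v)$q
      M <- col_op(M, "c1", q)
      ops <- c(ops, list(list(which = "c1", q = q)))
    } else {
      q <- lp_div_best(v, u)$q
      M <- col_op(M, "c2", q)
      ops <- c(ops, list(list(which = "c2", q = q)))
    }
  }
  if (!lp_is_zero(M[[1]][[2]]))
    stop("factorization failed to annihilate the polyphase corner for ", name)
  m1 <- M[[1]][[1]]
  if (lp_span(m1) != 0L)
    stop("polyphase gcd is not a monomial for ", name)
  g2 <- M[[2]][[2]]
  if (lp_span(g2) != 0L)
    stop("polyphase determinant is not a monomial for ", name)
  g1 <- M[[2]][[1]]
  if (!lp_is_zero(g1)) {
    q <- lp_scale_mono(g1, 1 / g2$c, -g2$lo)   # exact division by monomial
    M <- col_op(M, "c1", q)
    ops <- c(ops, list(list(which = "c1", q = q)))
  }
  # forward transform applies the inverse column ops in recorded order:
  # "c1" q  => xo <- xo + q(xe);  "c2" q  => xe <- xe + q(xo)
  steps <- lapply(ops, function(op)
    list(target = if (op$which == "c1") "o" else "e", q = op$q))
  out <- list(
    steps = steps,
    scale = list(a = list(coef = m1$c, shift = m1$lo),
                 d = list(coef = g2$c, shift = g2$lo))
  )
  .wn_lift_cache[[name]] <- out
  out
}

# apply Laurent filter q to a periodic sequence: (q u)[n] = sum_j c_j u[n+j]
lp_apply <- function(q, u) {
  if (lp_is_zero(q)) return(numeric(length(u)))
  M <- length(u)
  out <- numeric(M)
  idx0 <- seq_len(M) - 1L
  for (j in seq_along(q$c)) {
    s <- q$lo + j - 1L
    out <- out + q$c[j] * u[((idx0 + s) %% M) + 1L]
  }
  out
}

shift_periodic <- function(u, s) {
  M <- length(u)
  if (s %% M == 0) return(u)
  u[(((seq_len(M) - 1L) + s) %% M) + 1L]
}

# one analysis level by lifting
lift_step_forward <- function(x, name, normalize = TRUE) {
  N <- length(x)
  if (N %% 2L != 0L) stop("signal length must be even")
  fac <- lifting_steps(name)
  xe <- x[seq(1, N, 2)]
  xo <- x[seq(2, N, 2)]
  for (st in fac$steps) {
    if (st$target == "o") xo <- xo + lp_apply(st$q, xe)
    else xe <- xe + lp_apply(st$q, xo)
  }
  if (normalize) {
    xe <- fac$scale$a$coef * shift_periodic(xe, fac$scale$a$shift)
    xo <- fac$scale$d$coef * shift_periodic(xo, fac$scale$d$shift)
  }
  list(a = xe, d = xo)
}

# exact inverse of lift_step_forward
lift_step_inverse <- function(a, d, name, normalize = TRUE) {
  fac <- lifting_steps(name)
  xe <- a
  xo <- d
  if (normalize) {
    xe <- shift_periodic(xe / fac$scale$a$coef, -fac$scale$a$shift)
    xo <- shift_periodic(xo / fac$scale$d$coef, -fac$scale$d$shift)
  }
  for (st in rev(fac$steps)) {
    if (st$target == "o") xo <- xo - lp_apply(st$q, xe)
    else xe <- xe - lp_apply(st$q, xo)
  }
  x <- numeric(2L * length(xe))
  x[seq(1, length(x), 2)] <- xe
  x[seq(2, length(x), 2)] <- xo
  x
}
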