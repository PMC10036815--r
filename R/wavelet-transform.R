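# Multi-level 1-D wavelet transforms: lifting implementation (LWT) and
# the classical filter-bank implementation (WT), sharing one periodic
# boundary convention so the two produce identical subbands.

# one analysis level by periodic filter-bank convolution
fb_step_forward <- function(x, name) {
  N <- length(x)
  if (N %% 2L != 0L) stop("signal length must be even")
  flt <- wavelet_filters(name)
  n2 <- N %/% 2L
  base <- 2L * (seq_len(n2) - 1L)
  a <- numeric(n2)
  d <- numeric(n2)
  for (k in seq_along(flt$dec_lo)) {
    idx <- ((base + k - 1L) %% N) + 1L
    a <- a + flt$dec_lo[k] * x[idx]
    d <- d + flt$dec_hi[k] * x[idx]
  }
  list(a = a, d = d)
}

fb_step_inverse <- function(a, d, name) {
  flt <- wavelet_filters(name)
  rl <- rev(flt$rec_lo)
  rh <- rev(flt$rec_hi)
  N <- 2L * length(a)
  x <- numeric(N)
  base <- 2L * (seq_along(a) - 1L)
  for (k in seq_along(rl)) {
    idx <- ((base + k - 1L) %% N) + 1L
    x[idx] <- x[idx] + a * rl[k] + d * rh[k]
  }
  x
}

# symmetric-reflection padding to a multiple of 2^level
pad_signal <- function(x, level) {
  N0 <- length(x)
  if (N0 < 2^level)
    stop("signal length ", N0, " too short for decomposition level ", level)
  N <- as.integer(ceiling(N0 / 2^level) * 2^level)
  if (N > N0) x <- c(x, rev(x)[seq_len(N - N0)])
  list(x = x, n_orig = N0)
}

wt_analyze <- function(x, name, level, method = c("lifting", "filterbank"),
                       normalize = TRUE) {
  method <- match.arg(method)
  details <- vector("list", level)
  a <- x
  for (j in seq_len(level)) {
    st <- if (method == "lifting") lift_step_forward(a, name, normalize)
          else fb_step_forward(a, name)
    details[[j]] <- st$d
    a <- st$a
  }
  list(approx = a, details = details, level = level, name = name,
       method = method, normalize = normalize)
}

wt_synthesize <- function(pyr) {
  a <- pyr$approx
  for (j in rev(seq_len(pyr$level))) {
    a <- if (pyr$method == "lifting")
      lift_step_inverse(a, pyr$details[[j]], pyr$name, pyr$normalize)
    else fb_step_inverse(a, pyr$details[[j]], pyr$name)
  }
  a
}

#' Forward lifting wavelet transform
#'
#' Decomposes a signal to `spec$level` levels via the lifting scheme:
#' each level splits the signal into even and odd samples, applies the
#' wavelet's predict/update lifting steps, and (when `normalize = TRUE`)
#' the final diagonal scaling that makes the subbands agree with the
#' classical filter-bank transform. Boundaries are handled periodically;
#' the signal length must be divisible by `2^level` (see [lwt_denoise()]
#' for the padded variant).
#'
#' @param x numeric signal.
#' @param spec a [wavelet_spec()] (or registered wavelet name; then
#'   `level` must be given).
#' @param level decomposition depth, defaulting to `spec$level`.
#' @param normalize apply the final scaling step. With `normalize = FALSE`
#'   the Haar transform returns the classic unnormalized lifting output
#'   (details = odd - even, approximations = pairwise means).
#' @return A coefficient pyramid: list with `approx`, `details` (finest
#'   first) and bookkeeping fields, invertible by [lwt_inverse()].
#' @examples
#' p <- lwt_forward(c(4, 2, 6, 8), "haar", level = 1, normalize = FALSE)
#' p$details[[1]] # -2 2
#' p$approx       # 3 7
#' @export
lwt_forward <- function(x, spec, level = NULL, normalize = TRUE) {
  name <- resolve_wavelet_name(spec)
  level <- level %||% (if (inherits(spec, "wavelet_spec")) spec$level else
    stop("level required when spec is a name"))
  if (length(x) %% 2^level != 0L)
    stop("signal length must be divisible by 2^level; pad first")
  wt_analyze(x, name, level, method = "lifting", normalize = normalize)
}

#' Inverse lifting wavelet transform
#'
#' Exactly undoes [lwt_forward()] by running the lifting steps in reverse.
#'
#' @param pyramid output of [lwt_forward()].
#' @return The reconstructed signal.
#' @export
lwt_inverse <- function(pyramid) wt_synthesize(pyramid)

#' Forward classical (filter-bank) wavelet transform
#'
#' Same subband decomposition as [lwt_forward()] computed by periodic
#' convolution with the analysis filters and dyadic downsampling.
#'
#' @inheritParams lwt_forward
#' @return A coefficient pyramid invertible by [dwt_inverse()].
#' @export
dwt_forward <- function(x, spec, level = NULL) {
  name <- resolve_wavelet_name(spec)
  level <- level %||% (if (inherits(spec, "wavelet_spec")) spec$level else
    stop("level required when spec is a name"))
  if (length(x) %% 2^level != 0L)
    stop("signal length must be divisible by 2^level; pad first")
  wt_analyze(x, name, level, method = "filterbank")
}

#' Inverse classical wavelet transform
#'
#' @param pyramid output of [dwt_forward()].
#' @return The reconstructed signal.
#' @export
dwt_inverse <- function(pyramid) wt_synthesize(pyramid)
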