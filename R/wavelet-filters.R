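# Filter banks for the registered wavelet families.
#
# Coefficients are the standard published values (Daubechies extremal-phase,
# least-asymmetric/symlet, and spline-biorthogonal 1.x families), stored to
# full double precision. Orientation: `dec_lo` is the analysis lowpass used
# as a correlation filter, a[n] = sum_k dec_lo[k] x[2n + k]. The highpass
# and reconstruction filters are derived by the usual quadrature relations
# (see `wavelet_filters()`).

.wn_dec_lo <- list(
  haar = c(0.70710678118654757, 0.70710678118654757),
  db2 = c(-0.12940952255126037, 0.22414386804201339,
          0.83651630373780794, 0.48296291314453416),
  db3 = c(0.035226291885709533, -0.085441273882026658, -0.13501102001025458,
          0.45987750211849154, 0.80689150931109255, 0.33267055295008263),
  db4 = c(-0.010597401785069032, 0.032883011666885197, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.63088076792985892,
          0.71484657055291567, 0.23037781330889651),
  db5 = c(0.0033357252854737712, -0.012580751999081999, -0.0062414902127982744,
          0.077571493840045719, -0.032244869584638375, -0.24229488706638203,
          0.13842814590132074, 0.72430852843777294, 0.60382926979718965,
          0.16010239797419293),
  db6 = c(-0.0010773010853084796, 0.0047772575109455108, 0.00055384220116149613,
          -0.03158203931748603, 0.027522865530305727, 0.097501605587323043,
          -0.12976686756726194, -0.22626469396543983, 0.31525035170919763,
          0.75113390802109536, 0.49462389039845306, 0.11154074335010947),
  db7 = c(0.00035371379997452024, -0.0018016407040474908, 0.00042957797292136651,
          0.01255099855609984, -0.016574541630666881, -0.038029936935014413,
          0.080612609151083078, 0.071309219266830259, -0.22403618499387498,
          -0.14390600392856498, 0.46978228740519312, 0.72913209084623509,
          0.39653931948191729, 0.077852054085009184),
  db8 = c(-0.00011747678412476953, 0.00067544940645056933, -0.00039174037337694705,
          -0.0048703529934515741, 0.0087460940474057766, 0.013981027917398282,
          -0.044088253930794755, -0.017369301001807547, 0.12874742662047847,
          0.00047248457391328279, -0.28401554296154691, -0.015829105256349306,
          0.58535468365420673, 0.67563073629728976, 0.31287159091429995,
          0.054415842243104008),
  sym2 = c(-0.12940952255092145, 0.22414386804185735,
           0.83651630373746899, 0.48296291314469025),
  sym3 = c(0.035226291882100656, -0.085441273882241486, -0.13501102001039084,
           0.45987750211933132, 0.80689150931333875, 0.33267055295095688),
  sym4 = c(-0.075765714789273325, -0.02963552764599851, 0.49761866763201545,
           0.80373875180591614, 0.29785779560527736, -0.099219543576847216,
           -0.012603967262037833, 0.032223100604042702),
  sym5 = c(0.027333068345077982, 0.029519490925774643, -0.039134249302383094,
           0.1993975339773936, 0.72340769040242059, 0.63397896345821192,
           0.016602105764522319, -0.17532808990845047, -0.021101834024758855,
           0.019538882735286728),
  sym6 = c(0.015404109327027373, 0.0034907120842174702, -0.11799011114819057,
           -0.048311742585632998, 0.49105594192674662, 0.787641141030194,
           0.3379294217276218, -0.072637522786462516, -0.021060292512300564,
           0.044724901770665779, 0.0017677118642428036, -0.007800708325034148),
  sym7 = c(0.0026818145682578781, -0.0010473848886829163, -0.01263630340325193,
           0.03051551316596357, 0.067892693501372697, -0.049552834937127255,
           0.017441255086855827, 0.5361019170917628, 0.76776431700316405,
           0.28862963175151463, -0.14004724044296152, -0.10780823770381774,
           0.0040102448715336634, 0.010268176708511255),
  sym8 = c(-0.0033824159510061256, -0.00054213233179114812, 0.031695087811492981,
           0.0076074873249176054, -0.14329423835080971, -0.061273359067658524,
           0.48135965125837221, 0.77718575170052351, 0.3644418948353314,
           -0.051945838107709037, -0.027219029917056003, 0.049137179673607506,
           0.0038087520138906151, -0.014952258337048231, -0.0003029205147213668,
           0.0018899503327594609),
  bior1.1 = c(0.70710678118654757, 0.70710678118654757),
  bior1.3 = c(-0.088388347648318447, 0.088388347648318447, 0.70710678118654757,
              0.70710678118654757, 0.088388347648318447, -0.088388347648318447),
  bior1.5 = c(0.016572815184059706, -0.016572815184059706, -0.12153397801643785,
              0.12153397801643785, 0.70710678118654757, 0.70710678118654757,
              0.12153397801643785, -0.12153397801643785, -0.016572815184059706,
              0.016572815184059706)
)

# reconstruction lowpass for the biorthogonal pairs (zero-padded to the
# analysis length so all four filters share one index range)
.wn_rec_lo_bior <- list(
  bior1.1 = c(0.70710678118654757, 0.70710678118654757),
  bior1.3 = c(0, 0, 0.70710678118654757, 0.70710678118654757, 0, 0),
  bior1.5 = c(0, 0, 0, 0, 0.70710678118654757, 0.70710678118654757,
              0, 0, 0, 0)
)

#' Names of the registered wavelets
#'
#' @return Character vector of wavelet names accepted by [wavelet_spec()]
#'   and the transform functions: `haar`, `db2`..`db8`, `sym2`..`sym8`,
#'   `bior1.1`, `bior1.3`, `bior1.5`.
#' @export
registered_wavelets <- function() names(.wn_dec_lo)

#' Analysis/synthesis filter bank of a registered wavelet
#'
#' For orthogonal families the highpass is the quadrature mirror of the
#' lowpass, `dec_hi[k] = (-1)^(k+1) dec_lo[L-1-k]`, and reconstruction
#' filters are the time-reversed analysis filters. For the biorthogonal
#' 1.x family the analysis and reconstruction lowpass differ and the
#' highpass filters are derived from the opposite branch's lowpass.
#'
#' @param name a wavelet name from [registered_wavelets()].
#' @return List with elements `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi`,
#'   `orthogonal`.
#' @export
wavelet_filters <- function(name) {
  dec_lo <- .wn_dec_lo[[name]]
  if (is.null(dec_lo)) stop("unregistered wavelet: ", name)
  L <- length(dec_lo)
  k <- seq_len(L) - 1L
  if (startsWith(name, "bior")) {
    rec_lo <- .wn_rec_lo_bior[[name]]
    dec_hi <- (-1)^(k + 1) * rev(rec_lo)
    rec_hi <- (-1)^k * rev(dec_lo)
    orth <- FALSE
  } else {
    dec_hi <- (-1)^(k + 1) * rev(dec_lo)
    rec_lo <- rev(dec_lo)
    rec_hi <- rev(dec_hi)
    orth <- TRUE
  }
  list(dec_lo = dec_lo, dec_hi = dec_hi,
       rec_lo = rec_lo, rec_hi = rec_hi, orthogonal = orth)
}

#' Specify a wavelet denoising configuration
#'
#' @param family `"haar"`, `"db"`, `"sym"` or `"bior"`.
#' @param order vanishing-moment order (ignored for `haar`; for `bior` the
#'   reconstruction order Nd of the bior1.Nd pair, one of 1, 3, 5).
#' @param level decomposition depth k, 1..8.
#' @param threshold_rule `"soft"` (default) or `"hard"`.
#' @param threshold_scale multiplier on the per-level universal threshold;
#'   0 disables thresholding entirely.
#' @return An object of class `wavelet_spec`.
#' @examples
#' wavelet_spec("db", 3, level = 8)
#' @export
wavelet_spec <- function(family = c("haar", "db", "sym", "bior"),
                         order = 3L, level = 8L,
                         threshold_rule = c("soft", "hard"),
                         threshold_scale = 1) {
  family <- match.arg(family)
  threshold_rule <- match.arg(threshold_rule)
  level <- as.integer(level)
  if (level < 1L || level > 8L) stop("level must be in 1..8")
  if (threshold_scale < 0) stop("threshold_scale must be >= 0")
  name <- switch(family,
    haar = "haar",
    db = paste0("db", order),
    sym = paste0("sym", order),
    bior = paste0("bior1.", order)
  )
  if (!name %in% registered_wavelets())
    stop("unregistered wavelet: ", name)
  structure(
    list(family = family, order = as.integer(order), level = level,
         name = name, threshold_rule = threshold_rule,
         threshold_scale = threshold_scale),
    class = "wavelet_spec"
  )
}

#' @export
print.wavelet_spec <- function(x, ...) {
  cat(sprintf("<wavelet_spec> %s, level %d, %s threshold (scale %.3g)\n",
              x$name, x$level, x$threshold_rule, x$threshold_scale))
  invisible(x)
}

# Accept either a wavelet_spec or a plain name string.
resolve_wavelet_name <- function(spec) {
  if (inherits(spec, "wavelet_spec")) return(spec$name)
  if (is.character(spec) && spec %in% registered_wavelets()) return(spec)
  stop("expected a wavelet_spec or registered wavelet name")
}
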