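# Two-component Frechet mixture model of intron length.
#
# Intron length histograms are typically bimodal: a tight population of
# short introns and a heavy right tail of long ones. Both populations are
# modelled with three-parameter Frechet (inverse Weibull) laws; the mixture
# density, discretised to unit intervals and renormalised on
# [L_min, L_max), yields the per-intron length information score
# log2(f(l) / c) against the uniform background c = 1 / (L_max - L_min).

#' The Frechet distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the three-parameter Frechet law with shape `shape` (alpha > 0), scale
#' `scale` (sigma > 0) and location `loc` (m); support is `x > loc`.
#'
#' @param x,q,p,n usual distribution-function arguments.
#' @param shape,scale,loc parameters.
#' @return numeric vector.
#' @name frechet
NULL

#' @rdname frechet
#' @export
dfrechet <- function(x, shape, scale, loc = 0) {
  z <- (x - loc) / scale
  out <- numeric(length(z))
  pos <- !is.na(z) & z > 0
  zp <- z[pos]
  out[pos] <- (shape / scale) * zp^(-1 - shape) * exp(-zp^(-shape))
  out
}

#' @rdname frechet
#' @export
pfrechet <- function(q, shape, scale, loc = 0) {
  z <- (q - loc) / scale
  out <- numeric(length(z))
  pos <- !is.na(z) & z > 0
  out[pos] <- exp(-z[pos]^(-shape))
  out
}

#' @rdname frechet
#' @export
qfrechet <- function(p, shape, scale, loc = 0) {
  loc + scale * (-log(p))^(-1 / shape)
}

#' @rdname frechet
#' @export
rfrechet <- function(n, shape, scale, loc = 0) {
  qfrechet(stats::runif(n), shape, scale, loc)
}

#' Construct an intron length model from mixture parameters
#'
#' Components are ordered so that component 1 is the *short* one (smaller
#' median). `L_max`, unless supplied, is the 99% quantile of the longer
#' component; the discrete density is the mixture CDF increment on each
#' unit interval, renormalised over `[L_min, L_max)`.
#'
#' @param shape,scale,loc length-2 numeric vectors of component parameters.
#' @param weight mixture weight of component 1 (the short component).
#' @param L_min minimal intron length considered (default 30).
#' @param L_max optional upper bound; default the 99% quantile of the long
#'   component.
#' @return object of class `length_model` with the discrete density table
#'   `density` over lengths `L_min .. L_max - 1`, background `c`, and the
#'   component parameters.
#' @export
length_model <- function(shape, scale, loc, weight, L_min = 30L, L_max = NULL) {
  stopifnot(length(shape) == 2L, length(scale) == 2L, length(loc) == 2L)
  if (weight < 0 || weight > 1) stop("'weight' must lie in [0, 1]")
  if (any(shape <= 0) || any(scale <= 0) || any(loc < 0))
    stop("invalid Frechet parameters")
  med <- qfrechet(0.5, shape, scale, loc)
  if (med[1] > med[2]) {  # reorder: component 1 = short
    shape <- rev(shape); scale <- rev(scale); loc <- rev(loc)
    weight <- 1 - weight
  }
  if (is.null(L_max))
    L_max <- ceiling(qfrechet(0.99, shape[2], scale[2], loc[2]))
  L_max <- as.integer(L_max)
  L_min <- as.integer(L_min)
  if (L_max <= L_min + 1L) stop("'L_max' must exceed 'L_min' + 1")
  lens <- seq.int(L_min, L_max - 1L)
  cdf <- function(x) weight  * pfrechet(x, shape[1], scale[1], loc[1]) +
    (1 - weight) * pfrechet(x, shape[2], scale[2], loc[2])
  mass <- cdf(lens + 1) - cdf(lens)
  tot <- sum(mass)
  if (tot <= 0) stop("length density vanishes on [L_min, L_max)")
  dens <- mass / tot
  names(dens) <- lens
  structure(
    list(shape = shape, scale = scale, loc = loc, weight = weight,
         L_min = L_min, L_max = L_max, density = dens,
         c = 1 / (L_max - L_min)),
    class = "length_model")
}

#' Length model from an explicit discrete density
#'
#' Mainly for closed-form tests and for non-parametric length tables.
#'
#' @param density numeric vector of masses for lengths `L_min`, `L_min+1`,
#'   ...; normalised internally.
#' @param L_min first length of the table.
#' @return a `length_model` without component parameters.
#' @export
length_model_from_density <- function(density, L_min = 30L) {
  density <- density / sum(density)
  L_min <- as.integer(L_min)
  L_max <- L_min + length(density)
  names(density) <- seq.int(L_min, L_max - 1L)
  structure(list(shape = NULL, scale = NULL, loc = NULL, weight = NULL,
                 L_min = L_min, L_max = L_max, density = density,
                 c = 1 / (L_max - L_min)),
            class = "length_model")
}

#' @export
print.length_model <- function(x, ...) {
  cat(sprintf("length_model on [%d, %d)\n", x$L_min, x$L_max))
  if (!is.null(x$shape))
    cat(sprintf("  short: alpha=%.3g sigma=%.3g m=%.3g (w=%.3f)\n  long : alpha=%.3g sigma=%.3g m=%.3g\n",
                x$shape[1], x$scale[1], x$loc[1], x$weight,
                x$shape[2], x$scale[2], x$loc[2]))
  invisible(x)
}

# mixture log-likelihood of tabulated integer lengths under discretised
# (unit-interval) component masses; used by the fitter
.lm_negll <- function(theta, lens, cnts) {
  w  <- stats::plogis(theta[1])
  a  <- exp(theta[c(2, 5)]); s <- exp(theta[c(3, 6)]); m <- exp(theta[c(4, 7)])
  m1 <- w  * (pfrechet(lens + 1, a[1], s[1], m[1]) - pfrechet(lens, a[1], s[1], m[1]))
  m2 <- (1 - w) * (pfrechet(lens + 1, a[2], s[2], m[2]) - pfrechet(lens, a[2], s[2], m[2]))
  p <- m1 + m2
  if (any(p <= 0)) return(1e12)
  -sum(cnts * log(p))
}

#' Fit a two-component Frechet mixture to intron lengths
#'
#' Direct numerical maximum likelihood on the discretised mixture (unit
#' intervals), with several quantile-split initialisations plus jittered
#' restarts; the best converged optimum is kept.
#'
#' @param lengths integer vector of intron lengths (all > 30 expected).
#' @param L_min lower support bound for the resulting model (default 30).
#' @param n_restarts number of jittered restarts per initialisation.
#' @param max_iter Nelder-Mead iteration cap per start.
#' @return a [length_model()]; attribute `logLik` holds the attained
#'   log-likelihood.
#' @export
fit_length_model <- function(lengths, L_min = 30L, n_restarts = 3L,
                             max_iter = 2000L) {
  lengths <- as.numeric(lengths)
  if (length(lengths) < 200L)
    warning("fewer than 200 lengths; mixture fit may be unstable")
  if (stats::var(lengths) == 0)
    stop("degenerate input: all lengths identical")
  tab <- table(lengths)
  lens <- as.numeric(names(tab))
  cnts <- as.numeric(tab)

  # restart jitters come from a private, fixed RNG stream so the fit is a
  # deterministic function of the data; the caller's RNG state is restored
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(20731L)

  inits <- list()
  for (qs in c(0.5, 0.65, 0.8)) {
    cut <- stats::quantile(lengths, qs)
    lo <- lengths[lengths <= cut]; hi <- lengths[lengths > cut]
    if (length(lo) < 10 || length(hi) < 10) next
    mk <- function(x) {
      m0 <- max(0.5, min(x) - 2)
      s0 <- max(1, stats::median(x) - m0)
      c(log(2), log(s0), log(m0))
    }
    inits[[length(inits) + 1L]] <-
      c(stats::qlogis(length(lo) / length(lengths)), mk(lo), mk(hi))
  }
  # single-population style init: both components span the whole sample
  m0 <- max(0.5, min(lengths) - 2)
  s0 <- max(1, stats::median(lengths) - m0)
  inits[[length(inits) + 1L]] <-
    c(0, log(2), log(s0), log(m0), log(2), log(4 * s0), log(m0))

  best <- NULL
  for (ini in inits) {
    for (r in seq_len(n_restarts)) {
      th0 <- if (r == 1L) ini else ini + stats::rnorm(7, 0, 0.3)
      fit <- try(stats::optim(th0, .lm_negll, lens = lens, cnts = cnts,
                              method = "Nelder-Mead",
                              control = list(maxit = max_iter)),
                 silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  }
  if (is.null(best) || best$value >= 1e12)
    stop("Frechet mixture fit failed to converge; supply more data or inspect the length distribution")
  polish <- try(stats::optim(best$par, .lm_negll, lens = lens, cnts = cnts,
                             method = "BFGS",
                             control = list(maxit = 500)), silent = TRUE)
  if (!inherits(polish, "try-error") && polish$value < best$value)
    best <- polish
  th <- best$par
  model <- length_model(shape = exp(th[c(2, 5)]), scale = exp(th[c(3, 6)]),
                        loc = exp(th[c(4, 7)]),
                        weight = stats::plogis(th[1]), L_min = L_min)
  attr(model, "logLik") <- -best$value
  model
}

#' Length information score
#'
#' `log2(f(l) / c)` where `f` is the model's discrete density and `c` the
#' uniform background on `[L_min, L_max)`. Lengths outside the range get
#' the most penalised in-range score and are flagged in the
#' `"out_of_range"` attribute.
#'
#' @param l integer vector of lengths.
#' @param model a [length_model()].
#' @return numeric vector of scores in bits.
#' @export
length_score <- function(l, model) {
  stopifnot(inherits(model, "length_model"))
  dens <- model$density
  floorv <- log2(max(min(dens), 1e-300) / model$c)
  idx <- l - model$L_min + 1L
  ok <- idx >= 1L & idx <= length(dens)
  out <- rep(floorv, length(l))
  out[ok] <- log2(pmax(dens[idx[ok]], 1e-300) / model$c)
  attr(out, "out_of_range") <- !ok
  out
}

#' Short-intron length threshold across species
#'
#' Averages the fitted *short* components of several species' length models
#' (equal species weights, via the average of the component CDFs) and
#' returns the requested quantile of that average distribution. The
#' conventional pipeline default rounds this to a fixed cutoff.
#'
#' @param models list of [length_model()] objects (parametric fits).
#' @param p quantile, default 0.95.
#' @return numeric threshold length in nucleotides.
#' @export
short_intron_threshold <- function(models, p = 0.95) {
  if (!length(models)) stop("no models supplied")
  if (inherits(models, "length_model")) models <- list(models)
  for (m in models)
    if (is.null(m$shape)) stop("all models must carry Frechet components")
  avg_cdf <- function(x) {
    mean(vapply(models, function(m)
      pfrechet(x, m$shape[1], m$scale[1], m$loc[1]), numeric(1)))
  }
  hi <- max(vapply(models, function(m)
    qfrechet(0.999, m$shape[1], m$scale[1], m$loc[1]), numeric(1)))
  lo <- min(vapply(models, function(m) m$loc[1], numeric(1)))
  stats::uniroot(function(x) avg_cdf(x) - p, lower = lo + 1e-9, upper = hi,
                 tol = 1e-9, extendInt = "upX")$root
}
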