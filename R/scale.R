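#' Power-transform scale model
#'
#' Represents the monotone scale relating additive phenotypes to observed
#' phenotypes:
#' \deqn{\tau(p) = a \frac{(p+A)^\lambda - 1}{\lambda\, GM^{\lambda-1}} + B,}
#' where `A` and `B` are translation constants, `GM` is the geometric mean of
#' the shifted additive phenotypes `p + A`, `lambda` is the shape parameter
#' and `a` is the curve amplitude. With `amplitude = 1` this is the classic
#' geometric-mean-normalized Box-Cox form, whose derivative
#' `((p+A)/GM)^(lambda-1)` has geometric mean 1 over the data: the curve can
#' bend but not change overall gain. Fitting (see [fit_power_transform()])
#' estimates the amplitude as well, as Box-Cox regression does through its
#' freely-scaled linear predictor. At `lambda -> 0` the transform passes
#' continuously to the log limit `a * GM * log(p+A) + B`.
#'
#' @param lambda shape parameter (dimensionless)
#' @param A,B translation constants (phenotype units)
#' @param GM geometric mean of the shifted additive phenotypes; 1 for a
#'   hand-specified curve
#' @param amplitude curve gain; 1 reproduces the normalized Box-Cox form
#' @return a `power_transform` object
#' @export
power_transform <- function(lambda, A, B, GM = 1, amplitude = 1) {
  stopifnot(is.finite(lambda), is.finite(A), is.finite(B), GM > 0,
            is.finite(amplitude), amplitude != 0)
  structure(list(lambda = lambda, A = A, B = B, GM = GM,
                 amplitude = amplitude),
            class = "power_transform")
}

#' @export
print.power_transform <- function(x, ...) {
  cat(sprintf(
    "Power transform: lambda = %.4g, A = %.4g, B = %.4g, GM = %.4g, amplitude = %.4g\n",
    x$lambda, x$A, x$B, x$GM, x$amplitude))
  if (!is.null(x$objective))
    cat(sprintf("  fit: SSQ = %.4g over %d points, R^2 = %.4f%s\n",
                x$objective, x$n, x$r2,
                if (isTRUE(x$fallback)) " (lambda >= 0 fallback fit)" else ""))
  invisible(x)
}

LAMBDA_LOG_EPS <- 1e-5

# core curve without amplitude/offset
pt_core <- function(p, lambda, A, GM) {
  if (abs(lambda) < LAMBDA_LOG_EPS) GM * log(p + A)
  else ((p + A)^lambda - 1) / (lambda * GM^(lambda - 1))
}

#' Apply a power-transform scale to additive-scale phenotypes
#'
#' @param p numeric phenotypes on the additive (linear) scale; `p + A` must
#'   be positive
#' @param pt a [power_transform]
#' @return numeric transformed phenotypes on the observed scale
#' @export
transform_phenotypes <- function(p, pt) {
  stopifnot(inherits(pt, "power_transform"))
  if (any(p + pt$A <= 0))
    stop("domain error: p + A must be positive (violated for ",
         sum(p + pt$A <= 0), " value(s))", call. = FALSE)
  pt$amplitude * pt_core(p, pt$lambda, pt$A, pt$GM) + pt$B
}

#' Back-transform observed phenotypes onto the additive (linear) scale
#'
#' Exact functional inverse of [transform_phenotypes()]:
#' \deqn{p = [\lambda\,GM^{\lambda-1}(p_{obs}-B)/a + 1]^{1/\lambda} - A.}
#' The bracketed quantity must be positive for every phenotype; values for
#' which it is not lie outside the representable range of the fitted scale.
#'
#' @param p_obs numeric observed phenotypes
#' @param pt a [power_transform]
#' @param clip if `TRUE`, non-positive brackets are floored at zero (the
#'   affected phenotypes map to the boundary value `-A`) instead of raising
#'   an error; used by the pipeline so a handful of extreme genotypes cannot
#'   abort an analysis
#' @return numeric linearized phenotypes
#' @export
linearize <- function(p_obs, pt, clip = FALSE) {
  stopifnot(inherits(pt, "power_transform"))
  y <- (p_obs - pt$B) / pt$amplitude
  if (abs(pt$lambda) < LAMBDA_LOG_EPS) return(exp(y / pt$GM) - pt$A)
  br <- pt$lambda * pt$GM^(pt$lambda - 1) * y + 1
  if (any(br <= 0)) {
    if (!clip)
      stop("phenotype(s) outside the representable range of the fitted scale",
           " at position(s): ",
           paste(which(br <= 0), collapse = ", "), call. = FALSE)
    br <- pmax(br, 0)
  }
  br^(1 / pt$lambda) - pt$A
}

#' Fit the power-transform scale by nonlinear least squares
#'
#' Estimates `(lambda, A, B)` (and, by default, the curve amplitude)
#' minimizing the sum of squared differences between `tau(p_add)` and
#' `p_obs`. `GM` is recomputed from `p_add + A` inside the objective, and
#' `A` is bounded so every `p_add + A` stays positive. Amplitude and `B`
#' enter the model linearly and are profiled out exactly; the remaining
#' two-dimensional `(lambda, A)` surface is searched by a coarse grid
#' followed by Nelder-Mead polish. Two safeguards keep the fitted scale
#' invertible over the data: curves whose finite asymptote falls within
#' `margin` x range of the observed phenotypes are penalized, and if the
#' back-transform still maps observations beyond three times the additive
#' range the fit is redone with `lambda >= 0` (for which the inverse is
#' bounded below and the log branch is invertible everywhere).
#'
#' @param p_add numeric additive-scale predictions (from [fit_additive()])
#' @param p_obs numeric observed phenotypes, aligned with `p_add`
#' @param lambda_range numeric length-2 search interval for `lambda`
#' @param margin invertibility margin, as a fraction of the observed
#'   phenotype range
#' @param amplitude estimate the curve gain (`TRUE`, default) or pin it at 1
#'   (the strictly geometric-mean-normalized form)
#' @param start optional `c(lambda, A)` warm start; skips the grid search
#'   (used by the bootstrap to refit from the point estimate)
#' @return a [power_transform] with fit annotations: `objective` (residual
#'   sum of squares), `residuals`, `fitted`, `r2` (squared Pearson
#'   correlation of fitted vs observed), `n`, `fallback` (whether the
#'   `lambda >= 0` guard fired) and `curved` (whether the nonlinear curve
#'   was preferred over the affine baseline)
#' @export
fit_power_transform <- function(p_add, p_obs, lambda_range = c(-4, 4),
                                margin = 0.05, amplitude = TRUE,
                                start = NULL) {
  stopifnot(length(p_add) == length(p_obs))
  n <- length(p_add)
  if (n < 4)
    stop("at least 4 points are needed to fit (lambda, A, B)", call. = FALSE)
  # identifiability guard: a (near-)constant additive predictor carries no
  # scale information, so the identity transform is returned
  if (stats::sd(p_add) <= 1e-8 * max(stats::sd(p_obs), 1e-300)) {
    A <- -min(p_add) + max(abs(p_add), 1) + 1
    pt <- power_transform(1, A, 1 - A, GM = 1, amplitude = 1)
    pt$fitted <- transform_phenotypes(p_add, pt)
    pt$residuals <- p_obs - pt$fitted
    pt$objective <- sum(pt$residuals^2)
    pt$n <- n
    pt$r2 <- 0
    pt$fallback <- FALSE
    pt$curved <- FALSE
    return(pt)
  }
  # a straight line that already fits to machine precision needs no curve
  # (identity data, affinely re-scaled linear maps)
  aff0 <- stats::.lm.fit(cbind(1, p_add), p_obs)
  if (sum(aff0$residuals^2) <= 1e-20 * max(sum(p_obs^2), 1e-300))
    return(affine_pt(p_add, p_obs))
  fit <- pt_fit_once(p_add, p_obs, lambda_range, margin, amplitude, start)
  plin <- linearize(p_obs, fit, clip = TRUE)
  if (any(!is.finite(plin)) ||
      diff(range(plin)) > 3 * diff(range(p_add))) {
    fit2 <- pt_fit_once(p_add, p_obs, c(0, max(lambda_range[2], 0)), margin,
                        amplitude, start = NULL)
    fit2$fallback <- TRUE
    fit <- fit2
    plin <- linearize(p_obs, fit, clip = TRUE)
    if (any(!is.finite(plin)) ||
        diff(range(plin)) > 1e3 * diff(range(p_add)))
      return(affine_pt(p_add, p_obs))
  }
  fit$curved <- TRUE
  fit
}

# affine member of the family (lambda = 1), used when no curvature is
# supported or when even the guarded fits cannot be inverted sanely
affine_pt <- function(p_add, p_obs) {
  af <- stats::.lm.fit(cbind(1, p_add), p_obs)
  slope <- af$coefficients[2]
  if (!is.finite(slope) || slope == 0) slope <- 1
  A <- -min(p_add) + max(diff(range(p_add)), 1) + 1
  pt <- power_transform(1, A, af$coefficients[1] + slope * (1 - A),
                        GM = 1, amplitude = slope)
  pt$fitted <- transform_phenotypes(p_add, pt)
  pt$residuals <- p_obs - pt$fitted
  pt$objective <- sum(pt$residuals^2)
  pt$n <- length(p_obs)
  pt$r2 <- if (stats::var(pt$fitted) > 0 && stats::var(p_obs) > 0)
    stats::cor(pt$fitted, p_obs)^2 else 1
  pt$fallback <- FALSE
  pt$curved <- FALSE
  pt
}

pt_fit_once <- function(p_add, p_obs, lambda_range, margin, amplitude,
                        start) {
  rng <- diff(range(p_add))
  if (rng == 0) rng <- max(abs(p_add), 1)
  orng <- diff(range(p_obs))
  if (orng == 0) orng <- max(abs(p_obs), 1)
  Amin <- -min(p_add) + 1e-6 * rng

  eval_pt <- function(lambda, A) {
    if (!is.finite(lambda) || !is.finite(A) || A < Amin) return(NULL)
    GM <- exp(mean(log(p_add + A)))
    t0 <- pt_core(p_add, lambda, A, GM)
    if (any(!is.finite(t0))) return(NULL)
    if (amplitude) {
      lf <- stats::.lm.fit(cbind(1, t0), p_obs)
      B <- lf$coefficients[1]; amp <- lf$coefficients[2]
      res <- lf$residuals
    } else {
      B <- mean(p_obs - t0); amp <- 1
      res <- t0 + B - p_obs
    }
    if (!is.finite(amp) || amp == 0) return(NULL)
    v <- sum(res^2)
    # invertibility margin: the curve's finite asymptote (bracket zero) must
    # clear the observed phenotypes
    if (abs(lambda) >= LAMBDA_LOG_EPS) {
      cc <- lambda * GM^(lambda - 1) / amp
      ystar <- B - 1 / cc
      viol <- if (cc < 0) max(p_obs) + margin * orng - ystar
              else ystar - (min(p_obs) - margin * orng)
      if (viol > 0) v <- v + 1e4 * orng^2 * (viol / orng)^2 + 1e-2 * orng^2
    }
    if (!is.finite(v)) return(NULL)
    list(v = v, lambda = lambda, A = A, B = B, amp = amp, GM = GM)
  }
  obj <- function(par) {
    e <- eval_pt(par[1], par[2])
    if (is.null(e)) 1e10 * orng^2 else e$v
  }

  if (is.null(start)) {
    lams <- seq(lambda_range[1], lambda_range[2], by = 0.1)
    As <- Amin + rng * 10^seq(-3, 2, by = 0.2)
    best_v <- Inf; best_par <- c(1, Amin + rng)
    for (l in lams) for (a in As) {
      e <- eval_pt(l, a)
      if (!is.null(e) && e$v < best_v) { best_v <- e$v; best_par <- c(l, a) }
    }
    if (!is.finite(best_v))
      stop("power-transform fit failed: objective not finite anywhere on the",
           " search grid", call. = FALSE)
  } else {
    best_par <- c(start[1], max(start[2], Amin))
  }
  opt <- stats::optim(best_par, obj, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-13))
  # restart the simplex at the optimum once; Nelder-Mead stalls otherwise
  opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-13))
  # the grid bounds only seed the search; the polish may settle outside
  lambda <- opt$par[1]
  if (lambda_range[1] >= 0) lambda <- max(lambda, 0)
  e <- eval_pt(lambda, max(opt$par[2], Amin))
  if (is.null(e)) e <- eval_pt(best_par[1], best_par[2])
  pt <- power_transform(e$lambda, e$A, e$B, e$GM, e$amp)
  pt$fitted <- transform_phenotypes(p_add, pt)
  pt$residuals <- p_obs - pt$fitted
  pt$objective <- sum(pt$residuals^2)
  pt$n <- length(p_obs)
  pt$r2 <- if (stats::var(pt$fitted) > 0 && stats::var(p_obs) > 0)
    stats::cor(pt$fitted, p_obs)^2 else 1
  pt$fallback <- FALSE
  pt
}

#' Saturating (diminishing-returns) scale
#'
#' `(1+K) p / (1 + K p)`: the identity at `K = 0`, with fixed points at
#' `p = 0` and `p = 1`. As `K` grows, mutations have systematically smaller
#' effects in backgrounds with higher phenotypes.
#'
#' @param p numeric phenotypes
#' @param K saturation constant, `K >= 0`
#' @return numeric transformed phenotypes
#' @examples
#' saturating_scale(0.5, 2)  # 0.75
#' @export
saturating_scale <- function(p, K) {
  stopifnot(is.numeric(K), length(K) == 1, K >= 0)
  if (any(1 + K * p == 0))
    stop("domain error: input at the pole p = -1/K", call. = FALSE)
  (1 + K) * p / (1 + K * p)
}

#' Scale-fit report as a JSON string or file
#'
#' @param pt a fitted [power_transform]
#' @param path optional output path; when omitted the JSON string is
#'   returned
#' @return JSON (invisibly when written to `path`)
#' @export
scale_report <- function(pt, path = NULL) {
  stopifnot(inherits(pt, "power_transform"))
  obj <- list(lambda = pt$lambda, A = pt$A, B = pt$B, GM = pt$GM,
              amplitude = pt$amplitude, objective = pt$objective,
              n_points = pt$n, pearson_r2_fit = pt$r2)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
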