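#' Bootstrap measurement uncertainty into epistatic coefficients
#'
#' Repeatedly (i) draws one pseudo-phenotype per genotype from
#' `Normal(phenotype_mean, phenotype_sd)`, (ii) puts the pseudoreplicate
#' vector on the linear scale (either refitting the power transform to each
#' pseudoreplicate, propagating scale-fit uncertainty, or reusing the
#' point-estimate transform), and (iii) decomposes it into epistatic
#' coefficients. Running means and variances of every coefficient are
#' checked after each batch of `batch` pseudoreplicates; the run stops when
#' all of them change by less than `tol` (relative) from one batch to the
#' next, or at `max_reps` (with a warning and `converged = FALSE`). Fully
#' reproducible for a given `seed`.
#'
#' @param map a [gpmap] with per-genotype `stdev` and `n`
#' @param max_order interaction-order cutoff or `"full"`
#' @param scale `"power"` (fit and remove the nonlinear scale) or `"none"`
#' @param refit_transform refit the power transform on every pseudoreplicate
#'   (default; warm-started from the point estimate) or reuse the point
#'   estimate
#' @param batch pseudoreplicates per convergence-check batch
#' @param tol relative convergence tolerance on every coefficient's running
#'   mean and variance (0.001 = 0.1 percent)
#' @param max_reps pseudoreplicate budget
#' @param alpha significance level passed to [significance()]
#' @param seed optional RNG seed
#' @return a `bootstrap_summary` data.frame: `sites`, `order`, `beta`
#'   (bootstrap mean), `beta_sd`, plus the [significance()] columns;
#'   attributes `n_pseudoreplicates`, `converged`, `seed`, `point_estimate`
#'   (the decomposition of the observed means) and `transform` (the
#'   point-estimate [power_transform], when `scale = "power"`)
#' @export
bootstrap_coefficients <- function(map, max_order = "full",
                                   scale = c("power", "none"),
                                   refit_transform = TRUE, batch = 50,
                                   tol = 0.001, max_reps = 200000,
                                   alpha = 0.05, seed = NULL) {
  stopifnot(inherits(map, "gpmap"))
  scale <- match.arg(scale)
  if (!is.null(seed)) set.seed(seed)

  design <- if (is_binary_map(map)) walsh_encode(map, max_order)
            else wyk_encode(map, max_order)
  X <- design$X
  G <- nrow(X)
  square_hadamard <- ncol(X) == G && all(crossprod(X) == G * diag(ncol(X)))
  qrX <- if (!square_hadamard) qr(X) else NULL
  solve_p <- function(P) {
    if (square_hadamard) crossprod(X, P) / G else qr.coef(qrX, P)
  }

  mu <- map$data$phenotype
  sdv <- map$data$stdev
  pt0 <- NULL
  op <- NULL
  if (scale == "power") {
    add <- fit_additive(map)
    pt0 <- fit_power_transform(add$p_add, mu)
    if (refit_transform) op <- additive_operator(map)
  }
  point_est <- decompose(if (scale == "power")
    linearize(mu, pt0, clip = TRUE) else mu, design,
    origin_scale = if (scale == "power") "linearized" else "raw")

  ncoef <- ncol(X)
  S1 <- numeric(ncoef); S2 <- numeric(ncoef); nrep <- 0L
  prev_mean <- NULL; prev_var <- NULL
  converged <- FALSE

  relchange <- function(new, old) {
    out <- ifelse(new == old, 0, abs(new - old) / abs(old))
    out[is.nan(out)] <- 0
    out
  }

  while (nrep < max_reps) {
    b <- min(batch, max_reps - nrep)
    P <- matrix(stats::rnorm(G * b, mean = mu, sd = sdv), nrow = G)
    if (scale == "power") {
      if (refit_transform) {
        padd <- op$W %*% P
        for (j in seq_len(b)) {
          ptj <- tryCatch(
            fit_power_transform(padd[, j], P[, j],
                                start = c(pt0$lambda, pt0$A)),
            error = function(e) pt0)
          P[, j] <- linearize(P[, j], ptj, clip = TRUE)
        }
      } else {
        P <- linearize(P, pt0, clip = TRUE)
      }
    }
    B <- solve_p(P)
    S1 <- S1 + rowSums(B)
    S2 <- S2 + rowSums(B^2)
    nrep <- nrep + b
    cur_mean <- S1 / nrep
    cur_var <- pmax((S2 - S1^2 / nrep) / max(nrep - 1L, 1L), 0)
    if (!is.null(prev_mean)) {
      if (all(relchange(cur_mean, prev_mean) < tol) &&
          all(relchange(cur_var, prev_var) < tol)) {
        converged <- TRUE
        prev_mean <- cur_mean; prev_var <- cur_var
        break
      }
    }
    prev_mean <- cur_mean; prev_var <- cur_var
  }
  if (!converged)
    warning("bootstrap reached max_reps = ", max_reps,
            " without meeting the convergence rule; results returned with ",
            "converged = FALSE", call. = FALSE)

  out <- data.frame(sites = design$labels, order = design$orders,
                    beta = prev_mean, beta_sd = sqrt(prev_var),
                    stringsAsFactors = FALSE)
  attr(out, "n_pseudoreplicates") <- nrep
  attr(out, "converged") <- converged
  attr(out, "seed") <- seed
  attr(out, "point_estimate") <- point_est
  attr(out, "transform") <- pt0
  class(out) <- c("bootstrap_summary", "data.frame")
  significance(out, alpha = alpha)
}

#' Significance of bootstrapped epistatic coefficients
#'
#' Computes per-coefficient z-scores (bootstrap mean over bootstrap standard
#' deviation), two-sided standard-normal p-values, and Bonferroni-corrected
#' p-values over the `m` non-constant coefficients (the constant term has no
#' null hypothesis of interest and is not tested). Stars follow the usual
#' convention on the corrected p-value: `*` < 0.05, `**` < 0.01,
#' `***` < 0.001.
#'
#' @param summary a `bootstrap_summary` from [bootstrap_coefficients()]
#' @param alpha significance level for the `significant` flag
#' @return the summary with columns `z`, `p_raw`, `p_bonferroni`,
#'   `significant`, `stars` (re)computed
#' @export
significance <- function(summary, alpha = 0.05) {
  stopifnot(inherits(summary, "bootstrap_summary") ||
              all(c("beta", "beta_sd", "order") %in% names(summary)))
  z <- ifelse(summary$beta_sd > 0, summary$beta / summary$beta_sd,
              ifelse(summary$beta == 0, 0, Inf * sign(summary$beta)))
  p_raw <- ifelse(is.finite(z), 2 * stats::pnorm(-abs(z)), 0)
  p_raw[summary$beta_sd == 0 & summary$beta == 0] <- 1
  tested <- summary$order > 0
  m <- sum(tested)
  p_bonf <- pmin(1, m * p_raw)
  summary$z <- z
  summary$p_raw <- p_raw
  summary$p_bonferroni <- p_bonf
  summary$significant <- tested & p_bonf < alpha
  summary$stars <- ifelse(!tested, "",
                   ifelse(p_bonf < 0.001, "***",
                   ifelse(p_bonf < 0.01, "**",
                   ifelse(p_bonf < 0.05, "*", "ns"))))
  summary$significant[!tested] <- NA
  summary$z[!tested] <- NA
  summary$p_raw[!tested] <- NA
  summary$p_bonferroni[!tested] <- NA
  attr(summary, "alpha") <- alpha
  summary
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat("Bootstrap summary: ", attr(x, "n_pseudoreplicates"),
      " pseudoreplicates, converged = ", attr(x, "converged"), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 8), digits = 4)
  if (nrow(x) > 8) cat("... ", nrow(x) - 8, " more coefficients\n")
  invisible(x)
}
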