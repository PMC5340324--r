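#' Additive (first-order average-effect) model of a map
#'
#' The average effect of a mutation is the mean, over all genetic
#' backgrounds, of the phenotype difference between carrying that mutation
#' and carrying the wild-type state at its site. The additive prediction for
#' genotype i is the observed wild-type phenotype plus the sum of the
#' average effects of the mutations genotype i carries. The wild-type
#' intercept puts predictions on the same scale as the observations, so the
#' predicted-vs-observed cloud can be compared to the identity line and fed
#' to [fit_power_transform()].
#'
#' @param map a [gpmap] (binary or mixed 2/4-state sites)
#' @return An `additive_model`: list with `avg_effects` (named vector, one
#'   entry per non-wild-type state per site; names like `"2"` for the mutant
#'   state of binary site 2, `"3:A"` for state A at a 4-state site 3),
#'   `intercept` (observed wild-type phenotype) and `p_add` (per-genotype
#'   additive predictions, in map record order).
#' @examples
#' m <- gpmap(data.frame(genotype = c("00", "01", "10", "11"),
#'                       phenotype = c(0, 2, 1, 2)))
#' fit_additive(m)$avg_effects  # site 1: 0.5, site 2: 1.5
#' @export
fit_additive <- function(map) {
  stopifnot(inherits(map, "gpmap"))
  op <- additive_operator(map)
  p <- map$data$phenotype
  effects <- drop(op$E %*% p)
  names(effects) <- op$effect_names
  p_add <- drop(op$W %*% p)
  structure(list(avg_effects = effects,
                 intercept = p[op$wt_row],
                 p_add = p_add),
            class = "additive_model")
}

# Linear operators for the additive model: E maps the phenotype vector to the
# per-mutation average effects; W maps it to the additive predictions
# (wild-type intercept included). Both are exact linear maps because every
# average effect is a mean of paired phenotype differences, which makes
# bootstrap re-estimation a single matrix product.
additive_operator <- function(map) {
  g <- map$data$genotype
  G <- length(g)
  L <- length(map$sites)
  chars <- do.call(rbind, strsplit(g, ""))
  wt <- strsplit(map$wildtype, "")[[1]]
  row_of <- match(g, g)  # identity, kept for clarity
  lookup <- seq_len(G)
  names(lookup) <- g
  wt_row <- lookup[[map$wildtype]]

  eff_rows <- list()
  eff_names <- character(0)
  memb <- list()  # indicator of mutation presence per genotype
  for (i in seq_len(L)) {
    st <- map$sites[[i]]
    for (s in setdiff(st, wt[i])) {
      carriers <- which(chars[, i] == s)
      partner_g <- g[carriers]
      substr(partner_g, i, i) <- wt[i]
      partners <- lookup[partner_g]
      w <- numeric(G)
      nb <- length(carriers)
      w[carriers] <- w[carriers] + 1 / nb
      for (p in partners) w[p] <- w[p] - 1 / nb
      eff_rows[[length(eff_rows) + 1L]] <- w
      eff_names <- c(eff_names,
                     if (length(st) == 2L) as.character(i)
                     else paste0(i, ":", s))
      memb[[length(memb) + 1L]] <- as.numeric(chars[, i] == s)
    }
  }
  E <- do.call(rbind, eff_rows)
  M <- do.call(cbind, memb)  # G x n_effects
  Iwt <- matrix(0, nrow = G, ncol = G)
  Iwt[, wt_row] <- 1
  W <- Iwt + M %*% E
  list(E = E, W = W, effect_names = eff_names, wt_row = wt_row)
}

#' Decompose phenotypes into epistatic coefficients
#'
#' For a full-order design on a complete binary map the design (with
#' constant) is a Hadamard matrix and the decomposition is the exact
#' orthogonal transform `beta = t(X) p / 2^L`. Square non-orthogonal designs
#' are solved exactly; non-square (truncated or tetrahedral) designs by
#' ordinary least squares.
#'
#' @param phenotypes numeric vector aligned with the design rows
#' @param design an `epistasis_design` from [walsh_encode()] or
#'   [wyk_encode()]
#' @param origin_scale scale annotation stored on the result (`"raw"` or
#'   `"linearized"`)
#' @return An `epistasis_coefficients` data.frame with columns `sites`
#'   (label), `order` and `beta`, one row per design column in design column
#'   order.
#' @export
decompose <- function(phenotypes, design, origin_scale = "raw") {
  stopifnot(inherits(design, "epistasis_design"))
  X <- design$X
  if (length(phenotypes) != nrow(X))
    stop("phenotype vector length (", length(phenotypes),
         ") does not match design rows (", nrow(X), ")", call. = FALSE)
  beta <- solve_design(X, phenotypes)
  structure(data.frame(sites = design$labels, order = design$orders,
                       beta = as.numeric(beta), stringsAsFactors = FALSE),
            class = c("epistasis_coefficients", "data.frame"),
            origin_scale = origin_scale)
}

# Solver shared by decompose and the bootstrap (p may be a matrix of
# phenotype columns).
solve_design <- function(X, p) {
  p <- as.matrix(p)
  n <- nrow(X); m <- ncol(X)
  if (n == m) {
    if (all(crossprod(X) == n * diag(m))) {
      crossprod(X, p) / n       # Hadamard: exact orthogonal inverse
    } else {
      solve(X, p)
    }
  } else {
    qrX <- qr(X)
    if (qrX$rank < m) {
      dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):m]]
      stop("rank-deficient design; collinear column(s): ",
           paste(dropped, collapse = ", "), call. = FALSE)
    }
    qr.coef(qrX, p)
  }
}

#' Reconstruct phenotypes from epistatic coefficients
#'
#' @param coefs an `epistasis_coefficients` object (or numeric vector in
#'   design column order)
#' @param design the matching `epistasis_design`
#' @return numeric per-genotype phenotypes `X %*% beta`
#' @export
reconstruct <- function(coefs, design) {
  stopifnot(inherits(design, "epistasis_design"))
  beta <- if (is.data.frame(coefs)) coefs$beta else as.numeric(coefs)
  if (length(beta) != ncol(design$X))
    stop("coefficient length (", length(beta),
         ") does not match design columns (", ncol(design$X), ")",
         call. = FALSE)
  unname(drop(design$X %*% beta))
}

#' Partition phenotypic variance by interaction order
#'
#' Fits nested truncated models (all columns of order <= k, k = 1..L) by
#' ordinary least squares and measures each fit as the squared Pearson
#' correlation between fitted and observed phenotypes. The contribution of
#' order k is the increase in that fraction over the order-(k-1) model; the
#' constant-only model defines fit(0) = 0. On a complete binary map the
#' columns are orthogonal, so the contributions equal the normalized sums of
#' squared Walsh coefficients per order and the full-order fit is exactly 1.
#'
#' @param phenotypes numeric per-genotype phenotypes (linearized scale if a
#'   nonlinear scale was removed)
#' @param design a full-order `epistasis_design`
#' @return a `variance_partition` data.frame with columns `order`,
#'   `contribution` and `cumulative`
#' @export
partition_variance <- function(phenotypes, design) {
  stopifnot(inherits(design, "epistasis_design"))
  X <- design$X
  if (length(phenotypes) != nrow(X))
    stop("phenotype vector does not match design rows", call. = FALSE)
  L <- max(design$orders)
  if (stats::var(phenotypes) == 0) {
    out <- data.frame(order = seq_len(L), contribution = 0,
                      cumulative = 1)
    class(out) <- c("variance_partition", "data.frame")
    return(out)
  }
  fits <- numeric(L)
  for (k in seq_len(L)) {
    Xi <- X[, design$orders <= k, drop = FALSE]
    fitted <- Xi %*% qr.coef(qr(Xi), phenotypes)
    fits[k] <- stats::cor(as.numeric(fitted), phenotypes)^2
  }
  out <- data.frame(order = seq_len(L),
                    contribution = diff(c(0, fits)),
                    cumulative = fits)
  class(out) <- c("variance_partition", "data.frame")
  out
}

#' Write an epistatic-coefficient table
#'
#' Writes the deterministic coefficient CSV (design column order):
#' `sites,order,beta` plus, when a bootstrap summary is attached,
#' `beta_sd,z,p_raw,p_bonferroni,significant,stars`.
#'
#' @param coefs an `epistasis_coefficients` data.frame or a
#'   `bootstrap_summary`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_coefficients <- function(coefs, path) {
  df <- as.data.frame(coefs)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
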