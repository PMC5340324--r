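#' Random epistatic coefficients for a binary map
#'
#' Draws one coefficient per Walsh design column from zero-centered normal
#' distributions with per-order standard deviations. Columns above `order`
#' (and the constant) are zero. Defaults follow the package's study
#' conditions: unit-scale first-order effects and smaller (0.35) higher-order
#' interactions.
#'
#' @param L number of binary sites
#' @param order highest nonzero interaction order (1 to `L`, or `"full"`)
#' @param magnitudes per-order standard deviations, recycled to length
#'   `order`; default `c(1, 0.35, 0.35, ...)`
#' @param seed optional RNG seed for reproducibility
#' @return an `epistasis_coefficients` data.frame (full design column order)
#'   with attribute `L`
#' @export
random_coefficients <- function(L, order = "full", magnitudes = NULL,
                                seed = NULL) {
  L <- as.integer(L)
  if (identical(order, "full")) order <- L
  order <- as.integer(order)
  if (order < 1L || order > L)
    stop("order must be between 1 and L", call. = FALSE)
  if (is.null(magnitudes)) magnitudes <- c(1, rep(0.35, max(order - 1L, 0L)))
  magnitudes <- rep_len(magnitudes, order)
  if (!is.null(seed)) set.seed(seed)
  design <- walsh_encode(template_map(L), "full")
  sd_per_col <- c(0, magnitudes)[design$orders + 1L]
  sd_per_col[design$orders > order] <- 0
  beta <- stats::rnorm(ncol(design$X), 0, sd = pmax(sd_per_col, 0))
  beta[sd_per_col == 0] <- 0
  out <- structure(data.frame(sites = design$labels, order = design$orders,
                              beta = beta, stringsAsFactors = FALSE),
                   class = c("epistasis_coefficients", "data.frame"),
                   origin_scale = "linear", L = L)
  out
}

# all-binary map skeleton with genotypes in lexicographic order
template_map <- function(L) {
  states <- rep(list(c("0", "1")), L)
  g <- do.call(expand.grid, c(rev(states), list(stringsAsFactors = FALSE)))
  g <- sort(apply(g[, rev(seq_len(L)), drop = FALSE], 1, paste, collapse = ""))
  gpmap(data.frame(genotype = g, phenotype = 0), sites = states,
        wildtype = strrep("0", L))
}

#' Scale specifications for the simulator
#'
#' `scale_none()` leaves phenotypes on the linear scale. `scale_saturating()`
#' first maps the linear phenotypes affinely onto the span `[0.02*S, S]`
#' (keeping them positive and clear of the transform's pole) and then applies
#' [saturating_scale()] with constant `K`. `scale_power()` applies a
#' [power_transform()] curve directly. Any monotone function of one numeric
#' vector can also be passed wherever a scale spec is accepted.
#'
#' @param K saturation constant (`scale_saturating`)
#' @param span upper end `S` of the pre-scaled phenotype interval
#'   `[0.02*S, S]`; the default 8 spans the saturating curve's working range
#'   so that a shallow `K` still produces the strong, high-order spurious
#'   epistasis regime
#' @param lambda,A,B,GM,amplitude parameters for `scale_power`
#' @return a `scale_spec` list
#' @export
scale_none <- function() structure(list(type = "none"), class = "scale_spec")

#' @rdname scale_none
#' @export
scale_saturating <- function(K = 2, span = 8) {
  stopifnot(K >= 0, span > 0)
  structure(list(type = "saturating", K = K, span = span),
            class = "scale_spec")
}

#' @rdname scale_none
#' @export
scale_power <- function(lambda, A, B, GM = 1, amplitude = 1) {
  structure(list(type = "power",
                 pt = power_transform(lambda, A, B, GM, amplitude)),
            class = "scale_spec")
}

apply_scale <- function(p, spec) {
  if (is.function(spec)) return(spec(p))
  stopifnot(inherits(spec, "scale_spec"))
  switch(spec$type,
         none = p,
         saturating = {
           rng <- diff(range(p))
           q <- if (rng == 0) rep(spec$span, length(p)) else
             0.02 * spec$span + (0.98 * spec$span) * (p - min(p)) / rng
           saturating_scale(q, spec$K)
         },
         power = transform_phenotypes(p, spec$pt),
         stop("unknown scale spec", call. = FALSE))
}

#' Build a synthetic genotype-phenotype map from known coefficients
#'
#' Phenotypes are constructed as `X beta` on the Walsh design, passed through
#' the requested scale, and observed with replicate noise: `n_replicates`
#' draws from `Normal(P, noise_sd)` per genotype give the recorded replicate
#' mean, standard deviation and count. With one replicate the generating
#' `noise_sd` is recorded as the standard deviation (the measurement-error
#' scale is then known rather than estimated).
#'
#' @param coefs generating coefficients from [random_coefficients()] (or any
#'   `epistasis_coefficients` with attribute `L`)
#' @param scale_spec a scale specification ([scale_none()],
#'   [scale_saturating()], [scale_power()] or a monotone function)
#' @param noise_sd replicate noise standard deviation (phenotype units;
#'   scalar or per-genotype)
#' @param n_replicates replicates per genotype
#' @param seed optional RNG seed
#' @return a `simulated_map`: list with `map` (the realized [gpmap]),
#'   `true_coefs`, `scale_spec`, `noise_sd`, `seed`, `p_linear` (noiseless
#'   linear phenotypes) and `p_scaled` (noiseless scaled phenotypes)
#' @export
build_map <- function(coefs, scale_spec = scale_none(), noise_sd = 0,
                      n_replicates = 3, seed = NULL) {
  L <- attr(coefs, "L")
  if (is.null(L)) L <- max(nchar(gsub("[^0-9,]", "", coefs$sites)))
  if (!is.null(seed)) set.seed(seed)
  skel <- template_map(L)
  design <- walsh_encode(skel, "full")
  if (nrow(coefs) != ncol(design$X))
    stop("coefficients do not match a full-order design on ", L, " sites",
         call. = FALSE)
  p_lin <- reconstruct(coefs, design)
  p_scaled <- apply_scale(p_lin, scale_spec)
  G <- length(p_scaled)
  noise_sd <- rep_len(noise_sd, G)
  n_replicates <- as.integer(n_replicates)
  stopifnot(n_replicates >= 1L, all(noise_sd >= 0))
  if (all(noise_sd == 0)) {
    mean_p <- p_scaled; sd_p <- rep(0, G)
  } else {
    reps <- matrix(stats::rnorm(G * n_replicates, mean = p_scaled,
                                sd = noise_sd),
                   nrow = G, ncol = n_replicates)
    mean_p <- rowMeans(reps)
    sd_p <- if (n_replicates >= 2L) apply(reps, 1, stats::sd) else noise_sd
  }
  map <- gpmap(data.frame(genotype = skel$data$genotype, phenotype = mean_p,
                          stdev = sd_p, n = n_replicates),
               sites = skel$sites, wildtype = skel$wildtype)
  structure(list(map = map, true_coefs = coefs, scale_spec = scale_spec,
                 noise_sd = noise_sd, seed = seed, p_linear = p_lin,
                 p_scaled = p_scaled),
            class = "simulated_map")
}

#' @export
print.simulated_map <- function(x, ...) {
  cat("Simulated map: ", nrow(x$map$data), " genotypes; scale: ",
      if (is.function(x$scale_spec)) "custom" else x$scale_spec$type,
      "; max noise sd ", format(max(x$noise_sd), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Observed vs additive-prediction table for a simulated map
#'
#' Pairs each genotype's observed phenotype with the additive prediction
#' estimated from the realized map itself (never the generating truth), the
#' input to scale fitting and to diminishing-returns diagnostics.
#'
#' @param sim a `simulated_map`
#' @return data.frame with columns `genotype`, `p_add`, `p_obs`
#' @export
padd_vs_pobs_table <- function(sim) {
  stopifnot(inherits(sim, "simulated_map"))
  add <- fit_additive(sim$map)
  data.frame(genotype = sim$map$data$genotype, p_add = add$p_add,
             p_obs = sim$map$data$phenotype, stringsAsFactors = FALSE)
}

#' Write a simulated map plus its ground truth
#'
#' The map goes to `<stem>_map.json` (readable by [read_map()]); the
#' generating coefficients, scale specification and seed go to
#' `<stem>_truth.json`.
#'
#' @param sim a `simulated_map`
#' @param stem output path stem
#' @return character vector of the two paths, invisibly
#' @export
write_simulated_map <- function(sim, stem) {
  stopifnot(inherits(sim, "simulated_map"))
  map_path <- paste0(stem, "_map.json")
  truth_path <- paste0(stem, "_truth.json")
  write_map(sim$map, map_path, "json")
  spec <- sim$scale_spec
  truth <- list(
    true_coefs = as.data.frame(sim$true_coefs),
    scale_spec = if (is.function(spec)) list(type = "custom")
                 else lapply(spec, function(z)
                   if (inherits(z, "power_transform")) unclass(z) else z),
    noise_sd = sim$noise_sd,
    seed = sim$seed)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(c(map = map_path, truth = truth_path))
}
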