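#' Walsh (Hadamard) encoding of a binary genotype-phenotype map
#'
#' Encodes each site as -1 (wild type) / +1 (mutant) and builds the design
#' matrix whose columns are the constant column plus, for every subset of at
#' most `max_order` sites, the product of the per-site codes. For
#' `max_order = "full"` on an all-binary map the result (including the
#' constant) is a `2^L x 2^L` Hadamard matrix: `t(X) %*% X == 2^L * I` in
#' exact integer arithmetic, so the coefficient transform is orthogonal and
#' coefficients measure average effects relative to the geometric center of
#' the map.
#'
#' @param map a [gpmap] with two states at every site
#' @param max_order integer interaction-order cutoff, or `"full"` for all
#'   orders up to the number of sites
#' @return An `epistasis_design`: list with `X` (integer matrix, one row per
#'   map record in record order), `labels` (comma-separated 1-based site
#'   tuples, `""` for the constant), `orders` (integer interaction order per
#'   column) and `sites` (list of integer site tuples).
#' @examples
#' m <- gpmap(data.frame(genotype = c("00", "01", "10", "11"),
#'                       phenotype = c(0, 2, 1, 2)))
#' d <- walsh_encode(m)
#' crossprod(d$X)  # 4 * diag(4)
#' @export
walsh_encode <- function(map, max_order = "full") {
  stopifnot(inherits(map, "gpmap"))
  if (!is_binary_map(map))
    stop("walsh_encode requires binary sites; use wyk_encode for 4-state sites",
         call. = FALSE)
  build_design(map, max_order)
}

#' WYK tetrahedral encoding of a map with 2- and 4-state sites
#'
#' Four-state (nucleotide) sites are encoded by three +/-1 bit columns: the
#' wild-type state is (1,1,1) and the remaining states, in their order within
#' the site's state list, take the tetrahedron corners (1,-1,-1), (-1,1,-1)
#' and (-1,-1,1). Binary sites contribute the single Walsh column (-1 wild
#' type, +1 mutant), so an all-binary map yields exactly the
#' [walsh_encode()] design. Interaction columns are products of bit columns
#' from distinct sites; the order of a column is the number of distinct
#' sites contributing to it.
#'
#' @inheritParams walsh_encode
#' @param map a [gpmap] whose sites have 2 or 4 states
#' @return an `epistasis_design` (see [walsh_encode()]); labels carry a
#'   `.b` suffix for the bit index of 4-state sites (e.g. `"2.1"`)
#' @export
wyk_encode <- function(map, max_order = "full") {
  stopifnot(inherits(map, "gpmap"))
  ns <- vapply(map$sites, length, 0L)
  if (any(!ns %in% c(2L, 4L)))
    stop("unsupported state count: sites must have 2 or 4 states (site ",
         which(!ns %in% c(2L, 4L))[1], " has ", ns[!ns %in% c(2L, 4L)][1],
         ")", call. = FALSE)
  build_design(map, max_order)
}

# Shared design construction. Each site contributes 1 (binary) or 3
# (tetrahedral) +/-1 factor columns; design columns are products of factor
# columns from distinct sites, grouped by ascending interaction order, site
# tuples in combn (lexicographic) order, bit tuples lexicographic within.
build_design <- function(map, max_order) {
  L <- length(map$sites)
  G <- nrow(map$data)
  if (identical(max_order, "full")) max_order <- L
  max_order <- as.integer(max_order)
  if (max_order < 1L || max_order > L)
    stop("max_order must be between 1 and the number of sites", call. = FALSE)

  chars <- do.call(rbind, strsplit(map$data$genotype, ""))
  wt <- strsplit(map$wildtype, "")[[1]]
  tetra <- rbind(c(1L, 1L, 1L),      # wild type
                 c(1L, -1L, -1L),    # 1st non-wild-type state
                 c(-1L, 1L, -1L),    # 2nd
                 c(-1L, -1L, 1L))    # 3rd

  # factor columns per site: list of G x n_bits integer matrices
  fac <- vector("list", L)
  for (i in seq_len(L)) {
    st <- map$sites[[i]]
    if (length(st) == 2L) {
      fac[[i]] <- matrix(ifelse(chars[, i] == wt[i], -1L, 1L), ncol = 1)
    } else {
      ord_states <- c(wt[i], setdiff(st, wt[i]))
      idx <- match(chars[, i], ord_states)
      fac[[i]] <- tetra[idx, , drop = FALSE]
    }
  }
  nbits <- vapply(fac, ncol, 0L)

  cols <- list(matrix(1L, nrow = G, ncol = 1))
  labels <- ""
  orders <- 0L
  site_sets <- list(integer(0))
  for (k in seq_len(max_order)) {
    subsets <- utils::combn(L, k, simplify = FALSE)
    for (s in subsets) {
      bit_grid <- do.call(expand.grid, rev(lapply(s, function(i)
        seq_len(nbits[i]))))
      bit_grid <- bit_grid[, rev(seq_len(ncol(bit_grid))), drop = FALSE]
      for (r in seq_len(nrow(bit_grid))) {
        bits <- as.integer(bit_grid[r, ])
        col <- rep(1L, G)
        for (j in seq_along(s)) col <- col * fac[[s[j]]][, bits[j]]
        cols[[length(cols) + 1L]] <- matrix(col, ncol = 1)
        labels <- c(labels, paste(ifelse(nbits[s] > 1L,
                                         paste0(s, ".", bits),
                                         as.character(s)),
                                  collapse = ","))
        orders <- c(orders, k)
        site_sets[[length(site_sets) + 1L]] <- s
      }
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- map$data$genotype
  colnames(X) <- ifelse(labels == "", "(const)", labels)
  structure(list(X = X, labels = labels, orders = orders, sites = site_sets),
            class = "epistasis_design")
}

#' @export
print.epistasis_design <- function(x, ...) {
  cat("Epistasis design: ", nrow(x$X), " genotypes x ", ncol(x$X),
      " columns (orders ", paste(range(x$orders), collapse = "-"), ")\n",
      sep = "")
  invisible(x)
}
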