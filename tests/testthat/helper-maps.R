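# fixtures built in code

# two-site map with negative epistasis: P00=0, P01=2, P10=1, P11=2
toy_map <- function() {
  gpmap(data.frame(genotype = c("00", "01", "10", "11"),
                   phenotype = c(0, 2, 1, 2)))
}

# complete binary map with iid standard-normal phenotypes
random_binary_map <- function(L, seed = 1, sd_phen = 1) {
  set.seed(seed)
  skel <- epiwalsh:::template_map(L)
  gpmap(data.frame(genotype = skel$data$genotype,
                   phenotype = stats::rnorm(2^L, sd = sd_phen)),
        sites = skel$sites, wildtype = skel$wildtype)
}

# additive map built from known effects (wildtype phenotype 0)
additive_map <- function(effects) {
  L <- length(effects)
  skel <- epiwalsh:::template_map(L)
  xi <- do.call(rbind, strsplit(skel$data$genotype, "")) == "1"
  gpmap(data.frame(genotype = skel$data$genotype,
                   phenotype = as.numeric(xi %*% effects)),
        sites = skel$sites, wildtype = skel$wildtype)
}

# mixed map: two 4-state nucleotide sites plus binary sites
nucleotide_map <- function(n_binary = 3, seed = 1) {
  set.seed(seed)
  sites <- c(rep(list(c("A", "C", "G", "T")), 2),
             rep(list(c("0", "1")), n_binary))
  L <- length(sites)
  g <- do.call(expand.grid, c(rev(sites), list(stringsAsFactors = FALSE)))
  g <- apply(g[, rev(seq_len(L)), drop = FALSE], 1, paste, collapse = "")
  gpmap(data.frame(genotype = g, phenotype = stats::rnorm(length(g))),
        sites = sites, wildtype = paste0("GG", strrep("0", n_binary)))
}
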