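# shared fixtures, all built in code

# tiny expression dataset from a matrix literal
make_ds <- function(values, n_ref = NULL, ref = "LMP", case = "HGSOC") {
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  if (is.null(n_ref)) n_ref <- ncol(values) %/% 2
  labs <- rep(c(ref, case), c(n_ref, ncol(values) - n_ref))
  expr_dataset(values, setNames(labs, colnames(values)), ref_level = ref)
}

# balanced two-group dataset of pure noise
noise_ds <- function(n_genes, n_per_group, seed = 1, gene_prefix = "g") {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * 2 * n_per_group), n_genes,
              dimnames = list(paste0(gene_prefix, seq_len(n_genes)),
                              paste0("s", seq_len(2 * n_per_group))))
  make_ds(m, n_ref = n_per_group)
}

# graph from an even-length vertex-name vector of edge endpoints
graph_lit <- function(...) igraph::make_graph(c(...), directed = FALSE)

# independent oracle: exact two-sided Wilcoxon rank-sum p by enumerating
# every assignment of the pooled ranks to the case group
wilcoxon_exact_oracle <- function(ref, case) {
  pooled <- c(ref, case)
  n <- length(pooled)
  k <- length(case)
  r <- rank(pooled)
  obs_w <- sum(r[(length(ref) + 1):n]) - k * (k + 1) / 2
  combos <- utils::combn(n, k)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]) - k * (k + 1) / 2)
  mu <- k * (n - k) / 2
  mean(abs(w_all - mu) >= abs(obs_w - mu) - 1e-12)
}

# independent oracle: plugin MI in bits via the entropy identity
# H(X) + H(Y) - H(X,Y) on already-binned data
mi_entropy_oracle <- function(bins, labels) {
  ent <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log2(p))
  }
  ent(bins) + ent(labels) - ent(paste(bins, labels))
}

# canonical planted-subnetwork fixture: the study condition for recovery
# (5-gene subnetwork, activity effect 2 sd, 20+20 samples, sparse graph)
planted_subnet_fixture <- function(rng_seed = 42) {
  g <- generate_ppi(300, 1, rng_seed = 7)
  cfg <- sim_config(20, 20, de_n = 0,
                    subnetworks = list(list(size = 5, effect = 2, member_sd = 2)),
                    rng_seed = rng_seed)
  gen <- generate_dataset(cfg, g)
  list(graph = g, dataset = gen$dataset, truth = gen$truth$subnetworks[[1]])
}

# canonical planted-hub fixture (rho 0.8 -> 0.0, 30+30 samples)
planted_hub_fixture <- function(rng_seed = 42) {
  g <- generate_ppi(300, 2, rng_seed = 7)
  cfg <- sim_config(30, 30, de_n = 0,
                    hubs = list(list(degree = 5, rho_ref = 0.8, rho_case = 0)),
                    rng_seed = rng_seed)
  gen <- generate_dataset(cfg, g)
  list(graph = g, dataset = gen$dataset, truth = gen$truth$hubs[[1]])
}
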