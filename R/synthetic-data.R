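#' Simulation configuration for two-phenotype expression data
#'
#' Collects every knob of the synthetic generator in one validated object.
#' Effect sizes are expressed in units of the baseline within-group standard
#' deviation (`noise_sd`), so `de_effect = 2` plants a two-standard-deviation
#' mean shift in the case phenotype.
#'
#' @param n_samples_ref,n_samples_case samples per phenotype group.
#' @param de_n number of planted differentially expressed genes.
#' @param de_genes optional explicit gene symbols to plant as differentially
#'   expressed (overrides random selection; lets two datasets share one
#'   planted signature). Overrides `de_n`.
#' @param de_effect mean shift added to case samples of planted DE genes,
#'   in units of `noise_sd`.
#' @param subnetworks list of planted discriminative subnetworks, each a list
#'   with elements `size` (member count), `effect` (shift of the shared
#'   latent activity in case samples, units of `noise_sd`), `member_sd`
#'   (standard deviation of per-member noise around the latent) and
#'   optionally `latent_sd` (within-group standard deviation of the shared
#'   latent, default 0.3). The defaults make each member individually a weak
#'   phenotype marker while the member average separates the phenotypes
#'   clearly — the structure subnetwork discovery is designed to exploit.
#'   Members are drawn by random breadth-first growth restricted to the
#'   seed node's distance-2 neighborhood, so every planted subnetwork is
#'   admissible for [grow_subnetwork()]'s distance rule.
#' @param hubs list of planted differentially correlated hubs, each a list
#'   with elements `degree` (number of partners), `rho_ref` and `rho_case`
#'   (partner-hub Pearson correlation within each phenotype group).
#' @param noise_sd baseline expression standard deviation.
#' @param class_names the two phenotype labels, reference first.
#' @param rng_seed integer seed; the generator derives an independent
#'   sub-stream per component from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples_ref = 20, n_samples_case = 20,
                       de_n = 0, de_genes = NULL, de_effect = 2,
                       subnetworks = list(), hubs = list(),
                       noise_sd = 1, class_names = c("LMP", "HGSOC"),
                       rng_seed = 1L) {
  stopifnot(n_samples_ref >= 2, n_samples_case >= 2, de_n >= 0,
            is.finite(de_effect), noise_sd > 0, length(class_names) == 2)
  subnetworks <- lapply(subnetworks, function(sn) {
    stopifnot(sn$size >= 1, is.finite(sn$effect), sn$member_sd >= 0)
    if (is.null(sn$latent_sd)) sn$latent_sd <- 0.3
    stopifnot(sn$latent_sd >= 0)
    sn
  })
  for (h in hubs)
    stopifnot(h$degree >= 1, abs(h$rho_ref) < 1, abs(h$rho_case) < 1)
  if (!is.null(de_genes)) de_n <- length(de_genes)
  structure(list(n_samples_ref = n_samples_ref,
                 n_samples_case = n_samples_case,
                 de_n = de_n, de_genes = de_genes, de_effect = de_effect,
                 subnetworks = subnetworks, hubs = hubs,
                 noise_sd = noise_sd, class_names = class_names,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

# independent sub-stream seeds derived from one global seed (Lehmer step);
# component k always gets the same seed, so adding a component later does
# not perturb the others
.derive_seed <- function(seed, k) {
  x <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(k)
  as.integer(x %% 2147483646) + 1L
}

# evaluate expr under a local RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a scale-free protein-interaction graph
#'
#' Preferential attachment (Barabasi-Albert): nodes join one at a time and
#' attach `attachment` edges to existing nodes with probability proportional
#' to degree, yielding the heavy-tailed degree distribution typical of
#' curated human interactomes. The result is connected by construction, and
#' a tree when `attachment = 1`.
#'
#' @param n_nodes number of genes.
#' @param attachment edges added per new node (>= 1, < `n_nodes`).
#' @param rng_seed integer seed; fixed seed gives an identical graph.
#' @return an undirected igraph with vertex names `G0001`, `G0002`, ...
#' @export
generate_ppi <- function(n_nodes, attachment = 2, rng_seed = 1L) {
  if (!(n_nodes > attachment && attachment >= 1))
    stop("need n_nodes > attachment >= 1")
  g <- .with_seed(rng_seed,
    igraph::sample_pa(n_nodes, power = 1, m = attachment, directed = FALSE))
  igraph::V(g)$name <- sprintf("G%04d", seq_len(n_nodes))
  g
}

#' Generate a two-phenotype expression dataset with planted signal
#'
#' Baseline expression is i.i.d. normal noise. On top of it the generator
#' plants, per the configuration: (i) differentially expressed genes (a mean
#' shift in case samples); (ii) connected discriminative subnetworks, whose
#' members share a per-sample latent activity whose mean differs between
#' phenotypes; and (iii) differentially correlated hubs, whose partners are
#' built as \eqn{\rho h + \sqrt{1-\rho^2}\,\epsilon} with a phenotype-specific
#' \eqn{\rho}. Planted gene sets are disjoint. A fixed seed reproduces the
#' dataset exactly.
#'
#' @param cfg a [sim_config()].
#' @param graph the PPI graph defining the gene universe (vertex names become
#'   the dataset's genes).
#' @return a list: `dataset` (an [expr_dataset()]) and `truth`, a manifest
#'   list with elements `de_genes`, `subnetworks` (each with `seed_gene`,
#'   `members` and the planted parameters) and `hubs` (each with `hub`,
#'   `partners`, `rho_ref`, `rho_case`).
#' @export
generate_dataset <- function(cfg, graph) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- igraph::V(graph)$name
  n_genes <- length(genes)
  n_ref <- cfg$n_samples_ref; n_case <- cfg$n_samples_case
  n_s <- n_ref + n_case
  sam <- sprintf("S%03d", seq_len(n_s))
  labels <- factor(rep(cfg$class_names, c(n_ref, n_case)),
                   levels = cfg$class_names)
  case_cols <- which(labels == cfg$class_names[2])

  vals <- .with_seed(.derive_seed(cfg$rng_seed, 1L),
    matrix(rnorm(n_genes * n_s, 0, cfg$noise_sd), n_genes, n_s,
           dimnames = list(genes, sam)))

  taken <- character(0)
  truth <- list(de_genes = character(0), subnetworks = list(), hubs = list())

  # planted connected subnetworks: random BFS growth from a random seed node
  if (length(cfg$subnetworks)) {
    truth$subnetworks <- .with_seed(.derive_seed(cfg$rng_seed, 3L), {
      lapply(cfg$subnetworks, function(sn) {
        mem <- .random_connected_set(graph, sn$size, exclude = taken,
                                     max_dist = 2)
        taken <<- c(taken, mem)
        latent <- rnorm(n_s, 0, sn$latent_sd * cfg$noise_sd)
        latent[case_cols] <- latent[case_cols] + sn$effect * cfg$noise_sd
        for (g in mem)
          vals[g, ] <<- latent + rnorm(n_s, 0, sn$member_sd * cfg$noise_sd)
        list(seed_gene = mem[1], members = mem, effect = sn$effect,
             member_sd = sn$member_sd, latent_sd = sn$latent_sd)
      })
    })
  }

  # planted hubs: partners regenerated as correlated copies of the hub row
  if (length(cfg$hubs)) {
    truth$hubs <- .with_seed(.derive_seed(cfg$rng_seed, 4L), {
      lapply(cfg$hubs, function(h) {
        deg <- igraph::degree(graph)
        ok <- names(deg)[deg >= h$degree & !genes %in% taken]
        ok <- ok[vapply(ok, function(v) {
          sum(!igraph::neighbors(graph, v)$name %in% taken) >= h$degree
        }, logical(1))]
        if (!length(ok)) stop("no available node with degree >= ", h$degree)
        hub <- sample(ok, 1)
        nb <- setdiff(igraph::neighbors(graph, hub)$name, taken)
        partners <- sample(nb, h$degree)
        taken <<- c(taken, hub, partners)
        hz <- vals[hub, ] / cfg$noise_sd
        rho <- ifelse(seq_len(n_s) %in% case_cols, h$rho_case, h$rho_ref)
        for (p in partners)
          vals[p, ] <<- cfg$noise_sd *
            (rho * hz + sqrt(1 - rho^2) * rnorm(n_s))
        list(hub = hub, partners = partners,
             rho_ref = h$rho_ref, rho_case = h$rho_case)
      })
    })
  }

  if (cfg$de_n > 0) {
    if (!is.null(cfg$de_genes)) {
      missing <- setdiff(cfg$de_genes, genes)
      if (length(missing))
        stop("de_genes not in the gene universe: ",
             paste(missing, collapse = ", "))
      truth$de_genes <- sort(cfg$de_genes)
    } else {
      free <- setdiff(genes, taken)
      if (length(free) < cfg$de_n) stop("not enough genes left to plant DE set")
      truth$de_genes <- .with_seed(.derive_seed(cfg$rng_seed, 2L),
                                   sort(sample(free, cfg$de_n)))
    }
    vals[truth$de_genes, case_cols] <-
      vals[truth$de_genes, case_cols] + cfg$de_effect * cfg$noise_sd
  }

  list(dataset = expr_dataset(vals, setNames(as.character(labels), sam),
                              ref_level = cfg$class_names[1]),
       truth = truth)
}

# connected vertex set of the requested size, grown by random BFS within the
# start node's max_dist-ball; the first element is the growth seed
.random_connected_set <- function(graph, size, exclude = character(0),
                                  max_dist = Inf) {
  avail <- setdiff(igraph::V(graph)$name, exclude)
  if (size > length(avail)) stop("cannot plant subgraph of size ", size)
  for (attempt in seq_len(50L)) {
    start <- sample(avail, 1)
    ball <- if (is.finite(max_dist)) {
      d <- igraph::distances(graph, v = start)[1, ]
      setdiff(names(d)[d <= max_dist], exclude)
    } else avail
    if (length(ball) < size) next
    mem <- start
    repeat {
      if (length(mem) == size) return(mem)
      frontier <- setdiff(
        intersect(
          unique(unlist(lapply(mem, function(v)
            igraph::neighbors(graph, v)$name))),
          ball),
        mem)
      if (!length(frontier)) break
      mem <- c(mem, sample(frontier, 1))
    }
  }
  stop("could not find a connected subgraph of size ", size,
       " avoiding already-planted genes")
}

#' Write a ground-truth manifest as flat key-value text
#'
#' @param truth the `truth` element of [generate_dataset()]'s result.
#' @param path output file.
#' @return `truth`, invisibly.
#' @export
write_manifest <- function(truth, path) {
  lines <- c(paste0("de_genes=", paste(truth$de_genes, collapse = ";")))
  for (i in seq_along(truth$subnetworks)) {
    sn <- truth$subnetworks[[i]]
    lines <- c(lines,
      sprintf("subnetwork.%d.seed_gene=%s", i, sn$seed_gene),
      sprintf("subnetwork.%d.members=%s", i, paste(sn$members, collapse = ";")),
      sprintf("subnetwork.%d.effect=%g", i, sn$effect),
      sprintf("subnetwork.%d.member_sd=%g", i, sn$member_sd))
  }
  for (i in seq_along(truth$hubs)) {
    h <- truth$hubs[[i]]
    lines <- c(lines,
      sprintf("hub.%d.gene=%s", i, h$hub),
      sprintf("hub.%d.partners=%s", i, paste(h$partners, collapse = ";")),
      sprintf("hub.%d.rho_ref=%g", i, h$rho_ref),
      sprintf("hub.%d.rho_case=%g", i, h$rho_case))
  }
  writeLines(lines, path)
  invisible(truth)
}
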