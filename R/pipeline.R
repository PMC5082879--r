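#' Assemble a full-pipeline run configuration
#'
#' One object carrying every stage's parameters, with each threshold of the
#' published analysis as a named field at its published default:
#' discrimination score cutoff 0.66, subnetwork permutation p cutoff 1e-4
#' with 10,000 permutations, hub degree cutoff 5, hub permutation p cutoff
#' 0.05 with 1,000 permutations, 1,000 reproducibility draws, and 50 random
#' 2/3-1/3 classification splits.
#'
#' @param out_dir directory for stage outputs (created if absent).
#' @param sim a [sim_config()] describing the synthetic inputs; two
#'   independent datasets are generated from it over one shared graph.
#' @param n_genes,attachment synthetic PPI graph size and attachment.
#' @param top_k list depth for the reproducibility comparison.
#' @param reproducibility_reps random draws for the reproducibility null.
#' @param p_max_de,fc_min_de Wilcoxon p and |log2 FC| thresholds used for
#'   concordant gene selection (both datasets).
#' @param ds_min,subnet_p_max,subnet_reps,max_size subnetwork discovery
#'   parameters.
#' @param subnet_seeds seed genes for discovery, or `NULL` for all measured
#'   genes in the graph.
#' @param min_degree,hub_p_max,hub_reps hub analysis parameters.
#' @param svm_repeats,train_frac classifier evaluation parameters.
#' @param gene_sets optional named list of gene sets for enrichment; default
#'   builds sets from the planted truth plus random sets.
#' @param stages character vector of stages to run, in dependency order.
#' @param fast divide permutation counts by 50 (floored at 100) and relax
#'   the corresponding p thresholds by the same factor — for smoke runs; the
#'   manifest records it.
#' @param rng_seed global integer seed; every stochastic stage receives a
#'   derived sub-seed.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("netdiscrim_run_"),
                       sim = sim_config(
                         n_samples_ref = 20, n_samples_case = 20,
                         de_n = 10, de_effect = 2,
                         subnetworks = list(list(size = 5, effect = 2, member_sd = 0.5)),
                         hubs = list(list(degree = 5, rho_ref = 0.8, rho_case = 0))),
                       n_genes = 300, attachment = 2,
                       top_k = 20, reproducibility_reps = 1000,
                       p_max_de = 0.01, fc_min_de = 0.5,
                       ds_min = 0.66, subnet_p_max = 1e-4,
                       subnet_reps = 10000, max_size = 20,
                       subnet_seeds = NULL,
                       min_degree = 5, hub_p_max = 0.05, hub_reps = 1000,
                       svm_repeats = 50, train_frac = 2 / 3,
                       gene_sets = NULL,
                       stages = c("simulate", "normalize", "rank",
                                  "concordance", "subnet", "hubs",
                                  "enrich", "classify"),
                       fast = FALSE, rng_seed = 1L) {
  cfg <- as.list(environment())
  if (fast) {
    cfg$subnet_reps <- max(100, cfg$subnet_reps %/% 50)
    cfg$hub_reps <- max(100, cfg$hub_reps %/% 50)
    cfg$reproducibility_reps <- max(100, cfg$reproducibility_reps %/% 50)
    cfg$subnet_p_max <- min(1, cfg$subnet_p_max * 50)
  }
  structure(cfg, class = "run_config")
}

#' Run the full differential-network pipeline
#'
#' Executes the enabled stages in dependency order on a pair of synthetic
#' datasets sharing one PPI graph and one planted truth, writing each
#' stage's outputs to `cfg$out_dir` before the next stage starts. The run is
#' fully determined by `cfg$rng_seed`.
#'
#' Stages: `simulate` (graph + two datasets + truth manifest), `normalize`
#' (z-scoring), `rank` (four DE rankings per dataset + reproducibility
#' curve), `concordance` (shared DE genes), `subnet` (discriminative
#' subnetwork discovery per dataset + overlap), `hubs` (hub scoring, shared
#' hubs, brokers), `enrich` (hypergeometric enrichment of discovered
#' subnetwork genes), `classify` (intra-dataset SVM for the three signature
#' types + cross-dataset transfer).
#'
#' @param cfg a [run_config()].
#' @return a list with the in-memory stage `results` and a `manifest` tibble
#'   (stage, status, seconds, outputs); the manifest is also written to
#'   `manifest.tsv` in `out_dir`. A failing stage aborts with its name; its
#'   partial outputs remain on disk next to a `FAILED` marker file.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- new.env(parent = emptyenv())
  manifest <- list()
  all_stages <- c("simulate", "normalize", "rank", "concordance",
                  "subnet", "hubs", "enrich", "classify")

  run_stage <- function(name, fun) {
    if (!name %in% cfg$stages) {
      manifest[[name]] <<- tibble::tibble(
        stage = name, status = "skipped", seconds = 0, outputs = "")
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    outs <- tryCatch(fun(), error = function(e) {
      writeLines(paste(name, conditionMessage(e)),
                 file.path(cfg$out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest[[name]] <<- tibble::tibble(
      stage = name, status = if (isTRUE(cfg$fast)) "ok (fast mode)" else "ok",
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      outputs = paste(outs, collapse = ";"))
    invisible(NULL)
  }

  run_stage("simulate", function() {
    res$graph <- generate_ppi(cfg$n_genes, cfg$attachment,
                              rng_seed = .derive_seed(cfg$rng_seed, 101L))
    simA <- cfg$sim; simA$rng_seed <- .derive_seed(cfg$rng_seed, 102L)
    simB <- cfg$sim; simB$rng_seed <- .derive_seed(cfg$rng_seed, 103L)
    genA <- generate_dataset(simA, res$graph)
    genB <- generate_dataset(simB, res$graph)
    res$dsA <- genA$dataset; res$truthA <- genA$truth
    res$dsB <- genB$dataset; res$truthB <- genB$truth
    write_ppi(res$graph, file.path(cfg$out_dir, "ppi.tsv"))
    write_expression(res$dsA, file.path(cfg$out_dir, "exprA.tsv"),
                     file.path(cfg$out_dir, "labelsA.tsv"))
    write_expression(res$dsB, file.path(cfg$out_dir, "exprB.tsv"),
                     file.path(cfg$out_dir, "labelsB.tsv"))
    write_manifest(res$truthA, file.path(cfg$out_dir, "truthA.txt"))
    write_manifest(res$truthB, file.path(cfg$out_dir, "truthB.txt"))
    c("ppi.tsv", "exprA.tsv", "exprB.tsv", "truthA.txt", "truthB.txt")
  })

  run_stage("normalize", function() {
    res$zA <- zscore_normalize(res$dsA)
    res$zB <- zscore_normalize(res$dsB)
    character(0)
  })

  run_stage("rank", function() {
    methods <- c("mean_fc", "median_fc", "ttest", "wilcoxon")
    res$ranksA <- lapply(setNames(methods, methods), rank_genes, ds = res$dsA)
    res$ranksB <- lapply(setNames(methods, methods), rank_genes, ds = res$dsB)
    outs <- character(0)
    for (m in methods) {
      f <- sprintf("rank_%s_A.tsv", m)
      write.table(res$ranksA[[m]], file.path(cfg$out_dir, f), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      outs <- c(outs, f)
    }
    res$reproducibility <- tibble::tibble(
      method = methods,
      rate = vapply(methods, function(m)
        reproducibility_rate(res$ranksA[[m]], res$ranksB[[m]], cfg$top_k),
        numeric(1)))
    base <- random_baseline(nrow(res$dsA$values), cfg$top_k,
                            reps = cfg$reproducibility_reps,
                            rng_seed = .derive_seed(cfg$rng_seed, 104L))
    res$reproducibility$null_mean <- base$mean
    f <- "reproducibility.tsv"
    write.table(res$reproducibility, file.path(cfg$out_dir, f), sep = "\t",
                quote = FALSE, row.names = FALSE)
    c(outs, f)
  })

  run_stage("concordance", function() {
    res$concordant <- select_concordant(
      res$ranksA$wilcoxon, res$ranksA$median_fc,
      res$ranksB$wilcoxon, res$ranksB$median_fc,
      p_max_a = cfg$p_max_de, fc_min_a = cfg$fc_min_de, fc_scale_a = "log2",
      p_max_b = cfg$p_max_de, fc_min_b = cfg$fc_min_de, fc_scale_b = "log2")
    f <- "concordant_genes.tsv"
    write.table(res$concordant, file.path(cfg$out_dir, f), sep = "\t",
                quote = FALSE, row.names = FALSE)
    f
  })

  run_stage("subnet", function() {
    seeds <- cfg$subnet_seeds
    res$subnetA <- discover_subnetworks(
      res$zA, res$graph, seeds = seeds, ds_min = cfg$ds_min,
      p_max = cfg$subnet_p_max, reps = cfg$subnet_reps,
      rng_seed = .derive_seed(cfg$rng_seed, 105L), max_size = cfg$max_size)
    res$subnetB <- discover_subnetworks(
      res$zB, res$graph, seeds = seeds, ds_min = cfg$ds_min,
      p_max = cfg$subnet_p_max, reps = cfg$subnet_reps,
      rng_seed = .derive_seed(cfg$rng_seed, 106L), max_size = cfg$max_size)
    res$subnet_overlap <- cross_dataset_overlap(res$subnetA, res$subnetB)
    outs <- character(0)
    for (nm in c("subnetA", "subnetB")) {
      f <- paste0(nm, ".tsv")
      tab <- res[[nm]]
      flat <- data.frame(
        seed = vapply(tab$seed, paste, character(1), collapse = ";"),
        members = vapply(tab$members, paste, character(1), collapse = ";"),
        ds = tab$ds, p_random_same_seed = tab$p_random_same_seed,
        p_random_other_seed = tab$p_random_other_seed,
        p_label_perm = tab$p_label_perm)
      write.table(flat, file.path(cfg$out_dir, f), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      outs <- c(outs, f)
    }
    outs
  })

  run_stage("hubs", function() {
    res$hubsA <- score_all_hubs(res$graph, res$dsA,
                                min_degree = cfg$min_degree,
                                reps = cfg$hub_reps,
                                rng_seed = .derive_seed(cfg$rng_seed, 107L))
    res$hubsB <- score_all_hubs(res$graph, res$dsB,
                                min_degree = cfg$min_degree,
                                reps = cfg$hub_reps,
                                rng_seed = .derive_seed(cfg$rng_seed, 108L))
    res$shared_hubs <- cross_dataset_hubs(res$hubsA, res$hubsB,
                                          p_max = cfg$hub_p_max)
    sigA <- res$hubsA$hub[res$hubsA$p_perm < cfg$hub_p_max]
    res$brokers <- find_brokers(sigA, res$graph)
    outs <- character(0)
    for (nm in c("hubsA", "hubsB")) {
      f <- paste0(nm, ".tsv")
      write.table(res[[nm]], file.path(cfg$out_dir, f), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      outs <- c(outs, f)
    }
    outs
  })

  run_stage("enrich", function() {
    universe <- rownames(res$dsA$values)
    sets <- cfg$gene_sets
    if (is.null(sets)) {
      # planted truth plus size-matched random sets as the test collection
      sets <- list(planted_subnetwork =
                     unlist(lapply(res$truthA$subnetworks, `[[`, "members")),
                   planted_de = res$truthA$de_genes)
      sets <- sets[lengths(sets) > 0]
      rnd <- .with_seed(.derive_seed(cfg$rng_seed, 109L), {
        lapply(1:5, function(i) sample(universe, 20))
      })
      names(rnd) <- paste0("random_set_", 1:5)
      sets <- c(sets, rnd)
    }
    query <- unique(unlist(res$subnetA$members))
    if (!length(query)) query <- head(res$ranksA$wilcoxon$gene, cfg$top_k)
    res$enrichment <- hypergeom_enrich(query, sets, universe)
    f <- "enrichment.tsv"
    write.table(res$enrichment, file.path(cfg$out_dir, f), sep = "\t",
                quote = FALSE, row.names = FALSE)
    f
  })

  run_stage("classify", function() {
    de_sig <- if (!is.null(res$concordant) && nrow(res$concordant))
      res$concordant$gene else head(res$ranksA$wilcoxon$gene, cfg$top_k)
    sigs <- list(de_genes = de_sig)
    if (!is.null(res$subnetA) && nrow(res$subnetA))
      sigs$subnetworks <- res$subnetA$members
    hubsA_sig <- res$hubsA$hub[res$hubsA$p_perm < cfg$hub_p_max]
    if (length(hubsA_sig))
      sigs$hubs <- setNames(lapply(hubsA_sig, function(h)
        igraph::neighbors(res$graph, h)$name), hubsA_sig)
    res$classification <- lapply(names(sigs), function(ty) {
      ds_use <- if (ty == "de_genes") res$dsA else res$zA
      fm <- build_features(ds_use, sigs[[ty]], type = ty)
      evaluate_classifier(fm, repeats = cfg$svm_repeats,
                          train_frac = cfg$train_frac,
                          rng_seed = .derive_seed(cfg$rng_seed, 110L))
    })
    names(res$classification) <- names(sigs)
    fmA <- build_features(res$dsA, de_sig, type = "de_genes")
    fmB <- build_features(res$dsB, de_sig, type = "de_genes")
    res$cross_classification <- cross_dataset_evaluate(fmA, fmB)
    summ <- tibble::tibble(
      signature = c(names(res$classification), "de_genes (cross-dataset)"),
      mean_auc = c(vapply(res$classification, `[[`, numeric(1), "mean_auc"),
                   res$cross_classification$mean_auc),
      sd_auc = c(vapply(res$classification, `[[`, numeric(1), "sd_auc"),
                 NA_real_))
    f <- "classification.tsv"
    write.table(summ, file.path(cfg$out_dir, f), sep = "\t",
                quote = FALSE, row.names = FALSE)
    f
  })

  manifest <- dplyr::bind_rows(manifest[all_stages[all_stages %in% names(manifest)]])
  manifest$rng_seed <- cfg$rng_seed
  manifest$fast <- isTRUE(cfg$fast)
  write.table(manifest, file.path(cfg$out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  list(results = as.list(res), manifest = manifest)
}
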