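#' Default pipeline configuration
#'
#' Returns the shipped configuration: a synthetic seven-stage study
#' with two planted 20-gene modules, three planted pivot hubs and one
#' planted 4-cell vs 8-cell DE contrast, and the standard analysis
#' thresholds (TPM > 1 in > 50% replicates of some stage; edge BH
#' q <= 0.01; functional modules >= 10 genes with enrichment q <= 0.05;
#' hub degree >= 10; pivot hypergeometric p <= 0.05; DE BH q < 0.05
#' with fold change > 1.4).
#'
#' @param seed Integer master seed.
#' @param out_dir Output directory for [run_pipeline()] artifacts.
#' @return A config list of class `pivot_config`.
#' @export
default_config <- function(seed = 1, out_dir = tempfile("pivotnet_run_")) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    synthetic = list(
      n_genes = 200,
      stages = c("oocyte", "zygote", "2cell", "4cell", "8cell", "morula",
                 "blastocyst"),
      replicates_per_stage = 3,
      modules = list(c(20, 0.9), c(20, 0.9)),
      n_pivots = 3,
      pivot_strength = 0.9,
      de = list(list(stage_a = "4cell", stage_b = "8cell", n_de = 20,
                     fold_change = 3)),
      noise_sd = 0.5,
      ppi = list(p_within = 0.9, p_hub_to_module = 10 / 12,
                 p_background = 0.01, hub_min_degree = 12),
      go = list(terms_per_module = 3, annotation_noise = 0.05)
    ),
    input = NULL,
    thresholds = list(
      tpm_threshold = 1, replicate_fraction = 0.5,
      edge_q = 0.01, min_module_size = 10, enrichment_q = 0.05,
      hub_min_degree = 10, pivot_p = 0.05,
      de_q = 0.05, fold_change = 1.4
    ),
    mcl = list(inflation = 2, expansion = 2, loop_weight = 1,
               prune_threshold = 1e-5, max_iterations = 100,
               tolerance = 1e-6)
  ), class = "pivot_config")
}

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration file (or takes a list) and checks every
#' threshold range at once, reporting ALL violations together rather
#' than stopping at the first.  Exactly one of the `synthetic` block
#' and the `input` path block must be active.
#'
#' @param x Path to a YAML file, or a configuration list.
#' @return The validated configuration (class `pivot_config`); errors
#'   with the full list of violations otherwise.
#' @export
validate_config <- function(x) {
  cfg <- if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stop_pivotnet("config file not found: ", x)
    yaml::read_yaml(x)
  } else {
    x
  }
  base <- unclass(default_config())
  th <- utils::modifyList(base$thresholds, cfg$thresholds %||% list())
  mcl <- utils::modifyList(base$mcl, cfg$mcl %||% list())

  errors <- c(
    check_that(!is.null(cfg$seed) && is.numeric(cfg$seed) &&
                 cfg$seed == round(cfg$seed),
               "seed: must be an integer"),
    check_that(xor(is.null(cfg$synthetic), is.null(cfg$input)),
               "exactly one of `synthetic` and `input` must be given"),
    check_that(th$tpm_threshold >= 0, "tpm_threshold: must be >= 0"),
    check_that(th$replicate_fraction >= 0 && th$replicate_fraction < 1,
               "replicate_fraction: must lie in [0, 1)"),
    check_that(th$edge_q >= 0 && th$edge_q <= 1,
               "edge_q: must lie in [0, 1]"),
    check_that(th$min_module_size >= 1, "min_module_size: must be >= 1"),
    check_that(th$enrichment_q >= 0 && th$enrichment_q <= 1,
               "enrichment_q: must lie in [0, 1]"),
    check_that(th$hub_min_degree >= 1, "hub_min_degree: must be >= 1"),
    check_that(th$pivot_p >= 0 && th$pivot_p <= 1,
               "pivot_p: must lie in [0, 1]"),
    check_that(th$de_q >= 0 && th$de_q <= 1, "de_q: must lie in [0, 1]"),
    check_that(th$fold_change >= 1, "fold_change: must be >= 1"),
    check_that(mcl$inflation > 0, "mcl.inflation: must be > 0"),
    check_that(mcl$expansion >= 2, "mcl.expansion: must be >= 2"),
    check_that(mcl$loop_weight > 0, "mcl.loop_weight: must be > 0")
  )
  if (length(errors)) {
    stop_pivotnet("invalid configuration:\n  - ",
                  paste(errors, collapse = "\n  - "))
  }
  cfg$thresholds <- th
  cfg$mcl <- mcl
  if (!is.null(cfg$synthetic)) {
    # shallow merge: user-supplied fields replace the defaults outright
    # (modifyList would silently drop overrides held in unnamed lists
    # such as `modules` and `de`)
    merged <- base$synthetic
    for (nm in names(cfg$synthetic)) {
      if (nm %in% c("ppi", "go")) {
        merged[[nm]] <- utils::modifyList(merged[[nm]], cfg$synthetic[[nm]])
      } else {
        merged[[nm]] <- cfg$synthetic[[nm]]
      }
    }
    cfg$synthetic <- merged
  }
  cfg$out_dir <- cfg$out_dir %||% tempfile("pivotnet_run_")
  class(cfg) <- "pivot_config"
  cfg
}

#' Run the full pivot-detection pipeline
#'
#' Executes preparation, network construction, MCL clustering,
#' functional-module selection, hub and pivot detection, and the
#' configured differential-expression contrasts in order, writing every
#' intermediate artifact under `config$out_dir` and returning a run
#' manifest (also written as `manifest.json`) with the seed, thresholds
#' and per-stage record counts.  All randomness derives from the single
#' configured seed (stage-local seeds are `seed + 1, + 2, + 3`).
#'
#' @param config A `pivot_config` from [validate_config()] /
#'   [default_config()].
#' @param write_outputs Write TSV/JSON artifacts (default TRUE); the
#'   manifest and result objects are returned either way.
#' @return The manifest list, invisibly extended with a `results`
#'   element holding the in-memory stage outputs.
#' @export
run_pipeline <- function(config = default_config(), write_outputs = TRUE) {
  config <- validate_config(config)
  th <- config$thresholds
  out_dir <- config$out_dir
  if (write_outputs) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- data ---------------------------------------------------------
  if (!is.null(config$synthetic)) {
    sy <- config$synthetic
    sim <- generate_stage_expression(
      n_genes = sy$n_genes, stages = sy$stages,
      replicates_per_stage = sy$replicates_per_stage,
      modules = sy$modules, n_pivots = sy$n_pivots,
      pivot_strength = sy$pivot_strength, de_spec = sy$de,
      noise_sd = sy$noise_sd, seed = config$seed + 1L
    )
    em <- sim$expression
    truth <- sim$truth
    ppi_raw <- generate_ppi(
      truth, p_within = sy$ppi$p_within,
      p_hub_to_module = sy$ppi$p_hub_to_module,
      p_background = sy$ppi$p_background,
      hub_min_degree = sy$ppi$hub_min_degree, seed = config$seed + 2L
    )
    go <- generate_go_annotations(
      truth, terms_per_module = sy$go$terms_per_module,
      annotation_noise = sy$go$annotation_noise, seed = config$seed + 3L
    )
    contrasts <- sy$de
  } else {
    em <- read_expression(config$input$expression_prefix,
                          units = config$input$units %||% "TPM")
    truth <- NULL
    ppi_raw <- utils::read.delim(config$input$ppi, stringsAsFactors = FALSE)
    go <- utils::read.delim(config$input$go, stringsAsFactors = FALSE)
    contrasts <- config$input$contrasts %||% list()
  }

  # --- prep ---------------------------------------------------------
  if (identical(em$units, "counts")) em <- compute_tpm(em)
  expressed <- filter_expressed(em, threshold = th$tpm_threshold,
                                replicate_fraction = th$replicate_fraction)
  em_f <- subset_genes(em, expressed)

  # --- network ------------------------------------------------------
  ppi <- suppressMessages(load_ppi(ppi_raw))
  net <- edge_correlation(ppi, em_f, q_cutoff = th$edge_q)

  # --- modules ------------------------------------------------------
  if (nrow(net$edges) > 0) {
    partition <- mcl_cluster(
      net, inflation = config$mcl$inflation,
      expansion = config$mcl$expansion,
      loop_weight = config$mcl$loop_weight,
      prune_threshold = config$mcl$prune_threshold,
      max_iterations = config$mcl$max_iterations,
      tolerance = config$mcl$tolerance
    )
    modules <- select_functional_modules(
      partition, go, universe = net$nodes,
      min_size = th$min_module_size, q_cutoff = th$enrichment_q
    )
    hubs <- find_intermodular_hubs(net, modules,
                                   min_degree = th$hub_min_degree)
    pivots <- identify_pivots(hubs, net, modules, p_cutoff = th$pivot_p)
  } else {
    partition <- NULL
    modules <- structure(list(clusters = list(), enrichment = list(),
                              functional = logical(0),
                              min_size = th$min_module_size,
                              q_cutoff = th$enrichment_q),
                         class = "module_set")
    hubs <- character(0)
    pivots <- identify_pivots(character(0),
                              structure(list(edges = data.frame(),
                                             nodes = character(0)),
                                        class = "coexpr_network"),
                              modules, p_cutoff = th$pivot_p)
  }

  # --- differential expression -------------------------------------
  de_tables <- list()
  for (ct in contrasts) {
    cid <- paste0(ct$stage_a, "_vs_", ct$stage_b)
    de_tables[[cid]] <- stage_de(em_f, ct$stage_a, ct$stage_b,
                                 q_cutoff = th$de_q,
                                 fc_cutoff = th$fold_change)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("pivotnet")),
    seed = config$seed,
    thresholds = th,
    mcl = config$mcl,
    counts = list(
      genes_input = nrow(em$values),
      genes_expressed = length(expressed),
      ppi_edges = nrow(ppi),
      edges_tested = net$n_tested,
      edges_retained = nrow(net$edges),
      network_nodes = length(net$nodes),
      clusters = length(modules$clusters),
      functional_modules = sum(modules$functional),
      hubs = length(hubs),
      pivots = length(pivot_genes(pivots)),
      de_significant = lapply(de_tables, function(d) sum(d$significant))
    )
  )

  if (write_outputs) {
    write_expression(em, file.path(out_dir, "expression"))
    if (!is.null(truth)) write_truth(truth, file.path(out_dir, "truth.json"))
    utils::write.table(as.data.frame(ppi), file.path(out_dir, "ppi.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(go, file.path(out_dir, "go_annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(expressed, file.path(out_dir, "expressed_genes.txt"))
    write_coexpression(net, file.path(out_dir, "coexpression_edges.tsv"))
    if (length(modules$clusters)) {
      write_modules(modules, file.path(out_dir, "modules"))
    }
    writeLines(hubs, file.path(out_dir, "hubs.txt"))
    utils::write.table(as.data.frame(pivots),
                       file.path(out_dir, "pivots.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (cid in names(de_tables)) {
      write_de(de_tables[[cid]], file.path(out_dir, paste0("de_", cid, ".tsv")))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  manifest$results <- list(
    expression = em, expression_filtered = em_f, truth = truth,
    ppi = ppi, network = net, partition = partition, modules = modules,
    hubs = hubs, pivots = pivots, de = de_tables
  )
  invisible(manifest)
}
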