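#' Simulate stage-wise expression with planted modules, pivots and DE genes
#'
#' Generates a gene x sample abundance matrix emulating a multi-stage
#' developmental transcriptome (by default the seven preimplantation
#' stages: oocyte, zygote, 2-cell, 4-cell, 8-cell, morula, blastocyst,
#' with three replicates each) together with a ground-truth record of
#' everything that was planted.
#'
#' The generative model works on the log2 scale and is deliberately
#' simple: every planted module m receives one latent per-stage profile
#' z_m (i.i.d. Gaussian per stage, shared by all replicates of a stage);
#' a member gene g of m is
#' `log2 x_gs = b_g + strength_m * z_m[stage(s)] + eps`, with gene
#' baseline b_g and i.i.d. noise eps ~ N(0, noise_sd^2).  Members of the
#' same module are therefore collinear up to noise: at `noise_sd = 0`
#' their pairwise Pearson correlation is exactly 1, and in general the
#' expected within-module correlation exceeds the background one.
#' Background genes get independent private profiles, so their pairwise
#' correlations are centred on zero.  Planted pivot genes are background
#' genes whose profile is `sign * pivot_strength * z_target`, i.e. they
#' co-express (or anti-co-express, alternating sign) with one target
#' module without belonging to it.  Planted differentially expressed
#' genes get `log2(fold_change)` added to (direction "up") or subtracted
#' from (direction "down") all samples of the contrast's second stage.
#' Values are exponentiated to non-negative abundances.
#'
#' @param n_genes Total number of genes.
#' @param stages Character vector of stage labels.
#' @param replicates_per_stage Replicates per stage (>= 2; Pearson
#'   correlation is undefined below that).
#' @param modules List of planted modules, each a numeric vector
#'   `c(size, strength)` with strength in (0, 1].
#' @param n_pivots Number of planted pivot genes; targets are assigned
#'   round-robin over the planted modules and co-expression signs
#'   alternate (+, -, +, ...).
#' @param pivot_strength Coupling of a pivot's profile to its target
#'   module's latent profile.
#' @param de_spec List of planted contrasts, each a list with elements
#'   `stage_a`, `stage_b`, `n_de`, `fold_change` (> 1, linear scale).
#'   Directions alternate up/down ("up" = higher in `stage_b`).
#' @param noise_sd Log2-scale i.i.d. noise standard deviation.
#' @param base_log2_mean,base_log2_sd Per-gene baseline distribution.
#' @param profile_sd Per-stage standard deviation of the latent profiles.
#' @param seed Integer RNG seed; identical seeds give identical output.
#'
#' @return A list with elements `expression` (an [expression_matrix()]
#'   with units `"TPM"`) and `truth` (class `synthetic_truth`: module
#'   assignments, pivot table, DE tables per contrast, and the seed).
#' @export
generate_stage_expression <- function(n_genes = 200,
                                      stages = c("oocyte", "zygote", "2cell",
                                                 "4cell", "8cell", "morula",
                                                 "blastocyst"),
                                      replicates_per_stage = 3,
                                      modules = list(c(20, 0.9), c(20, 0.9)),
                                      n_pivots = 3,
                                      pivot_strength = 0.9,
                                      de_spec = list(list(stage_a = "4cell",
                                                          stage_b = "8cell",
                                                          n_de = 20,
                                                          fold_change = 3)),
                                      noise_sd = 0.5,
                                      base_log2_mean = 5,
                                      base_log2_sd = 1,
                                      profile_sd = 2,
                                      seed = 1) {
  if (length(stages) < 1) stop_pivotnet("`stages` must be non-empty")
  if (replicates_per_stage < 2) {
    stop_pivotnet("`replicates_per_stage` must be >= 2 (correlation undefined)")
  }
  mod_sizes <- vapply(modules, function(m) as.numeric(m[[1]]), numeric(1))
  mod_strength <- vapply(modules, function(m) as.numeric(m[[2]]), numeric(1))
  if (any(mod_sizes < 1) || any(mod_strength <= 0)) {
    stop_pivotnet("module sizes must be >= 1 and strengths > 0")
  }
  n_de_total <- sum(vapply(de_spec, function(d) as.numeric(d$n_de), numeric(1)))
  n_planted <- sum(mod_sizes) + n_pivots
  if (n_planted > n_genes) {
    stop_pivotnet("module sizes plus pivots exceed `n_genes`")
  }
  if (n_planted + n_de_total > n_genes) {
    stop_pivotnet("not enough background genes to plant the requested DE genes")
  }
  for (d in de_spec) {
    if (!all(c(d$stage_a, d$stage_b) %in% stages)) {
      stop_pivotnet("DE contrast names a stage not in `stages`")
    }
    if (d$fold_change <= 1) stop_pivotnet("planted fold changes must be > 1")
  }

  n_modules <- length(modules)
  module_ids <- paste0("module", seq_len(n_modules), recycle0 = TRUE)
  gene_ids <- c(
    unlist(lapply(seq_len(n_modules), function(j) {
      sprintf("MOD%d_G%03d", j, seq_len(mod_sizes[j]))
    })),
    if (n_pivots > 0) sprintf("PIV%03d", seq_len(n_pivots)),
    sprintf("BG%04d", seq_len(n_genes - n_planted))
  )
  assignment <- c(
    rep(module_ids, times = mod_sizes),
    rep("background", n_genes - sum(mod_sizes))
  )
  names(assignment) <- gene_ids

  n_stage <- length(stages)
  stage_of_sample <- rep(stages, each = replicates_per_stage)
  sample_ids <- paste0(stage_of_sample, "_r",
                       rep(seq_len(replicates_per_stage), times = n_stage))
  n_samples <- length(sample_ids)
  stage_index <- match(stage_of_sample, stages)

  out <- with_seed(seed, {
    profiles <- matrix(stats::rnorm(n_modules * n_stage, 0, profile_sd),
                       nrow = n_modules)
    baseline <- stats::rnorm(n_genes, base_log2_mean, base_log2_sd)
    log2x <- matrix(0, nrow = n_genes, ncol = n_samples,
                    dimnames = list(gene_ids, sample_ids))

    pivot_target <- integer(0)
    pivot_sign <- numeric(0)
    if (n_pivots > 0) {
      pivot_target <- ((seq_len(n_pivots) - 1L) %% n_modules) + 1L
      pivot_sign <- ifelse(seq_len(n_pivots) %% 2 == 1, 1, -1)
    }

    # choose planted DE genes (background, non-pivot, disjoint across
    # contrasts) up front: their own latent profile is flattened across
    # the contrast stages so the planted fold change is the only
    # systematic difference between them
    bg_pool <- gene_ids[assignment == "background" & !startsWith(gene_ids, "PIV")]
    de_genes <- list()
    de_flat <- list()   # gene id -> c(stage_a index, stage_b index)
    for (d in de_spec) {
      n_de <- as.integer(d$n_de)
      if (n_de == 0) next
      chosen <- sample(bg_pool, n_de)
      bg_pool <- setdiff(bg_pool, chosen)
      direction <- rep(c("up", "down"), length.out = n_de)
      cid <- paste0(d$stage_a, "_vs_", d$stage_b)
      de_genes[[cid]] <- data.frame(
        gene = chosen, direction = direction,
        log2_fold_change = rep(log2(d$fold_change), n_de),
        stringsAsFactors = FALSE
      )
      for (g in chosen) {
        de_flat[[g]] <- match(c(d$stage_a, d$stage_b), stages)
      }
    }

    for (g in seq_len(n_genes)) {
      id <- gene_ids[g]
      if (assignment[g] != "background") {
        j <- match(assignment[g], module_ids)
        signal <- mod_strength[j] * profiles[j, stage_index]
      } else if (startsWith(id, "PIV")) {
        k <- as.integer(sub("PIV", "", id))
        signal <- pivot_sign[k] * pivot_strength *
          profiles[pivot_target[k], stage_index]
      } else {
        own <- stats::rnorm(n_stage, 0, profile_sd)
        if (!is.null(de_flat[[id]])) {
          own[de_flat[[id]][2]] <- own[de_flat[[id]][1]]
        }
        signal <- own[stage_index]
      }
      log2x[g, ] <- baseline[g] + signal
    }
    if (noise_sd > 0) {
      log2x <- log2x + matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd),
                              nrow = n_genes)
    }

    # apply the planted contrast shifts ("up" = higher in stage_b)
    for (d in de_spec) {
      cid <- paste0(d$stage_a, "_vs_", d$stage_b)
      if (is.null(de_genes[[cid]])) next
      tab <- de_genes[[cid]]
      cols_b <- which(stage_of_sample == d$stage_b)
      shift <- ifelse(tab$direction == "up", 1, -1) * log2(d$fold_change)
      for (i in seq_len(nrow(tab))) {
        log2x[tab$gene[i], cols_b] <- log2x[tab$gene[i], cols_b] + shift[i]
      }
    }

    list(
      values = 2^log2x,
      pivots = if (n_pivots > 0) {
        data.frame(
          gene = sprintf("PIV%03d", seq_len(n_pivots)),
          target_module = module_ids[pivot_target],
          sign = ifelse(pivot_sign > 0, "correlated", "anti-correlated"),
          stringsAsFactors = FALSE
        )
      } else {
        data.frame(gene = character(0), target_module = character(0),
                   sign = character(0), stringsAsFactors = FALSE)
      },
      de_genes = de_genes
    )
  })

  truth <- structure(
    list(
      module_assignments = assignment,
      modules = stats::setNames(
        lapply(module_ids, function(m) gene_ids[assignment == m]), module_ids
      ),
      pivot_genes = out$pivots,
      de_genes = out$de_genes,
      seed = as.integer(seed)
    ),
    class = "synthetic_truth"
  )

  list(
    expression = expression_matrix(out$values, stage = stage_of_sample,
                                   units = "TPM"),
    truth = truth
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d genes; %d planted modules (%s); %d pivots; %d DE contrasts; seed %d\n",
    length(x$module_assignments), length(x$modules),
    paste(lengths(x$modules), collapse = "/"),
    nrow(x$pivot_genes), length(x$de_genes), x$seed
  ))
  invisible(x)
}

#' Serialise a synthetic ground-truth record to JSON
#'
#' @param truth A `synthetic_truth` object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(
      module_assignments = as.list(truth$module_assignments),
      pivot_genes = truth$pivot_genes,
      de_genes = truth$de_genes,
      seed = truth$seed
    ),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
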