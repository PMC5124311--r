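# End-to-end driver: simulate (or load) -> preprocess -> coexpression ->
# module detection -> permutation tests -> strength contrast -> network
# export -> enrichment, with a manifest recording every effective parameter,
# seed and output-file checksum so a rerun with the same config reproduces
# all numeric outputs.

default_pipeline_config <- function() {
  list(
    simulate  = list(default = TRUE, seed = 1L),
    preprocess = list(min_count = 5, min_samples = NULL),
    coexpr    = list(beta = 4, max_pairs = 2e6, seed = 1L),
    modules   = list(height_fraction = 0.712, min_size = 30,
                     merge_height = 0.2),
    permtest  = list(B = 1000L, alpha = 0.05, seed = 1L, between = "all",
                     paired = FALSE),
    export    = list(threshold = 0.75),
    enrich    = list(gmt = NULL))
}

#' Run the full differential-coexpression pipeline
#'
#' Executes, in order: data simulation (or loading of user-supplied count
#' and sample tables), preprocessing (filter + size factors + transform),
#' condition-wise coexpression matrices and transcriptome-wide
#' distribution comparison, TOM-based module detection with eigengene
#' merging, permutation significance tests with the DC-strength contrast
#' and the expression-variability check, thresholded network export, and
#' (when a GMT file is configured) gene-set enrichment. All outputs are
#' written under `out_dir`; `manifest.tsv` records each stage's status,
#' effective parameters and output checksums.
#'
#' @param config Path to a YAML configuration file, or a nested list with
#'   (all optional) entries `input` (`counts`, `samples`, optionally
#'   `modules` TSV paths), `simulate` (`default = TRUE` and/or [sim_config()]
#'   fields, `seed`), `preprocess` (`min_count`, `min_samples`), `coexpr`
#'   (`beta`, `max_pairs`, `seed`), `modules` (`height_fraction`,
#'   `min_size`, `merge_height`), `permtest` (`B`, `alpha`, `between`,
#'   `paired`, `seed`), `export` (`threshold`), `enrich` (`gmt`).
#'   Unspecified values fall back to package defaults.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results of every stage
#'   (`data`, `truth`, `expr`, `corr`, `comparison`, `assignment`,
#'   `report`, `strength`, `variability`, `networks`, `enrichment`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(default_pipeline_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  res <- list()

  log_stage <- function(stage, params, outputs) {
    sums <- if (length(outputs)) {
      paste(basename(outputs), unname(tools::md5sum(outputs)),
            sep = ":", collapse = ";")
    } else ""
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, status = "success",
      params = paste(names(params), vapply(params, function(p)
        paste(format(p), collapse = ","), character(1)),
        sep = "=", collapse = ";"),
      outputs = sums, stringsAsFactors = FALSE)
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      write_manifest(manifest, out_dir)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## stage 1: simulate or load -------------------------------------------
  run_stage("simulate", function() {
    if (!is.null(cfg$input)) {
      counts_mat <- read_matrix_tsv(cfg$input$counts)
      samples <- read_samples_tsv(cfg$input$samples)
      res$data <<- coex_counts(counts_mat, samples)
      res$truth <<- NULL
      if (!is.null(cfg$input$modules)) {
        pre <- read_assignment_tsv(cfg$input$modules)
        if (!setequal(names(pre$modules), rownames(counts_mat)))
          stop("gene universe of the modules file disagrees with the counts")
        res$preset_assignment <<- pre
      }
      log_stage("simulate", list(loaded = cfg$input$counts), character(0))
    } else {
      sc <- cfg$simulate
      custom <- setdiff(names(sc), c("default", "seed"))
      config_obj <- if (length(custom) == 0) {
        default_study_config(seed = sc$seed %||% 1L)
      } else {
        args <- sc[setdiff(names(sc), "default")]
        if (!is.null(args$module_specs))
          args$module_specs <- lapply(args$module_specs, function(m)
            if (inherits(m, "module_spec")) m else do.call(module_spec, m))
        do.call(sim_config, args)
      }
      sim <- simulate_expression(config_obj)
      res$data <<- sim$data
      res$truth <<- sim$truth
      f_counts <- file.path(out_dir, "counts.tsv")
      f_meta <- file.path(out_dir, "samples.tsv")
      f_truth <- file.path(out_dir, "truth.tsv")
      mat <- if (inherits(sim$data, "coex_counts")) sim$data$counts else sim$data$values
      write_matrix_tsv(mat, f_counts)
      write_samples_tsv(sim$data$samples, f_meta)
      write.table(data.frame(gene_id = names(sim$truth$module_of_gene),
                             module_id = unname(sim$truth$module_of_gene)),
                  f_truth, sep = "\t", quote = FALSE, row.names = FALSE)
      log_stage("simulate", list(seed = config_obj$seed,
                                 n_genes = config_obj$n_genes),
                c(f_counts, f_meta, f_truth))
    }
  })

  ## stage 2: preprocess --------------------------------------------------
  run_stage("preprocess", function() {
    if (inherits(res$data, "coex_expr")) {      # already transformed input
      res$expr <<- res$data
      log_stage("preprocess", list(skipped = "input already transformed"),
                character(0))
      return(invisible())
    }
    pp <- cfg$preprocess
    ms <- pp$min_samples %||% ceiling(0.25 * ncol(res$data$counts))
    filtered <- filter_genes(res$data, min_count = pp$min_count,
                             min_samples = ms)
    sf <- estimate_size_factors(filtered)
    res$expr <<- vst_transform(filtered, sf)
    f_expr <- file.path(out_dir, "expression.tsv")
    write_matrix_tsv(res$expr$values, f_expr)
    log_stage("preprocess",
              list(min_count = pp$min_count, min_samples = ms,
                   genes_retained = nrow(res$expr$values)), f_expr)
  })

  ## stage 3: coexpression matrices + distribution comparison -------------
  run_stage("coexpr", function() {
    cx <- cfg$coexpr
    conds <- conditions_of(res$expr)
    corr <- lapply(conds, function(cc) spearman_matrix(res$expr, cc))
    names(corr) <- conds
    res$corr <<- corr
    adj <- lapply(corr, signed_adjacency)
    res$dissim <<- difference_dissimilarity(adj[[1]], adj[[2]],
                                            beta = cx$beta)
    res$comparison <<- compare_distributions(
      coexpression_index(corr[[1]]), coexpression_index(corr[[2]]),
      max_pairs = cx$max_pairs, seed = cx$seed %||% 1L)
    f_cmp <- file.path(out_dir, "distribution_comparison.tsv")
    cmp <- res$comparison
    write.table(data.frame(
      key = c("ks_statistic", "ks_p", "rank_sum_W", "rank_sum_p",
              paste0("median_", names(cmp$medians)), "direction",
              "n_pairs", "subsampled"),
      value = c(cmp$ks_statistic, cmp$ks_p, cmp$rank_sum_W, cmp$rank_sum_p,
                cmp$medians, cmp$direction, cmp$n_pairs, cmp$subsampled)),
      f_cmp, sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("coexpr", list(beta = cx$beta, max_pairs = cx$max_pairs,
                             seed = cx$seed %||% 1L), f_cmp)
  })

  ## stage 4: module detection --------------------------------------------
  run_stage("modules", function() {
    md <- cfg$modules
    if (!is.null(res$preset_assignment)) {
      res$assignment <<- res$preset_assignment
      log_stage("modules", list(preset = TRUE), character(0))
      return(invisible())
    }
    tom <- topological_overlap(res$dissim)
    dendro <- cluster_genes(tom)
    cut0 <- cut_tree(dendro, height_fraction = md$height_fraction,
                     min_size = md$min_size)
    res$assignment <<- merge_similar_modules(res$expr, cut0,
                                             merge_height = md$merge_height)
    f_mod <- file.path(out_dir, "modules.tsv")
    write_assignment_tsv(res$assignment, f_mod)
    f_eig <- file.path(out_dir, "eigengenes.tsv")
    write_matrix_tsv(module_eigengene(res$expr, res$assignment), f_eig)
    log_stage("modules", md, c(f_mod, f_eig))
  })

  ## stage 5: permutation tests + contrasts + variability -----------------
  run_stage("permtest", function() {
    pt <- cfg$permtest
    res$report <<- permutation_test(res$expr, res$assignment, B = pt$B,
                                    alpha = pt$alpha, beta = cfg$coexpr$beta,
                                    between = pt$between, paired = pt$paired,
                                    seed = pt$seed %||% 1L)
    f_w <- file.path(out_dir, "dc_within.tsv")
    f_b <- file.path(out_dir, "dc_between.tsv")
    write.table(res$report$within, f_w, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(res$report$between, f_b, sep = "\t", quote = FALSE,
                row.names = FALSE)
    outs <- c(f_w, f_b)
    if (any(res$report$within$dc) || any(res$report$between$dc)) {
      if (any(!res$report$within$dc)) {
        res$strength <<- dc_strength_contrast(res$corr, res$assignment,
                                              res$report)
        f_s <- file.path(out_dir, "dc_strength.tsv")
        write.table(res$strength, f_s, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        outs <- c(outs, f_s)
      }
    }
    res$variability <<- expression_variability_check(res$expr)
    f_v <- file.path(out_dir, "variability.tsv")
    write.table(res$variability$per_gene, f_v, sep = "\t", quote = FALSE,
                row.names = FALSE)
    log_stage("permtest", list(B = pt$B, alpha = pt$alpha,
                               paired = pt$paired, seed = pt$seed %||% 1L),
              c(outs, f_v))
  })

  ## stage 6: network export ----------------------------------------------
  run_stage("export", function() {
    thr <- cfg$export$threshold
    res$networks <<- lapply(res$corr, export_network,
                            assignment = res$assignment, threshold = thr)
    outs <- character(0)
    for (cc in names(res$networks)) {
      f_e <- file.path(out_dir, paste0("edges_", cc, ".tsv"))
      f_n <- file.path(out_dir, paste0("nodes_", cc, ".tsv"))
      write_network_tsv(res$networks[[cc]], f_e, f_n)
      outs <- c(outs, f_e, f_n)
    }
    log_stage("export", list(threshold = thr), outs)
  })

  ## stage 7: enrichment ---------------------------------------------------
  run_stage("enrich", function() {
    if (is.null(cfg$enrich$gmt)) {
      log_stage("enrich", list(skipped = "no gene sets configured"),
                character(0))
      return(invisible())
    }
    sets <- read_gmt(cfg$enrich$gmt)
    res$enrichment <<- hypergeometric_enrichment(res$assignment, sets)
    f_en <- file.path(out_dir, "enrichment.tsv")
    write.table(res$enrichment, f_en, sep = "\t", quote = FALSE,
                row.names = FALSE)
    log_stage("enrich", list(gmt = cfg$enrich$gmt, n_sets = length(sets)),
              f_en)
  })

  res$manifest <- write_manifest(manifest, out_dir)
  invisible(res)
}

write_manifest <- function(manifest, out_dir) {
  df <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(stage = character(0), status = character(0),
               params = character(0), outputs = character(0))
  write.table(df, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  df
}
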