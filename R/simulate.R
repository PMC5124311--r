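# Synthetic two-condition expression data with planted, condition-dependent
# coexpression structure. Each module is driven by one latent factor per
# sample; the gene loading on that factor is condition-specific, which makes
# the expected within-module pairwise correlation in condition c equal to the
# configured loading r via lambda = sigma * sqrt(r / (1 - r)), since
# r = lambda^2 / (lambda^2 + sigma^2) for a single-factor model.

#' Specification of one planted module
#'
#' @param size Number of genes in the module (>= 2).
#' @param loading_a,loading_b Target within-module pairwise correlation (in
#'   `[0, 1)`) in the first and second condition respectively.
#' @param cross_partner Optional integer id of another module whose latent
#'   factor this module's genes additionally load on, planting between-module
#'   coexpression.
#' @param cross_loading_a,cross_loading_b Target correlation contributed by
#'   the partner's factor per condition (same `[0, 1)` scale). Ignored when
#'   `cross_partner` is `NA`.
#' @param de_log2fc Mean expression shift (log2 fold change) between
#'   conditions; applied as +/- half the shift per condition.
#' @return A `module_spec` list.
#' @export
module_spec <- function(size, loading_a, loading_b,
                        cross_partner = NA_integer_,
                        cross_loading_a = 0, cross_loading_b = 0,
                        de_log2fc = 0) {
  stopifnot(size >= 2)
  for (l in c(loading_a, loading_b, cross_loading_a, cross_loading_b))
    if (l < 0 || l >= 1) stop("loadings must lie in [0, 1)")
  structure(list(size = as.integer(size),
                 loading_a = loading_a, loading_b = loading_b,
                 cross_partner = as.integer(cross_partner),
                 cross_loading_a = cross_loading_a,
                 cross_loading_b = cross_loading_b,
                 de_log2fc = de_log2fc),
            class = "module_spec")
}

#' Simulation configuration
#'
#' Describes a two-condition study design: a fixed number of genetic lines,
#' each measured once per condition (paired design), thousands of genes of
#' which some belong to planted coexpression modules.
#'
#' @param n_genes Total number of genes, including unstructured background.
#' @param n_samples_per_condition Samples (lines) per condition (>= 3;
#'   default 17, one sample per line in each condition).
#' @param module_specs List of [module_spec()] objects. Module ids are their
#'   positions in this list; background genes carry id 0.
#' @param background_sd Log-scale residual noise SD (sigma above).
#' @param nb_dispersion Negative-binomial dispersion of the count layer
#'   (variance = mu + dispersion * mu^2).
#' @param baseline_log_mean_range Length-2 numeric, natural-log scale range
#'   from which per-gene baseline means are drawn uniformly.
#' @param library_size_factors `"uniform"` (all 1) or a positive numeric
#'   vector of length `2 * n_samples_per_condition`.
#' @param condition_labels Length-2 character; first label is "condition A"
#'   for the loading fields.
#' @param prop_silent Fraction of genes (taken from the background) emitted
#'   as all-zero counts, mimicking unexpressed annotated genes.
#' @param line_effect_sd SD of a per-line random intercept shared by the two
#'   samples of a line across conditions (0 = off, the default: correlation
#'   analyses are within-condition, so the paired line structure is inert
#'   unless robustness checks want it).
#' @param output `"counts"` for a negative-binomial count matrix or
#'   `"gaussian"` to emit the latent log-scale values directly as an
#'   expression matrix (for testing downstream stages in isolation).
#' @param seed Integer seed; identical seed and config give bit-identical
#'   output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes,
                       n_samples_per_condition = 17,
                       module_specs = list(),
                       background_sd = 1,
                       nb_dispersion = 0.1,
                       baseline_log_mean_range = c(log(50), log(5000)),
                       library_size_factors = "uniform",
                       condition_labels = c("A", "B"),
                       prop_silent = 0,
                       line_effect_sd = 0,
                       output = c("counts", "gaussian"),
                       seed = 1L) {
  output <- match.arg(output)
  if (n_samples_per_condition < 3)
    stop("n_samples_per_condition must be >= 3")
  if (background_sd <= 0) stop("background_sd must be positive")
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (length(condition_labels) != 2L || anyDuplicated(condition_labels))
    stop("condition_labels must be two distinct labels")
  if (prop_silent < 0 || prop_silent >= 1) stop("prop_silent must be in [0, 1)")
  sizes <- vapply(module_specs, function(m) m$size, integer(1))
  if (sum(sizes) > n_genes)
    stop("module sizes (", sum(sizes), ") exceed n_genes (", n_genes, ")")
  for (m in module_specs) {
    if (!is.na(m$cross_partner) &&
        (m$cross_partner < 1 || m$cross_partner > length(module_specs)))
      stop("cross_partner refers to a nonexistent module")
  }
  n_samples <- 2L * as.integer(n_samples_per_condition)
  if (is.character(library_size_factors)) {
    if (!identical(library_size_factors, "uniform"))
      stop("library_size_factors must be 'uniform' or a numeric vector")
  } else {
    if (length(library_size_factors) != n_samples ||
        any(library_size_factors <= 0))
      stop("library_size_factors must be ", n_samples, " positive values")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_samples_per_condition = as.integer(n_samples_per_condition),
                 module_specs = module_specs,
                 background_sd = background_sd,
                 nb_dispersion = nb_dispersion,
                 baseline_log_mean_range = baseline_log_mean_range,
                 library_size_factors = library_size_factors,
                 condition_labels = condition_labels,
                 prop_silent = prop_silent,
                 line_effect_sd = line_effect_sd,
                 output = output,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# lambda giving expected pairwise correlation r under a single shared factor
loading_to_lambda <- function(r, sigma) sigma * sqrt(r / (1 - r))

#' Simulate a two-condition expression study with planted modules
#'
#' Generates counts (or latent Gaussian expression) for a paired design of
#' `n_samples_per_condition` lines measured in each of two conditions, with
#' module-structured correlation that is condition-dependent, and returns the
#' planted ground truth for recovery scoring.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements:
#'   \describe{
#'     \item{data}{[coex_counts()] (or [coex_expr()] when
#'       `config$output == "gaussian"`).}
#'     \item{truth}{`sim_truth` list: `module_of_gene` (named integer, 0 =
#'       background), `dc_within` (logical per module: loadings differ
#'       between conditions), `dc_between` (data.frame of module pairs with
#'       planted cross-module coexpression change), `config`.}
#'   }
#' @examples
#' cfg <- sim_config(n_genes = 60, n_samples_per_condition = 5,
#'                   module_specs = list(module_spec(20, 0.7, 0.1)),
#'                   seed = 42)
#' sim <- simulate_expression(cfg)
#' table(sim$truth$module_of_gene)
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_g <- config$n_genes
  n_pc <- config$n_samples_per_condition
  n_s <- 2L * n_pc
  sigma <- config$background_sd
  specs <- config$module_specs
  n_mod <- length(specs)

  gene_ids <- sprintf("g%04d", seq_len(n_g))
  sample_ids <- c(sprintf("%s_L%02d", config$condition_labels[1], seq_len(n_pc)),
                  sprintf("%s_L%02d", config$condition_labels[2], seq_len(n_pc)))
  samples <- data.frame(
    sample_id = sample_ids,
    condition = rep(config$condition_labels, each = n_pc),
    line = rep(seq_len(n_pc), 2L),
    stringsAsFactors = FALSE)
  cond_idx <- rep(1:2, each = n_pc)  # 1 = condition A, 2 = condition B

  module_of_gene <- integer(n_g)
  pos <- 0L
  for (m in seq_len(n_mod)) {
    module_of_gene[pos + seq_len(specs[[m]]$size)] <- m
    pos <- pos + specs[[m]]$size
  }
  names(module_of_gene) <- gene_ids

  n_bg <- n_g - pos
  n_silent <- as.integer(floor(config$prop_silent * n_g))
  if (n_silent > n_bg)
    stop("prop_silent requires more background genes than available")
  silent <- rep(FALSE, n_g)
  if (n_silent > 0) silent[(n_g - n_silent + 1L):n_g] <- TRUE

  mu <- runif(n_g, config$baseline_log_mean_range[1],
              config$baseline_log_mean_range[2])
  # one latent factor per module per sample
  f <- if (n_mod > 0) {
    matrix(rnorm(n_mod * n_s), n_mod, n_s)
  } else matrix(0, 0, n_s)
  line_eff <- if (config$line_effect_sd > 0) {
    rep(rnorm(n_pc, 0, config$line_effect_sd), 2L)
  } else numeric(n_s)

  x <- matrix(mu, n_g, n_s) +
    matrix(line_eff, n_g, n_s, byrow = TRUE) +
    matrix(rnorm(n_g * n_s, 0, sigma), n_g, n_s)
  for (m in seq_len(n_mod)) {
    sp <- specs[[m]]
    rows <- which(module_of_gene == m)
    lam <- c(loading_to_lambda(sp$loading_a, sigma),
             loading_to_lambda(sp$loading_b, sigma))[cond_idx]
    x[rows, ] <- x[rows, ] + rep(lam * f[m, ], each = length(rows))
    if (!is.na(sp$cross_partner)) {
      clam <- c(loading_to_lambda(sp$cross_loading_a, sigma),
                loading_to_lambda(sp$cross_loading_b, sigma))[cond_idx]
      x[rows, ] <- x[rows, ] + rep(clam * f[sp$cross_partner, ], each = length(rows))
    }
    if (sp$de_log2fc != 0) {
      shift <- sp$de_log2fc * log(2) / 2
      x[rows, ] <- x[rows, ] + rep(c(shift, -shift)[cond_idx], each = length(rows))
    }
  }
  dimnames(x) <- list(gene_ids, sample_ids)

  truth <- structure(list(
    module_of_gene = module_of_gene,
    dc_within = vapply(specs, function(m) m$loading_a != m$loading_b, logical(1)),
    dc_between = dc_between_pairs(specs),
    config = config), class = "sim_truth")

  if (config$output == "gaussian") {
    x[silent, ] <- 0
    return(list(data = coex_expr(x, samples), truth = truth))
  }
  sf <- if (identical(config$library_size_factors, "uniform")) {
    rep(1, n_s)
  } else config$library_size_factors
  mu_counts <- exp(x) * matrix(sf, n_g, n_s, byrow = TRUE)
  counts <- matrix(rnbinom(n_g * n_s, mu = mu_counts,
                           size = 1 / config$nb_dispersion), n_g, n_s)
  counts[silent, ] <- 0L
  dimnames(counts) <- list(gene_ids, sample_ids)
  list(data = coex_counts(counts, samples), truth = truth)
}

dc_between_pairs <- function(specs) {
  rows <- list()
  for (m in seq_along(specs)) {
    sp <- specs[[m]]
    if (!is.na(sp$cross_partner) &&
        sp$cross_loading_a != sp$cross_loading_b) {
      pr <- sort(c(m, sp$cross_partner))
      rows[[length(rows) + 1L]] <- data.frame(module_1 = pr[1], module_2 = pr[2])
    }
  }
  if (length(rows) == 0)
    return(data.frame(module_1 = integer(0), module_2 = integer(0)))
  unique(do.call(rbind, rows))
}

#' Default benchmark study configuration
#'
#' A scaled-down analogue of a 17-lines-per-condition gnotobiotic/axenic
#' transcriptome study: 1,000 genes, six planted modules and unstructured
#' background. Four modules are differentially coexpressed within-module
#' (three with stronger coexpression in the gnotobiotic condition, one
#' stronger in the axenic condition, mirroring networks that the microbiota
#' suppresses), one module pair shares condition-specific cross-module
#' coexpression, and two modules have condition-invariant coexpression and
#' serve as the null baseline. Five percent of genes are emitted all-zero so
#' the QC filter has work to do, and library size factors vary ~2-fold.
#'
#' @param seed Integer seed forwarded to [sim_config()].
#' @return A [sim_config()] object.
#' @export
default_study_config <- function(seed = 1L) {
  n_pc <- 17L
  sf <- exp(seq(log(0.7), log(1.4), length.out = 2L * n_pc))
  sim_config(
    n_genes = 1000L,
    n_samples_per_condition = n_pc,
    module_specs = list(
      module_spec(100, 0.70, 0.20),                     # DC within, stronger A
      module_spec(90,  0.60, 0.15,                      # DC within + between
                  cross_partner = 1L,
                  cross_loading_a = 0.30, cross_loading_b = 0),
      module_spec(80,  0.15, 0.60, de_log2fc = 1),      # DC within, stronger B
      module_spec(80,  0.65, 0.20),                     # DC within, stronger A
      module_spec(70,  0.45, 0.45),                     # condition-invariant
      module_spec(70,  0.40, 0.40)),                    # condition-invariant
    background_sd = 1,
    nb_dispersion = 0.1,
    library_size_factors = sf,
    condition_labels = c("gnotobiotic", "axenic"),
    prop_silent = 0.05,
    seed = seed)
}

#' Score planted-module recovery
#'
#' Adjusted Rand index between a detected module assignment and the planted
#' membership, restricted to genes the pipeline assigned to a module
#' (detected label > 0).
#'
#' @param assignment A `module_assignment` (see [cut_tree()]).
#' @param truth A `sim_truth` from [simulate_expression()].
#' @return Numeric ARI in `[-1, 1]`.
#' @export
module_recovery_ari <- function(assignment, truth) {
  det <- assignment$modules
  planted <- truth$module_of_gene[names(det)]
  keep <- det > 0
  if (!any(keep)) return(0)
  mclust::adjustedRandIndex(det[keep], planted[keep])
}
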