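# Generic gene-set over/under-representation for modules: a hypergeometric
# test against user-supplied sets (GMT), replacing ontology-specific tools.

#' Read a GMT gene-set file
#'
#' Tab-separated lines: set name, description, then member gene ids.
#'
#' @param path GMT file path.
#' @return A named list of character vectors of gene ids; each element
#'   carries its description as attribute `"description"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(cells, `[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene-set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(cells, function(x) {
    if (length(x) < 3L) stop("gene set '", x[1L], "' is empty")
    structure(unique(x[-(1:2)]), description = x[2L])
  })
  names(sets) <- nm
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of character vectors (optionally with a
#'   `"description"` attribute each).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description") %||% "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric gene-set enrichment of modules
#'
#' For every (module, set) combination, tests over-representation
#' (`P(X >= k)`, upper hypergeometric tail) and under-representation
#' (`P(X <= k)`, lower tail) of the set among the module's genes, against a
#' background gene universe. Sets are intersected with the background;
#' module genes must be contained in it. BH adjustment is applied across all
#' tests separately per direction.
#'
#' @param assignment A `module_assignment`.
#' @param sets Named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param background Character vector of background gene ids; defaults to
#'   all genes in the assignment (the analyzed transcriptome).
#' @return `data.frame` with one row per (module, set): `module`, `set`,
#'   `overlap`, `module_size`, `set_size`, `expected`, `p_over`, `p_under`,
#'   `padj_over`, `padj_under`, `direction`.
#' @export
hypergeometric_enrichment <- function(assignment, sets,
                                      background = names(assignment$modules)) {
  if (length(background) == 0) stop("background gene set is empty")
  background <- unique(background)
  labels <- sort(unique(assignment$modules[assignment$modules > 0]))
  if (length(labels) == 0) stop("assignment contains no modules")
  n_bg <- length(background)
  rows <- list()
  for (m in labels) {
    mod_genes <- module_genes(assignment, m)
    if (!all(mod_genes %in% background))
      stop("module ", m, " contains genes outside the background")
    n_mod <- length(mod_genes)
    for (s in names(sets)) {
      set_genes <- intersect(sets[[s]], background)
      K <- length(set_genes)
      k <- length(intersect(mod_genes, set_genes))
      # X ~ Hypergeometric(white = K, black = n_bg - K, drawn = n_mod)
      p_over <- phyper(k - 1, K, n_bg - K, n_mod, lower.tail = FALSE)
      p_under <- phyper(k, K, n_bg - K, n_mod)
      expected <- n_mod * K / n_bg
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, set = s, overlap = k, module_size = n_mod,
        set_size = K, expected = expected,
        p_over = p_over, p_under = p_under,
        direction = if (k >= expected) "over" else "under",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$padj_over <- p.adjust(out$p_over, "BH")
  out$padj_under <- p.adjust(out$p_under, "BH")
  out[, c("module", "set", "overlap", "module_size", "set_size", "expected",
          "p_over", "p_under", "padj_over", "padj_under", "direction")]
}
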