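# Tabular readers/writers. All matrices travel as TSV with gene ids as
# row/column headers; numeric values are written with %.17g so a write/read
# round trip is bit-exact. TSV over CSV throughout: gene ids in some
# annotation dialects contain commas.

#' Write a numeric matrix as TSV
#'
#' First column holds row ids under the header `id`; numeric cells are
#' written with 17 significant digits so the round trip through
#' [read_matrix_tsv()] is lossless.
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("matrix must have row and column names")
  con <- file(path, open = "wb")  # binary: fixed \n endings on any platform
  on.exit(close(con))
  writeLines(paste(c("id", colnames(mat)), collapse = "\t"), con)
  body <- apply(mat, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(rownames(mat), body, sep = "\t"), con)
  invisible(path)
}

#' Read a numeric matrix from TSV
#'
#' Inverse of [write_matrix_tsv()]. Accepts Unix or Windows line endings.
#' Duplicate ids, ragged rows and non-numeric cells are errors naming the
#' offending row or column.
#'
#' @param path Input file path.
#' @return Numeric matrix with row and column names, in file order.
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("matrix file has no data rows: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  col_ids <- header[-1L]
  if (anyDuplicated(col_ids))
    stop("duplicate column id(s): ",
         paste(unique(col_ids[duplicated(col_ids)]), collapse = ", "))
  width <- length(header)
  row_ids <- character(length(cells) - 1L)
  vals <- matrix(NA_real_, length(cells) - 1L, width - 1L)
  for (i in seq_along(row_ids)) {
    row <- cells[[i + 1L]]
    if (length(row) != width)
      stop("ragged row '", row[1L], "': expected ", width, " fields, got ",
           length(row))
    row_ids[i] <- row[1L]
    v <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop("non-numeric cell at row '", row[1L], "', column '",
           col_ids[bad], "': '", row[bad + 1L], "'")
    }
    vals[i, ] <- v
  }
  if (anyDuplicated(row_ids))
    stop("duplicate row id(s): ",
         paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "))
  dimnames(vals) <- list(row_ids, col_ids)
  vals
}

#' Write/read a sample metadata table
#'
#' @param samples `data.frame` with `sample_id`, `condition`, `line`.
#' @param path File path.
#' @return `path` invisibly / the `data.frame`.
#' @export
write_samples_tsv <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_samples_tsv
#' @export
read_samples_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample_id", "condition", "line")
  if (!all(req %in% names(df)))
    stop("sample table must have columns ", paste(req, collapse = ", "))
  df
}

#' Write/read a module assignment table
#'
#' Two-column TSV (`gene_id`, `module_id`); 0 marks unassigned genes.
#'
#' @param assignment A `module_assignment`.
#' @param path File path.
#' @return `path` invisibly / a `module_assignment`.
#' @export
write_assignment_tsv <- function(assignment, path) {
  df <- data.frame(gene_id = names(assignment$modules),
                   module_id = unname(assignment$modules))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assignment_tsv
#' @export
read_assignment_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "module_id") %in% names(df)))
    stop("assignment table must have columns gene_id, module_id")
  modules <- setNames(as.integer(df$module_id), df$gene_id)
  sizes <- table(modules[modules > 0])
  structure(list(modules = modules,
                 sizes = setNames(as.integer(sizes), names(sizes)),
                 params = list(source = path)),
            class = "module_assignment")
}

#' Export a thresholded coexpression network
#'
#' Edge list of all unordered gene pairs whose Spearman correlation is at or
#' beyond `threshold` in magnitude (`rho >= threshold` or
#' `rho <= -threshold`), with node module labels attached.
#'
#' @param corr Spearman correlation matrix.
#' @param assignment A `module_assignment` over the same genes.
#' @param threshold Magnitude threshold in `(0, 1]` (default 0.75).
#' @return A list of class `coex_network`: `edges` (`gene_a`, `gene_b`,
#'   `rho`, `condition`; `gene_a < gene_b` lexicographically, no
#'   duplicates), `nodes` (`gene_id`, `module`), `threshold`.
#' @export
export_network <- function(corr, assignment, threshold = 0.75) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  genes <- rownames(corr)
  if (!all(genes %in% names(assignment$modules)))
    stop("correlation matrix and assignment cover different genes")
  ut <- which(upper.tri(corr) & abs(corr) >= threshold, arr.ind = TRUE)
  ga <- genes[ut[, 1L]]
  gb <- genes[ut[, 2L]]
  flip <- ga > gb
  tmp <- ga[flip]; ga[flip] <- gb[flip]; gb[flip] <- tmp
  ord <- order(ga, gb)
  edges <- data.frame(gene_a = ga, gene_b = gb,
                      rho = corr[ut],
                      condition = rep(attr(corr, "condition") %||% NA_character_,
                                      length(ga)),
                      stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- data.frame(gene_id = genes,
                      module = unname(assignment$modules[genes]),
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, nodes = nodes, threshold = threshold),
            class = "coex_network")
}

#' Write a network's edge list and node attributes
#'
#' @param network A `coex_network` from [export_network()].
#' @param edge_path,node_path Output TSV paths.
#' @return `edge_path`, invisibly.
#' @export
write_network_tsv <- function(network, edge_path, node_path) {
  write.table(network$edges, edge_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(network$nodes, node_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(edge_path)
}
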