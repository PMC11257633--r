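# Readers/writers for the tabular and tree formats shared by every stage,
# plus the packaged X-Y pair survival table.

#' Read a gene x sample expression table
#'
#' Reads a delimited text file whose header row names samples and whose first
#' column names genes, returning a validated numeric matrix of TPM values
#' (genes in rows, samples in columns).
#'
#' @param path Path to the file.
#' @param format Tabular dialect, `"tsv"` (default) or `"csv"`.
#' @return Numeric matrix with gene rownames and sample colnames. All values
#'   are finite and non-negative; gene and sample identifiers are unique.
#' @details Gene identifiers are treated as case-sensitive opaque strings; no
#'   symbol-alias resolution is attempted. A malformed numeric cell raises an
#'   error naming the offending row and column; duplicate gene or sample
#'   identifiers and negative values are rejected.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_expression_table(
#'   matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3"))), tf)
#' read_expression_table(tf)
read_expression_table <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                      colClasses = "character", comment.char = "",
                      quote = "\""),
    error = function(e) stop("parse error reading ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop("parse error: expected a header row plus at least one gene row ",
         "and one sample column in ", path)
  }
  genes <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(genes)) {
    stop("validation error: duplicate gene identifier(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  if (anyDuplicated(samples)) {
    stop("validation error: duplicate sample identifier(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  vals <- matrix(NA_real_, nrow(raw), length(samples),
                 dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    col <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(col) & !(raw[[j + 1L]] %in% c("NA", "")))
    if (length(bad)) {
      stop("parse error: malformed numeric cell at gene '", genes[bad[1L]],
           "', sample '", samples[j], "'")
    }
    vals[, j] <- col
  }
  validate_expression_table(vals)
  vals
}

#' Write an expression table to TSV/CSV
#'
#' @param expr Numeric matrix, genes x samples, with dimnames.
#' @param path Output path.
#' @param format `"tsv"` or `"csv"`.
#' @param gene_column Name for the first (gene identifier) column.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path, format = c("tsv", "csv"),
                                   gene_column = "gene") {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  df <- data.frame(rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- gene_column
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_expression_table <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("validation error: expression table must be a numeric matrix")
  }
  if (any(!is.finite(expr))) {
    stop("validation error: non-finite expression values present")
  }
  if (any(expr < 0)) {
    bad <- which(expr < 0, arr.ind = TRUE)[1L, ]
    stop("validation error: negative TPM at gene '",
         rownames(expr)[bad[1L]], "', sample '", colnames(expr)[bad[2L]], "'")
  }
  invisible(expr)
}

#' Read per-sample karyotype annotations
#'
#' Reads a TSV with columns `sample`, `nX`, `nY` and optionally `n21`,
#' `cell_type`, `condition`. Copy numbers must be non-negative integers with
#' `nX + nY >= 1` (at least one sex chromosome per viable karyotype);
#' `n21` defaults to 2.
#'
#' @param path Path to the annotation TSV.
#' @return A data.frame with one row per sample.
#' @export
read_sample_annotation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("sample", "nX", "nY")
  missing_cols <- setdiff(required, colnames(df))
  if (length(missing_cols)) {
    stop("validation error: annotation missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"n21" %in% colnames(df)) df$n21 <- 2L
  if (!"cell_type" %in% colnames(df)) df$cell_type <- "other"
  if (!"condition" %in% colnames(df)) df$condition <- "control"
  validate_sample_annotation(df)
  df
}

validate_sample_annotation <- function(meta) {
  for (col in c("nX", "nY", "n21")) {
    v <- meta[[col]]
    if (any(!is.finite(v)) || any(v < 0) || any(v != round(v))) {
      stop("validation error: ", col,
           " must contain non-negative integer copy numbers")
    }
  }
  if (any(meta$nX + meta$nY < 1)) {
    stop("validation error: karyotype with nX + nY < 1 is not viable")
  }
  if (anyDuplicated(meta$sample)) {
    stop("validation error: duplicate sample identifier(s) in annotation")
  }
  known_types <- c("LCL", "fibroblast", "other")
  if (any(!meta$cell_type %in% known_types)) {
    stop("validation error: cell_type must be one of ",
         paste(known_types, collapse = ", "))
  }
  invisible(meta)
}

#' Read a rooted species tree in Newick format
#'
#' Wraps [ape::read.tree()] with the validation the phylogenetic survival
#' metrics require: a single rooted tree with a branch length on every edge
#' (lengths are in million years, MY, and are summed downstream).
#'
#' @param path Path to a Newick file containing one tree.
#' @return An [ape] `phylo` object.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("parse error reading Newick: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("parse error: no tree could be read from ", path)
  if (inherits(tree, "multiPhylo")) {
    stop("validation error: expected a single tree, found ", length(tree))
  }
  validate_species_tree(tree)
  tree
}

#' Write a species tree to Newick
#'
#' @param tree An [ape] `phylo` object with branch lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

validate_species_tree <- function(tree) {
  if (!inherits(tree, "phylo")) {
    stop("validation error: not a phylo object")
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("validation error: every branch must carry a length (MY)")
  }
  if (any(tree$edge.length < 0)) {
    stop("validation error: negative branch length")
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("validation error: duplicate leaf labels")
  }
  invisible(tree)
}

#' Total branch length of a species tree
#'
#' @param tree An [ape] `phylo` object with branch lengths in MY.
#' @return Sum of all branch lengths (MY).
#' @export
tree_total_length <- function(tree) {
  validate_species_tree(tree)
  sum(tree$edge.length)
}

#' Read a gene x species presence/absence matrix
#'
#' TSV with genes in the first column and one logical/0-1 column per species,
#' recording in which species the Y-homolog survives.
#'
#' @param path Path to the TSV.
#' @param tree Optional `phylo`; if supplied, species names are checked
#'   against the tree's leaf set.
#' @return Logical matrix, genes x species.
#' @export
read_presence_matrix <- function(path, tree = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  genes <- df[[1L]]
  if (anyDuplicated(genes)) {
    stop("validation error: duplicate gene identifier(s) in presence matrix")
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "logical"
  rownames(m) <- genes
  if (anyNA(m)) stop("parse error: presence matrix cells must be TRUE/FALSE or 0/1")
  if (any(rowSums(m) == 0L)) {
    stop("validation error: gene(s) absent from every species: ",
         paste(genes[rowSums(m) == 0L], collapse = ", "))
  }
  if (!is.null(tree)) {
    unknown <- setdiff(colnames(m), tree$tip.label)
    if (length(unknown)) {
      stop("validation error: species not in tree: ",
           paste(unknown, collapse = ", "))
    }
  }
  m
}

#' Packaged survival table for the 17 human X-Y gene pairs
#'
#' Returns the packaged table of dosage-sensitivity observations for the 17
#' human X-Y gene pairs: whether the X-homolog is expressed from the inactive
#' X (Xi), and the Y-homolog's phylogenetic branch length (MY) and survival
#' fraction across therian species. `survival_fraction_printed` preserves the
#' published mixed-precision strings (e.g. "1.00" vs "0.990");
#' `survival_fraction` is the parsed numeric value. `stratum_max_MY` is the
#' maximum possible branch length for the gene's evolutionary stratum where
#' that maximum is itself determinable from the table (the branch length of
#' genes with survival fraction 1), and `NA` otherwise.
#'
#' @return A 17-row data.frame with columns `x_gene`, `xi_expressed`,
#'   `y_gene`, `survival_fraction_printed`, `survival_fraction`,
#'   `branch_length_MY`, `stratum_max_MY`.
#' @export
#' @examples
#' tab <- load_xy_pair_table()
#' subset(tab, y_gene == "DDX3Y")
load_xy_pair_table <- function() {
  path <- system.file("extdata", "xy_pair_survival.tsv", package = "pairdose",
                      mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "logical", "character",
                                         "character", "numeric", "numeric"),
                          stringsAsFactors = FALSE)
  df$survival_fraction <- as.numeric(df$survival_fraction_printed)
  df <- df[, c("x_gene", "xi_expressed", "y_gene",
               "survival_fraction_printed", "survival_fraction",
               "branch_length_MY", "stratum_max_MY")]
  stopifnot(nrow(df) == 17L,
            all(df$survival_fraction >= 0 & df$survival_fraction <= 1),
            all(df$branch_length_MY >= 0))
  df
}
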