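# Phylogenetic survival metrics, constraint-percentile composites, and
# expression breadth.

#' Phylogenetic branch length of a gene's survival subtree
#'
#' Sums the branch lengths of the minimal subtree connecting the root of the
#' species tree to every species in which the gene is present, each branch
#' counted once. The subtree always includes the root (the gene is assumed
#' ancestrally present), so a gene surviving in a single species still
#' accrues its full root-to-leaf path. The result, in MY, measures the gene's
#' longevity across the species set.
#'
#' @param tree Rooted [ape] `phylo` with branch lengths in MY.
#' @param present Character vector of species (leaf labels) where the gene
#'   survives; must be a non-empty subset of the tree's leaves.
#' @return Total branch length (MY) of the root-spanning survival subtree.
#' @seealso [survival_fraction()]
#' @export
#' @examples
#' tree <- ape::read.tree(text = "((A:10,B:10):5,C:15);")
#' branch_length(tree, c("A", "B"))  # 25
#' branch_length(tree, c("A", "B", "C"))  # 40, the total tree length
branch_length <- function(tree, present) {
  validate_species_tree(tree)
  present <- unique(present)
  if (length(present) == 0L) stop("empty present set")
  unknown <- setdiff(present, tree$tip.label)
  if (length(unknown)) {
    stop("unknown species label(s): ", paste(unknown, collapse = ", "))
  }
  # edge index reaching each child node; walk tip -> root, union the edges
  edge_to <- integer(max(tree$edge))
  edge_to[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  root <- ape::Ntip(tree) + 1L
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  used <- logical(nrow(tree$edge))
  for (tip in match(present, tree$tip.label)) {
    node <- tip
    while (node != root) {
      e <- edge_to[node]
      if (used[e]) break  # path above already accounted for
      used[e] <- TRUE
      node <- parent[node]
    }
  }
  sum(tree$edge.length[used])
}

#' Survival fraction of a Y-homolog
#'
#' The observed total branch length divided by the maximum possible branch
#' length over the species set: 1 means the gene is retained in every
#' lineage, values near 0 mean early loss in most lineages.
#'
#' @param observed_MY Observed branch length (MY), `0 <= observed <= max`.
#' @param max_MY Maximum possible branch length (stratum total, MY), > 0.
#' @return Survival fraction in `[0, 1]` (exact ratio; round to 3 decimals
#'   for presentation alongside published tables).
#' @export
#' @examples
#' survival_fraction(343, 967)  # 0.3547 -> prints as 0.355
survival_fraction <- function(observed_MY, max_MY) {
  stopifnot(length(observed_MY) == length(max_MY) ||
              length(observed_MY) == 1L || length(max_MY) == 1L)
  if (any(max_MY <= 0)) stop("max_MY must be > 0")
  if (any(observed_MY < 0)) stop("observed_MY must be >= 0")
  if (any(observed_MY > max_MY)) {
    stop("observed branch length exceeds stratum maximum")
  }
  observed_MY / max_MY
}

#' Percentile rank of a constraint metric
#'
#' Converts a per-gene metric into percentile ranks on a 0-100 scale with
#' 100 = most constrained. For metrics where low values indicate constraint
#' (e.g. LOEUF) use `constrained_direction = "low"`; for metrics where high
#' values do (e.g. probability of conserved miRNA targeting) use `"high"`.
#' Ties share the mean rank; missing values propagate as `NA` and are
#' excluded from the ranking denominator.
#'
#' @param values Numeric vector of per-gene metric values (>= 2 finite).
#' @param constrained_direction `"low"` or `"high"`.
#' @return Numeric vector of percentiles in `[0, 100]`.
#' @export
#' @examples
#' percentile_rank(c(0.1, 0.5, 0.9), "low")   # 100 50 0
#' percentile_rank(c(0.1, 0.5, 0.9), "high")  # 0 50 100
percentile_rank <- function(values, constrained_direction = c("low", "high")) {
  constrained_direction <- match.arg(constrained_direction)
  finite <- is.finite(values)
  n <- sum(finite)
  if (n < 2L) stop("need at least 2 finite values to rank")
  v <- values
  v[!finite] <- NA
  if (length(unique(v[finite])) == 1L) {
    warning("all metric values identical; returning rank 50 for all")
    out <- ifelse(finite, 50, NA_real_)
    return(out)
  }
  r <- rank(v, na.last = "keep", ties.method = "average")
  pct <- if (constrained_direction == "low") {
    (n - r) / (n - 1) * 100
  } else {
    (r - 1) / (n - 1) * 100
  }
  pct
}

#' Pythagorean combination of two scores
#'
#' Combines two percentile ranks (or two breadths) into a single composite
#' \eqn{\sqrt{(p_1^2 + p_2^2)/2}}, normalized so the maximum attainable
#' composite equals the maximum of the input scale (100 for percentiles, 1
#' for breadths). The combination is symmetric and monotone in each argument
#' and therefore preserves ordering.
#'
#' @param p1,p2 Scores on a common scale: both in `[0, 100]`
#'   (`scale = "percent"`) or both in `[0, 1]` (`scale = "unit"`).
#' @param scale `"auto"` (infer from the data: any value > 1 implies
#'   percentiles), `"percent"`, or `"unit"`. Mixing scales is an error.
#' @return Combined score on the input scale; `NA` if either input is `NA`.
#' @export
#' @examples
#' pythagorean_combine(60, 80)  # 70.71
pythagorean_combine <- function(p1, p2, scale = c("auto", "percent", "unit")) {
  scale <- match.arg(scale)
  if (scale == "auto") {
    hi <- suppressWarnings(max(c(p1, p2), na.rm = TRUE))
    scale <- if (is.finite(hi) && hi > 1) "percent" else "unit"
  }
  top <- if (scale == "percent") 100 else 1
  ok <- is.na(p1) | is.na(p2) |
    (p1 >= 0 & p1 <= top & p2 >= 0 & p2 <= top)
  if (any(!ok)) {
    stop("inputs outside [0, ", top, "]: mixed scales? ",
         "pass scale = 'percent' or 'unit' explicitly")
  }
  sqrt((p1^2 + p2^2) / 2)
}

#' Constraint composite for a table of genes
#'
#' Convenience wrapper: percentile-ranks a LOEUF-like metric (low =
#' constrained) and a conserved-miRNA-targeting-like metric (high =
#' constrained) across genes and combines them with
#' [pythagorean_combine()]. Genes ranking near 100 are jointly sensitive to
#' both diminished function and over-expression.
#'
#' @param metrics data.frame with columns `gene`, `loeuf`, `pct`.
#' @return The input with `loeuf_percentile`, `pct_percentile`, and
#'   `combined_rank_score` columns appended.
#' @export
constraint_composite <- function(metrics) {
  stopifnot(all(c("gene", "loeuf", "pct") %in% colnames(metrics)))
  metrics$loeuf_percentile <- percentile_rank(metrics$loeuf, "low")
  metrics$pct_percentile <- percentile_rank(metrics$pct, "high")
  metrics$combined_rank_score <- pythagorean_combine(
    metrics$loeuf_percentile, metrics$pct_percentile, scale = "percent")
  metrics
}

#' Expression breadth across tissues
#'
#' Breadth = sum of expression across tissues / (maximum tissue expression x
#' number of tissues). The value lies in `[1/N, 1]`: 1 means perfectly
#' uniform expression across all N tissues, 1/N means expression confined to
#' a single tissue. Scale-invariant: multiplying the vector by any positive
#' constant leaves breadth unchanged.
#'
#' @param tpm_by_tissue Non-negative numeric vector of per-tissue TPM, at
#'   least one positive value.
#' @return Breadth in `(0, 1]`, or `NA` (with a warning) for an all-zero
#'   vector.
#' @export
#' @examples
#' expression_breadth(c(5, 5, 5, 5))   # 1
#' expression_breadth(c(10, 0, 0, 0))  # 0.25
expression_breadth <- function(tpm_by_tissue) {
  stopifnot(length(tpm_by_tissue) >= 1L, all(is.finite(tpm_by_tissue)))
  if (any(tpm_by_tissue < 0)) stop("negative TPM value")
  m <- max(tpm_by_tissue)
  if (m == 0) {
    warning("all-zero expression vector: breadth undefined")
    return(NA_real_)
  }
  sum(tpm_by_tissue) / (m * length(tpm_by_tissue))
}

#' Combined expression breadth for an X-Y pair and its avian ortholog
#'
#' Averages the X- and Y-homolog breadths into a pair mean, then combines the
#' pair mean with the breadth of the autosomal ortholog in chicken (a proxy
#' for the ancestral state) via the Pythagorean composite on the unit scale.
#' A missing chicken breadth yields a missing combined score while the pair
#' mean is still reported.
#'
#' @param x_breadth,y_breadth Breadths of the X- and Y-homolog, in `(0, 1]`.
#' @param chicken_breadth Breadth of the chicken ortholog, or `NA`.
#' @return A one-row data.frame with `pair_mean_breadth` and
#'   `cross_species_combined`.
#' @export
pair_breadth <- function(x_breadth, y_breadth, chicken_breadth = NA_real_) {
  for (v in list(x_breadth, y_breadth)) {
    stopifnot(is.na(v) || (v > 0 && v <= 1))
  }
  stopifnot(is.na(chicken_breadth) ||
              (chicken_breadth > 0 && chicken_breadth <= 1))
  pair_mean <- (x_breadth + y_breadth) / 2
  combined <- if (is.na(chicken_breadth) || is.na(pair_mean)) {
    NA_real_
  } else {
    pythagorean_combine(pair_mean, chicken_breadth, scale = "unit")
  }
  data.frame(pair_mean_breadth = pair_mean,
             cross_species_combined = combined)
}

#' Survival metrics for a presence/absence matrix
#'
#' Applies [branch_length()] and [survival_fraction()] to every gene in a
#' presence matrix against one stratum tree.
#'
#' @param tree Rooted `phylo` with branch lengths in MY.
#' @param presence Logical gene x species matrix (see
#'   [read_presence_matrix()]).
#' @return data.frame with `gene`, `observed_branch_length_MY`,
#'   `stratum_max_MY`, `survival_fraction`.
#' @export
survival_table <- function(tree, presence) {
  total <- tree_total_length(tree)
  obs <- vapply(rownames(presence), function(g) {
    branch_length(tree, colnames(presence)[presence[g, ]])
  }, numeric(1))
  data.frame(gene = rownames(presence),
             observed_branch_length_MY = unname(obs),
             stratum_max_MY = total,
             survival_fraction = unname(obs) / total,
             stringsAsFactors = FALSE, row.names = NULL)
}
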