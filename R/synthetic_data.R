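# Synthetic-data generators emulating the statistical structure of the
# inputs the analyses assume: linear expression response to chromosome copy
# number with multiplicative lognormal noise, beta-binomial allele-specific
# counts, knockdown experiments with a tunable cross-compensation
# coefficient, saturation-kinetic labeling timecourses, and random
# phylogenies with presence/absence patterns.

#' Derive a deterministic substream seed
#'
#' One global integer seed drives every generator; per-generator substreams
#' are derived deterministically so that stages can be re-run independently
#' without seed bookkeeping.
#'
#' @param seed Global integer seed.
#' @param stream Character tag naming the substream.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  # modular arithmetic kept below 2^53 so doubles stay exact
  as.integer(((seed %% 2147483647) * 48271 + h * 7919) %% 2147483647)
}

lognormal_factors <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate an aneuploidy expression panel
#'
#' Generates a gene x sample TPM table over a list of sex-chromosome (and
#' chromosome 21) karyotypes. The expected value of gene \eqn{g} in a sample
#' with copy numbers \eqn{(nX, nY)} is
#' \deqn{\beta_0 (1 + \Delta E_X (nX - 1) + \Delta E_Y \, nY),}
#' i.e. expression is linear in added chromosomes relative to a single active
#' X. For designated homolog pairs, a cross-coupling coefficient
#' \eqn{\kappa \in [0, 1]} transfers a fraction of each partner's deviation
#' from its reference (nX = 1, nY = 1) expectation onto the other gene with
#' opposite sign, emulating negative cross-regulation. Noise is multiplicative
#' lognormal with the given coefficient of variation.
#'
#' @param genes data.frame with columns `gene`, `beta0` (baseline TPM > 0),
#'   `dEx`, `dEy` (relative increments per added X / Y).
#' @param karyotypes data.frame with columns `nX`, `nY` and optionally `n21`
#'   (default 2); one row per sample to generate per replicate.
#' @param n_per_karyotype Number of samples per karyotype row.
#' @param cv Coefficient of variation of the multiplicative lognormal noise.
#' @param pairs Optional data.frame with columns `gene_a`, `gene_b`, `kappa`
#'   naming cross-coupled homolog pairs.
#' @param cell_type Annotation label for all samples.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A list with `expr` (gene x sample TPM matrix) and `meta`
#'   (data.frame of per-sample `sample`, `nX`, `nY`, `n21`, `cell_type`,
#'   `condition`).
#' @details An expectation that would go negative (e.g. an X-expressed gene
#'   in an nX = 0 karyotype with strongly negative coupling) is clamped at 0
#'   with a warning.
#' @export
gen_aneuploidy_expression <- function(genes, karyotypes, n_per_karyotype = 1L,
                                      cv = 0.2, pairs = NULL,
                                      cell_type = "fibroblast", seed = 1L) {
  stopifnot(all(c("gene", "beta0", "dEx", "dEy") %in% colnames(genes)),
            all(genes$beta0 > 0), cv >= 0,
            all(c("nX", "nY") %in% colnames(karyotypes)))
  if (!"n21" %in% colnames(karyotypes)) karyotypes$n21 <- 2L
  if (!is.null(pairs)) {
    stopifnot(all(c("gene_a", "gene_b", "kappa") %in% colnames(pairs)),
              all(pairs$kappa >= 0 & pairs$kappa <= 1))
  }
  set.seed(derive_seed(seed, "aneuploidy"))

  kar <- karyotypes[rep(seq_len(nrow(karyotypes)), each = n_per_karyotype), ,
                    drop = FALSE]
  n_samp <- nrow(kar)
  expectation_at <- function(nX, nY) {
    genes$beta0 * (1 + genes$dEx * (nX - 1) + genes$dEy * nY)
  }
  mu <- vapply(seq_len(n_samp),
               function(s) expectation_at(kar$nX[s], kar$nY[s]),
               numeric(nrow(genes)))
  mu <- matrix(mu, nrow = nrow(genes))
  rownames(mu) <- genes$gene

  if (!is.null(pairs)) {
    ref <- expectation_at(1, 1)
    names(ref) <- genes$gene
    for (p in seq_len(nrow(pairs))) {
      a <- pairs$gene_a[p]; b <- pairs$gene_b[p]; k <- pairs$kappa[p]
      dev_a <- mu[a, ] - ref[a]
      dev_b <- mu[b, ] - ref[b]
      mu[a, ] <- mu[a, ] - k * dev_b
      mu[b, ] <- mu[b, ] - k * dev_a
    }
  }
  if (any(mu < 0)) {
    warning("negative expected expression clamped at 0 for ",
            sum(mu < 0), " gene-sample cell(s)")
    mu[mu < 0] <- 0
  }
  noise <- matrix(lognormal_factors(length(mu), cv), nrow = nrow(mu))
  expr <- mu * noise
  colnames(expr) <- sprintf("s%03d_X%dY%d", seq_len(n_samp), kar$nX, kar$nY)
  meta <- data.frame(sample = colnames(expr), nX = kar$nX, nY = kar$nY,
                     n21 = kar$n21, cell_type = cell_type,
                     condition = "control", stringsAsFactors = FALSE,
                     row.names = NULL)
  list(expr = expr, meta = meta)
}

#' Simulate allele-specific read counts at a target Xi/Xa ratio
#'
#' Per sample, total coverage is Poisson around `coverage` and Xi counts are
#' beta-binomial with mean proportion `ar_true / (1 + ar_true)` and
#' overdispersion `rho` (rho = 0 reduces to binomial); Xa counts are the
#' remainder. This emulates allele-specific expression counts summed over
#' informative SNPs for a gene with true allelic ratio `ar_true`.
#'
#' @param ar_true True Xi/Xa ratio, >= 0.
#' @param coverage Mean total reads per sample, > 0.
#' @param overdispersion Beta-binomial intra-class correlation rho in `[0, 1)`.
#' @param n_samples Number of samples.
#' @param seed Integer seed.
#' @return data.frame with columns `sample`, `xi_count`, `xa_count`.
#' @export
gen_allele_counts <- function(ar_true, coverage, overdispersion = 0,
                              n_samples = 1L, seed = 1L) {
  stopifnot(ar_true >= 0, overdispersion >= 0, overdispersion < 1)
  if (coverage <= 0) stop("coverage must be > 0")
  set.seed(derive_seed(seed, "alleles"))
  totals <- pmax(1L, stats::rpois(n_samples, coverage))
  p <- ar_true / (1 + ar_true)
  if (overdispersion > 0 && p > 0 && p < 1) {
    s <- (1 - overdispersion) / overdispersion
    ps <- stats::rbeta(n_samples, p * s, (1 - p) * s)
  } else {
    ps <- rep(p, n_samples)
  }
  xi <- stats::rbinom(n_samples, totals, ps)
  data.frame(sample = sprintf("s%03d", seq_len(n_samples)),
             xi_count = xi, xa_count = totals - xi,
             stringsAsFactors = FALSE)
}

#' Simulate a CRISPRi-style knockdown experiment for a homolog pair
#'
#' The target homolog's mean is reduced by `kd_efficiency`; the partner's
#' mean rises by `kappa` times the absolute expression lost from the target
#' (kappa = 1 is full compensation: the summed pair expectation is unchanged).
#' Multiplicative lognormal noise with coefficient of variation `cv` is
#' applied per replicate.
#'
#' @param control_levels Named numeric of length 2 giving control-mean TPM of
#'   the two homologs, e.g. `c(DDX3X = 100, DDX3Y = 50)`.
#' @param target Name of the knocked-down homolog (must match a name in
#'   `control_levels`).
#' @param kd_efficiency Fraction of target expression removed, in `[0, 1]`.
#' @param kappa Cross-compensation coefficient in `[0, 1]`.
#' @param replicates Replicates per condition.
#' @param cv Lognormal noise CV.
#' @param seed Integer seed.
#' @return A list with `expr` (2 x 2*replicates TPM matrix) and `meta`
#'   (per-sample condition annotation, `control` vs `KD_target:<gene>`).
#' @export
gen_knockdown_experiment <- function(control_levels, target,
                                     kd_efficiency, kappa,
                                     replicates = 3L, cv = 0.1, seed = 1L) {
  stopifnot(length(control_levels) == 2L, !is.null(names(control_levels)),
            target %in% names(control_levels),
            kd_efficiency >= 0, kd_efficiency <= 1,
            kappa >= 0, kappa <= 1, replicates >= 1)
  set.seed(derive_seed(seed, "knockdown"))
  partner <- setdiff(names(control_levels), target)
  loss <- control_levels[[target]] * kd_efficiency
  kd_means <- control_levels
  kd_means[[target]] <- control_levels[[target]] - loss
  kd_means[[partner]] <- control_levels[[partner]] + kappa * loss

  mu <- cbind(matrix(rep(unlist(control_levels), replicates), nrow = 2L),
              matrix(rep(unlist(kd_means), replicates), nrow = 2L))
  rownames(mu) <- names(control_levels)
  expr <- mu * matrix(lognormal_factors(length(mu), cv), nrow = 2L)
  conds <- rep(c("control", paste0("KD_target:", target)),
               each = replicates)
  colnames(expr) <- sprintf("%s_r%d", sub(":", "_", conds),
                            rep(seq_len(replicates), 2L))
  meta <- data.frame(sample = colnames(expr), nX = 1L, nY = 1L, n21 = 2L,
                     cell_type = "fibroblast", condition = conds,
                     stringsAsFactors = FALSE)
  list(expr = expr, meta = meta)
}

#' Simulate a 5-EU metabolic-labeling timecourse
#'
#' Under constant synthesis \eqn{\alpha} and first-order decay \eqn{\beta},
#' labeled (nascent) abundance approaches steady state as
#' \eqn{(\alpha/\beta)(1 - e^{-\beta t})} while total abundance sits at the
#' steady-state level \eqn{\alpha/\beta}. The generator emits nascent, total
#' and spike-in TPM columns per time point; after spike-in normalization the
#' noiseless nascent/total fraction equals \eqn{1 - e^{-\beta t}}, which is 0
#' at t = 0 and 0.5 at one half-life (\eqn{t = \ln 2/\beta}). Noise is
#' multiplicative lognormal on nascent and total TPM.
#'
#' @param beta Decay rate in 1/h, > 0.
#' @param alpha Synthesis rate in TPM/h, > 0 (sets the steady-state scale).
#' @param times Time points in hours, non-negative and strictly increasing.
#' @param spike_scale Spike-in TPM (constant across time points), > 0.
#' @param cv Lognormal noise CV applied to nascent and total TPM.
#' @param replicates Number of independent timecourse replicates.
#' @param gene,condition Labels copied into the output.
#' @param seed Integer seed.
#' @return Long data.frame with columns `gene`, `condition`, `replicate`,
#'   `time_h`, `nascent_tpm`, `total_tpm`, `spike_tpm`.
#' @export
gen_labeling_timecourse <- function(beta, alpha = 100,
                                    times = c(0, 0.5, 1, 1.5, 2, 3.5, 7),
                                    spike_scale = 50, cv = 0.1,
                                    replicates = 1L, gene = "DDX3X",
                                    condition = "46,XY", seed = 1L) {
  stopifnot(beta > 0, alpha > 0, spike_scale > 0, cv >= 0,
            all(times >= 0), !is.unsorted(times, strictly = TRUE))
  set.seed(derive_seed(seed, "labeling"))
  steady <- alpha / beta
  out <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    nascent <- steady * (1 - exp(-beta * times))
    total <- rep(steady, length(times))
    data.frame(gene = gene, condition = condition, replicate = r,
               time_h = times,
               nascent_tpm = nascent * lognormal_factors(length(times), cv),
               total_tpm = total * lognormal_factors(length(times), cv),
               spike_tpm = spike_scale,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a species tree and Y-homolog presence/absence patterns
#'
#' Draws a random rooted tree, rescales its branch lengths to the requested
#' total (the stratum maximum, in MY), and generates gene presence patterns
#' spanning survival fractions in `(0, 1]`: the first gene is present in all
#' species, and the rest are present in random non-empty subsets.
#'
#' @param n_species Number of leaves, >= 3.
#' @param total_length_MY Total branch length the tree is rescaled to.
#' @param n_genes Number of presence patterns to draw.
#' @param seed Integer seed.
#' @return A list with `tree` (`phylo`) and `presence` (logical gene x
#'   species matrix).
#' @export
gen_phylo_fixture <- function(n_species, total_length_MY = 663,
                              n_genes = 10L, seed = 1L) {
  stopifnot(n_species >= 3, total_length_MY > 0, n_genes >= 1)
  set.seed(derive_seed(seed, "phylo"))
  tree <- ape::rtree(n_species, rooted = TRUE)
  tree$edge.length <- tree$edge.length * total_length_MY / sum(tree$edge.length)
  presence <- matrix(FALSE, n_genes, n_species,
                     dimnames = list(sprintf("gene_%02d", seq_len(n_genes)),
                                     tree$tip.label))
  presence[1L, ] <- TRUE
  for (g in seq_len(n_genes)[-1L]) {
    k <- sample.int(n_species, 1L)
    presence[g, sample.int(n_species, k)] <- TRUE
  }
  list(tree = tree, presence = presence)
}
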