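#' Configuration for the coupled expression/mechanics simulator
#'
#' @param n_cells Number of cells (>= 4). Default 91, a typical per-line
#'   cell count in single-cell genomechanics panels.
#' @param genes Character vector of gene identifiers.
#' @param rho Numeric matrix (genes x 3) of target Spearman correlations
#'   between each gene and the mechanical properties, columns `lambda1`,
#'   `lambda2`, `stiffness`; entries in (-1, 1). A vector is accepted for a
#'   single gene.
#' @param mech_meanlog,mech_sdlog Log-normal marginal parameters for the
#'   three mechanical properties (named or positional:
#'   lambda1, lambda2, stiffness). Defaults give medians of about 3 1/s,
#'   0.3 1/s and 1 kPa with right-skewed spread typical of AFM data.
#' @param expr_mean,expr_sd Normal marginal mean and SD of gene expression
#'   on the housekeeping-normalized (-dCt) scale.
#' @param seed Integer RNG seed.
#' @return A list of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_cells = 91L, genes = paste0("G", 1:10),
                                  rho = matrix(0, length(genes), 3),
                                  mech_meanlog = c(lambda1 = log(3),
                                                   lambda2 = log(0.3),
                                                   stiffness = log(1000)),
                                  mech_sdlog = c(0.4, 0.4, 0.5),
                                  expr_mean = 0, expr_sd = 1, seed = 1L) {
  if (n_cells < 4L) gm_stop("n_cells must be >= 4")
  genes <- as.character(genes)
  if (is.vector(rho)) rho <- matrix(rho, nrow = length(genes), ncol = 3,
                                    byrow = length(rho) == 3L)
  if (nrow(rho) != length(genes) || ncol(rho) != 3L) {
    gm_stop("rho must be a genes x 3 matrix (lambda1, lambda2, stiffness)")
  }
  if (any(abs(rho) >= 1)) gm_stop("target Spearman |rho| must be < 1")
  mech_sdlog <- rep_len(mech_sdlog, 3L)
  structure(list(n_cells = as.integer(n_cells), genes = genes, rho = rho,
                 mech_meanlog = mech_meanlog, mech_sdlog = mech_sdlog,
                 expr_mean = expr_mean, expr_sd = expr_sd,
                 seed = as.integer(seed)),
            class = "expression_sim_config")
}

#' Simulate single-cell expression coupled to mechanics by a Gaussian copula
#'
#' Draws a latent multivariate normal over (lambda1, lambda2, stiffness,
#' genes) whose pairwise latent Pearson correlations are
#' r = 2 sin(pi rho_s / 6) - the exact conversion that makes the
#' resulting Gaussian copula reproduce the requested Spearman `rho_s` -
#' then maps the three mechanical coordinates through log-normal marginals
#' and the gene coordinates through normal marginals. Rank correlations are
#' unaffected by these strictly monotone maps.
#'
#' @param config An [expression_sim_config()].
#' @return List with `expression` (data frame `cell_id` + one column per
#'   gene) and `mechanics` (data frame `cell_id`, `lambda1`, `lambda2`,
#'   `e_star`).
#' @export
simulate_expression_mechanics <- function(config) {
  stopifnot(inherits(config, "expression_sim_config"))
  g <- length(config$genes)
  p <- 3L + g
  latent <- diag(p)
  r <- 2 * sin(pi * config$rho / 6)
  latent[seq_len(3L), 3L + seq_len(g)] <- t(r)
  latent[3L + seq_len(g), seq_len(3L)] <- r
  ev <- eigen(latent, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    gm_stop("implied latent correlation matrix is not positive ",
            "semi-definite; reduce the requested |rho| values")
  }
  ch <- chol(latent + diag(1e-12, p))
  z <- with_seed(config$seed,
                 matrix(stats::rnorm(config$n_cells * p), config$n_cells, p)) %*% ch
  cell_id <- sprintf("cell_%03d", seq_len(config$n_cells))
  mech <- data.frame(
    cell_id = cell_id,
    lambda1 = exp(config$mech_meanlog[1L] + config$mech_sdlog[1L] * z[, 1L]),
    lambda2 = exp(config$mech_meanlog[2L] + config$mech_sdlog[2L] * z[, 2L]),
    e_star = exp(config$mech_meanlog[3L] + config$mech_sdlog[3L] * z[, 3L]),
    stringsAsFactors = FALSE)
  expr <- as.data.frame(config$expr_mean + config$expr_sd * z[, 3L + seq_len(g),
                                                              drop = FALSE])
  names(expr) <- config$genes
  expr <- cbind(data.frame(cell_id = cell_id, stringsAsFactors = FALSE), expr)
  list(expression = expr, mechanics = mech)
}

#' Configuration for the qPCR Ct-table simulator
#'
#' @param targets Character vector of assayed target identifiers.
#' @param fold True fold changes (treated vs control), recycled across
#'   targets; fold > 0. A fold of 4 shifts the treated Ct down by 2 cycles.
#' @param target_baseline_ct Control-group Ct per target (recycled).
#' @param housekeeping Named numeric vector of housekeeping baseline Cts,
#'   identical in both groups. Default `c(GAPDH = 18, RPL32 = 20)`.
#' @param replicate_sd Gaussian replicate noise SD in cycles (>= 0).
#' @param n_replicates Replicates per group (>= 2).
#' @param seed Integer RNG seed.
#' @return A list of class `ct_sim_config`.
#' @export
ct_sim_config <- function(targets = c("CDH1", "VIM"), fold = 1,
                          target_baseline_ct = 25,
                          housekeeping = c(GAPDH = 18, RPL32 = 20),
                          replicate_sd = 0, n_replicates = 3L, seed = 1L) {
  targets <- as.character(targets)
  fold <- rep_len(fold, length(targets))
  if (any(fold <= 0)) gm_stop("fold must be > 0")
  check_scalar(replicate_sd, "replicate_sd", nonneg = TRUE)
  if (n_replicates < 2L) gm_stop("n_replicates must be >= 2")
  if (is.null(names(housekeeping))) gm_stop("housekeeping must be named")
  structure(list(targets = targets, fold = fold,
                 target_baseline_ct = rep_len(target_baseline_ct,
                                              length(targets)),
                 housekeeping = housekeeping, replicate_sd = replicate_sd,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "ct_sim_config")
}

#' Simulate a replicated qPCR Ct table
#'
#' Control and treated replicates share housekeeping baselines; each
#' treated target Ct is shifted by `-log2(fold)` relative to control so
#' that the downstream ddCt analysis recovers the configured fold exactly
#' when `replicate_sd = 0`. Gaussian noise of `replicate_sd` cycles is
#' added independently to every Ct.
#'
#' @param config A [ct_sim_config()].
#' @return Long-format data frame with columns `sample_id`, `group`,
#'   `target_id`, `replicate`, `ct`.
#' @export
simulate_ct_table <- function(config) {
  stopifnot(inherits(config, "ct_sim_config"))
  hk <- config$housekeeping
  rows <- list()
  for (group in c("control", "treated")) {
    shift <- if (group == "treated") -log2(config$fold) else rep(0, length(config$fold))
    for (rep_i in seq_len(config$n_replicates)) {
      sample_id <- paste0(group, "_", rep_i)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_id, group = group,
        target_id = c(names(hk), config$targets),
        replicate = rep_i,
        ct = c(unname(hk), config$target_baseline_ct + shift),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (config$replicate_sd > 0) {
    out$ct <- out$ct + with_seed(config$seed,
                                 stats::rnorm(nrow(out), 0,
                                              config$replicate_sd))
  }
  rownames(out) <- NULL
  out
}

#' Configuration for the signed causal-network simulator
#'
#' @param n_regulators Number of upstream regulators.
#' @param n_genes Number of downstream genes in the universe.
#' @param mean_out_degree Target mean number of downstream targets per
#'   regulator.
#' @param skew Power-law exponent of the out-degree distribution
#'   (`P(k) ~ k^-skew` on `1..n_genes`); smaller exponents give heavier
#'   tails, i.e. stronger hub character.
#' @param activation_prob Probability that an edge carries sign +1.
#' @param seed Integer RNG seed.
#' @return A list of class `network_sim_config`.
#' @export
network_sim_config <- function(n_regulators = 20L, n_genes = 100L,
                               mean_out_degree = 8, skew = 2.5,
                               activation_prob = 0.7, seed = 1L) {
  if (n_regulators < 1L || n_genes < 2L) gm_stop("network too small")
  check_scalar(mean_out_degree, "mean_out_degree", positive = TRUE)
  check_scalar(skew, "skew", positive = TRUE)
  if (activation_prob < 0 || activation_prob > 1) {
    gm_stop("activation_prob must lie in [0, 1]")
  }
  structure(list(n_regulators = as.integer(n_regulators),
                 n_genes = as.integer(n_genes),
                 mean_out_degree = mean_out_degree, skew = skew,
                 activation_prob = activation_prob, seed = as.integer(seed)),
            class = "network_sim_config")
}

#' Simulate a signed regulator-target network with hub-skewed degrees
#'
#' Out-degrees are drawn from a discrete power law `P(k) ~ k^-skew`
#' truncated to `[1, n_genes]` and rescaled (rounded, clamped) to the
#' requested mean out-degree; each regulator's targets are then sampled
#' uniformly without replacement, and each edge receives sign +1 with the
#' configured activation probability (-1 otherwise).
#'
#' @param config A [network_sim_config()].
#' @return A [causal_network()] over genes `G1..Gn` and regulators
#'   `R1..Rm`.
#' @export
simulate_network <- function(config) {
  stopifnot(inherits(config, "network_sim_config"))
  genes <- paste0("G", seq_len(config$n_genes))
  regs <- paste0("R", seq_len(config$n_regulators))
  ks <- seq_len(config$n_genes)
  pk <- ks^(-config$skew)
  pk <- pk / sum(pk)
  mu <- sum(ks * pk)
  edges <- with_seed(config$seed, {
    raw <- sample(ks, config$n_regulators, replace = TRUE, prob = pk)
    deg <- pmin(config$n_genes,
                pmax(1L, round(raw * config$mean_out_degree / mu)))
    do.call(rbind, lapply(seq_len(config$n_regulators), function(i) {
      tg <- sample(genes, deg[i])
      data.frame(regulator_id = regs[i], target_gene = tg,
                 sign = ifelse(stats::runif(deg[i]) < config$activation_prob,
                               1L, -1L),
                 molecule_type = "gene", stringsAsFactors = FALSE)
    }))
  })
  causal_network(edges, universe = genes)
}
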