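#' Signed causal regulator-target network
#'
#' A directed, signed edge list: each edge states that a regulator
#' activates (+1) or represses (-1) a downstream gene, as curated from the
#' literature or simulated. Duplicate (regulator, target) pairs are
#' rejected at construction, so conflicting signs cannot be silently
#' merged.
#'
#' @param edges Data frame with columns `regulator_id`, `target_gene`,
#'   `sign` (+1/-1, or the strings `activation`/`inhibition`), and
#'   optionally `molecule_type`.
#' @param universe Character vector of the gene universe; defaults to the
#'   distinct target genes in `edges`. All targets must lie inside it.
#' @return An object of class `causal_network`.
#' @export
causal_network <- function(edges, universe = NULL) {
  check_columns(edges, c("regulator_id", "target_gene", "sign"))
  sgn <- edges$sign
  if (is.character(sgn)) {
    sgn <- ifelse(tolower(sgn) %in% c("activation", "+1", "1", "+"), 1L,
                  ifelse(tolower(sgn) %in% c("inhibition", "-1", "-"), -1L,
                         NA_integer_))
  }
  sgn <- as.integer(sgn)
  if (any(is.na(sgn)) || !all(sgn %in% c(-1L, 1L))) {
    gm_stop("edge signs must be +1/-1 (or activation/inhibition)")
  }
  edges$sign <- sgn
  key <- paste(edges$regulator_id, edges$target_gene, sep = "\r")
  if (anyDuplicated(key)) {
    gm_stop("duplicate (regulator, target) pair(s): ",
            paste(utils::head(sub("\r", " -> ", key[duplicated(key)]), 5L),
                  collapse = ", "))
  }
  if (is.null(edges$molecule_type)) edges$molecule_type <- "unknown"
  universe <- universe %||% sort(unique(edges$target_gene))
  outside <- setdiff(edges$target_gene, universe)
  if (length(outside)) {
    gm_stop("target gene(s) outside the universe: ",
            paste(utils::head(outside, 5L), collapse = ", "))
  }
  structure(list(edges = edges[, c("regulator_id", "target_gene", "sign",
                                   "molecule_type")],
                 universe = as.character(universe)),
            class = "causal_network")
}

#' @export
print.causal_network <- function(x, ...) {
  cat("<causal_network> ", nrow(x$edges), " edges, ",
      length(unique(x$edges$regulator_id)), " regulators, universe of ",
      length(x$universe), " genes\n", sep = "")
  invisible(x)
}

#' Read a signed network from a TSV edge list
#'
#' Expects columns `regulator_id`, `target_gene`, `sign` and optionally
#' `molecule_type`; signs may be +1/-1 or `activation`/`inhibition`
#' strings.
#'
#' @param path File path (tab- or comma-delimited by extension).
#' @param universe Optional gene universe (see [causal_network()]).
#' @return A [causal_network()].
#' @export
read_causal_network <- function(path, universe = NULL) {
  df <- read_table(path, schema = c(regulator_id = "character",
                                    target_gene = "character",
                                    sign = "character"))
  causal_network(df, universe = universe)
}

regulator_edges <- function(network, regulator_id) {
  e <- network$edges[network$edges$regulator_id == regulator_id, ,
                     drop = FALSE]
  if (!nrow(e)) gm_stop("unknown regulator: ", regulator_id)
  e
}

#' Right-tailed overlap p-value between regulator targets and observed genes
#'
#' The probability, under the hypergeometric null of drawing the observed
#' gene set uniformly from the universe, of an overlap with the
#' regulator's target set at least as large as the one observed
#' (right-tailed Fisher's exact test). Zero overlap gives p = 1.
#'
#' @param network A [causal_network()].
#' @param observed_genes Character vector of observed genes, a subset of
#'   the universe.
#' @param universe_size Size of the gene universe; defaults to the
#'   network's universe. Must be at least as large as both sets.
#' @return Named numeric vector of p-values, one per regulator.
#' @export
overlap_pvalue <- function(network, observed_genes, universe_size = NULL) {
  stopifnot(inherits(network, "causal_network"))
  observed_genes <- unique(observed_genes)
  if (is.null(universe_size)) {
    outside <- setdiff(observed_genes, network$universe)
    if (length(outside)) {
      gm_stop("observed gene(s) outside the universe: ",
              paste(utils::head(outside, 5L), collapse = ", "))
    }
    universe_size <- length(network$universe)
  }
  n_obs <- length(observed_genes)
  regs <- unique(network$edges$regulator_id)
  vapply(regs, function(rg) {
    targets <- unique(regulator_edges(network, rg)$target_gene)
    k_targets <- length(targets)
    if (universe_size < max(k_targets, n_obs)) {
      gm_stop("universe smaller than the target or observed set")
    }
    k_overlap <- length(intersect(targets, observed_genes))
    stats::phyper(k_overlap - 1L, k_targets, universe_size - k_targets,
                  n_obs, lower.tail = FALSE)
  }, numeric(1))
}

#' Activation z-score of a regulator against observed gene directions
#'
#' Over the regulator's edges whose targets carry an observed direction,
#' an edge is consistent when `edge sign x observed direction = +1`. With
#' `N+` consistent and `N-` inconsistent edges among `N = N+ + N-`,
#' \deqn{z = (N^+ - N^-) / \sqrt{N}.}
#' Positive z means the regulator's known effects line up with the
#' observed up/down pattern (predicted activated); `z = 0` with state
#' `"none"` when no target has an observed direction.
#'
#' @param network A [causal_network()].
#' @param observed Data frame with columns `gene`, `direction` (+1/-1),
#'   one row per gene.
#' @param regulator_id Regulator to score; must exist in the network.
#' @return List with `z`, `n_plus`, `n_minus`, `n`.
#' @export
activation_z <- function(network, observed, regulator_id) {
  stopifnot(inherits(network, "causal_network"))
  check_columns(observed, c("gene", "direction"))
  if (anyDuplicated(observed$gene)) {
    gm_stop("observed must have one record per gene")
  }
  e <- regulator_edges(network, regulator_id)
  dir <- observed$direction[match(e$target_gene, observed$gene)]
  keep <- !is.na(dir)
  n <- sum(keep)
  if (n == 0L) return(list(z = 0, n_plus = 0L, n_minus = 0L, n = 0L))
  consistent <- e$sign[keep] * dir[keep] == 1
  n_plus <- sum(consistent)
  n_minus <- n - n_plus
  list(z = (n_plus - n_minus) / sqrt(n), n_plus = n_plus, n_minus = n_minus,
       n = n)
}

#' Permutation hub-bias-corrected p-value for a regulator's z-score
#'
#' Genes targeted by many regulators ("hub character") inflate naive
#' overlap statistics; this empirical correction keeps the network's
#' degree structure and the observed up/down counts fixed and asks how
#' often a random reassignment of the observed directions across the
#' observed genes yields an activation z at least as extreme:
#' `p = (1 + #permutations with |z*| >= |z|) / (n_perm + 1)` (two-sided,
#' add-one so p is never exactly zero). Seeded and reproducible.
#'
#' @param network A [causal_network()].
#' @param observed Observed gene directions (see [activation_z()]).
#' @param regulator_id Regulator to score.
#' @param n_perm Number of permutations (>= 100). Default 10000.
#' @param seed Integer RNG seed.
#' @return The bias-corrected p-value. Regulators with no observed target
#'   (`N = 0`) get p = 1 with a warning.
#' @export
bias_corrected_p <- function(network, observed, regulator_id,
                             n_perm = 10000L, seed = 1L) {
  if (n_perm < 100L) gm_stop("n_perm must be >= 100")
  score <- activation_z(network, observed, regulator_id)
  if (score$n == 0L) {
    gm_warn("regulator '", regulator_id,
            "' has no target with an observed direction; p = 1")
    return(1)
  }
  e <- regulator_edges(network, regulator_id)
  pos <- match(e$target_gene, observed$gene)
  keep <- !is.na(pos)
  signs <- e$sign[keep]
  pos <- pos[keep]
  dirs <- observed$direction
  sqrt_n <- sqrt(score$n)
  z_obs <- abs(score$z)
  hits <- with_seed(seed, {
    h <- 0L
    for (b in seq_len(n_perm)) {
      zb <- sum(signs * sample(dirs)[pos]) / sqrt_n
      if (abs(zb) >= z_obs - 1e-12) h <- h + 1L
    }
    h
  })
  (1 + hits) / (n_perm + 1)
}

#' Score every regulator of a network against observed gene directions
#'
#' Computes, per regulator: overlap counts, activation z-score,
#' right-tailed hypergeometric overlap p, and the permutation
#' bias-corrected p.
#'
#' @inheritParams bias_corrected_p
#' @param universe_size Optional universe override for [overlap_pvalue()].
#' @return Data frame with columns `regulator_id`, `molecule_type`, `n`,
#'   `n_plus`, `n_minus`, `z`, `p_overlap`, `p_bias_corrected`,
#'   `predicted_state` (filled by [filter_significant()]; `"none"` here).
#' @export
score_regulators <- function(network, observed, n_perm = 10000L, seed = 1L,
                             universe_size = NULL) {
  stopifnot(inherits(network, "causal_network"))
  regs <- unique(network$edges$regulator_id)
  p_over <- overlap_pvalue(network, observed$gene, universe_size)
  rows <- lapply(seq_along(regs), function(i) {
    rg <- regs[i]
    sc <- activation_z(network, observed, rg)
    pb <- if (sc$n == 0L) 1 else bias_corrected_p(network, observed, rg,
                                                  n_perm = n_perm,
                                                  seed = seed + i)
    data.frame(regulator_id = rg,
               molecule_type = network$edges$molecule_type[
                 match(rg, network$edges$regulator_id)],
               n = sc$n, n_plus = sc$n_plus, n_minus = sc$n_minus,
               z = sc$z, p_overlap = unname(p_over[rg]),
               p_bias_corrected = pb, predicted_state = "none",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter regulator scores down to significant control nodes
#'
#' Retains regulators with bias-corrected p below `p_max` and absolute
#' activation z-score of at least `z_min` (boundary `|z| = z_min`
#' retained), and labels each retained regulator `activated` (z > 0) or
#' `inhibited` (z < 0).
#'
#' @param scores Data frame from [score_regulators()].
#' @param z_min Minimum absolute z. Default 2.
#' @param p_max Maximum bias-corrected p. Default 0.01.
#' @return The retained rows with `predicted_state` filled in.
#' @export
filter_significant <- function(scores, z_min = 2, p_max = 0.01) {
  check_columns(scores, c("regulator_id", "z", "p_bias_corrected"))
  keep <- abs(scores$z) >= z_min & scores$p_bias_corrected < p_max
  out <- scores[keep, , drop = FALSE]
  out$predicted_state <- ifelse(out$z > 0, "activated", "inhibited")
  rownames(out) <- NULL
  out
}

#' Predicted change of the mechanical property under an intervention
#'
#' A regulator with positive activation z-score supports the observed
#' positively correlated gene pattern, so activating it is predicted to
#' increase the property and inhibiting it to decrease it; the signs flip
#' for negative z (inhibiting a negative-z regulator predicts an
#' increase).
#'
#' @param score A regulator score (any list/row with a nonzero `z`).
#' @param intervention `"activate"` or `"inhibit"`.
#' @return `"increase"` or `"decrease"`.
#' @export
predict_mechanical_change <- function(score, intervention = c("activate",
                                                              "inhibit")) {
  intervention <- match.arg(intervention)
  z <- if (is.list(score) || is.data.frame(score)) score$z else score
  if (!is.finite(z) || z == 0) {
    gm_stop("no direction: regulator z-score is zero")
  }
  up <- (z > 0) == (intervention == "activate")
  if (up) "increase" else "decrease"
}
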