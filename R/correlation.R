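#' Spearman screen of genes against mechanical properties
#'
#' For every gene x property pair, computes the Spearman rank correlation
#' (average ranks for ties) over complete cases and a two-sided p-value:
#' by exhaustive enumeration of all rank permutations when the
#' complete-case n is at most `exact_n_max` (exact under the permutation
#' null), and by the usual t-approximation
#' `t = rho sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of freedom otherwise.
#' Pairs with fewer than 4 complete cases, or with a constant vector (zero
#' rank variance), are skipped with a warning.
#'
#' @param expression Data frame of cells x genes with a `cell_id` first
#'   column (housekeeping-normalized expression; `NA` allowed).
#' @param mechanics Data frame with `cell_id`, `lambda1`, `lambda2`,
#'   `e_star` per cell.
#' @param alpha Significance level used to flag records. Default 0.05.
#' @param exact_n_max Largest n for exact permutation p-values. Default 8.
#' @param adjust Optional multiple-testing correction passed to
#'   [stats::p.adjust()] (e.g. `"holm"`); the default `"none"` screens at
#'   raw p as is standard for this screen.
#' @return Data frame of correlation records: `gene`, `property`
#'   (`lambda1`, `lambda2`, `stiffness`), `rho`, `p`, `n`, `significant`.
#' @export
spearman_screen <- function(expression, mechanics, alpha = 0.05,
                            exact_n_max = 8L, adjust = "none") {
  check_columns(expression, "cell_id")
  check_columns(mechanics, c("cell_id", "lambda1", "lambda2", "e_star"))
  m <- match(expression$cell_id, mechanics$cell_id)
  if (any(is.na(m))) gm_stop("expression cell_ids missing from mechanics table")
  mech <- mechanics[m, , drop = FALSE]
  props <- c(lambda1 = "lambda1", lambda2 = "lambda2", stiffness = "e_star")
  genes <- setdiff(names(expression), "cell_id")
  rows <- list()
  for (gene in genes) {
    x_all <- expression[[gene]]
    for (pn in names(props)) {
      y_all <- mech[[props[[pn]]]]
      ok <- is.finite(x_all) & is.finite(y_all)
      n <- sum(ok)
      if (n < 4L) {
        gm_warn("skipping ", gene, " x ", pn, ": fewer than 4 complete cases")
        next
      }
      x <- x_all[ok]
      y <- y_all[ok]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        gm_warn("skipping ", gene, " x ", pn,
                ": constant vector, rho undefined")
        next
      }
      st <- spearman_test(x, y, exact_n_max = exact_n_max)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, property = pn, rho = st$rho, p = st$p, n = n,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) gm_stop("no testable gene-property pairs")
  out$p <- stats::p.adjust(out$p, method = adjust)
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}

# Spearman rho (average ranks) with exact permutation p for small n.
# The exact two-sided p is the proportion of the n! equally likely rank
# permutations whose |rho*| matches or exceeds the observed |rho|.
spearman_test <- function(x, y, exact_n_max = 8L) {
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_n_max) {
    perms <- permutations_of(n)
    ryc <- ry - mean(ry)
    rxc <- rx - mean(rx)
    # rho over all permutations of one rank vector, vectorized
    num <- matrix(ryc[perms], nrow = nrow(perms)) %*% rxc
    rho_all <- as.vector(num) / sqrt(sum(rxc^2) * sum(ryc^2))
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = min(p, 1))
}

#' Partition significant genes into unique and multiple property sets
#'
#' Builds the per-property significant gene sets at `p < alpha` and
#' partitions their union: a gene significant for exactly one property is
#' unique to it; genes significant for two or more fall in the `multiple`
#' block. The partition conserves counts: each property's significant count
#' equals its unique block plus its members of the multiple block.
#'
#' @param records Correlation records from [spearman_screen()].
#' @param alpha Significance level. Default 0.05.
#' @return List of class `property_gene_sets` with `significant` (named
#'   list of per-property gene sets), `partition` (`unique_lambda1`,
#'   `unique_lambda2`, `unique_stiffness`, `multiple`), and `counts`.
#' @export
classify_sets <- function(records, alpha = 0.05) {
  check_columns(records, c("gene", "property", "p"))
  props <- c("lambda1", "lambda2", "stiffness")
  sig <- lapply(props, function(pn) {
    sort(unique(records$gene[records$property == pn & records$p < alpha]))
  })
  names(sig) <- props
  all_sig <- sort(unique(unlist(sig)))
  n_props <- vapply(all_sig, function(g) {
    sum(vapply(sig, function(s) g %in% s, logical(1)))
  }, integer(1))
  partition <- list(
    unique_lambda1 = all_sig[n_props == 1L & all_sig %in% sig$lambda1],
    unique_lambda2 = all_sig[n_props == 1L & all_sig %in% sig$lambda2],
    unique_stiffness = all_sig[n_props == 1L & all_sig %in% sig$stiffness],
    multiple = all_sig[n_props >= 2L])
  counts <- list(
    per_property = vapply(sig, length, integer(1)),
    unique = stats::setNames(vapply(partition[1:3], length, integer(1)),
                             props),
    multiple = length(partition$multiple),
    union = length(all_sig),
    in_exactly_two = sum(n_props == 2L),
    in_all_three = sum(n_props == 3L))
  structure(list(significant = sig, partition = partition, counts = counts),
            class = "property_gene_sets")
}

#' @export
print.property_gene_sets <- function(x, ...) {
  cat("<property_gene_sets> union of", x$counts$union, "significant genes\n")
  cat("  per property:",
      paste(names(x$counts$per_property), x$counts$per_property,
            sep = " = ", collapse = ", "), "\n")
  cat("  unique:",
      paste(names(x$counts$unique), x$counts$unique, sep = " = ",
            collapse = ", "),
      "; multiple =", x$counts$multiple, "\n")
  invisible(x)
}
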