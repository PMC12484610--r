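#' Housekeeping-normalized delta-Ct values
#'
#' For every measurement unit (a `sample_id`/`replicate` pair) and every
#' non-housekeeping target, computes
#' `delta_ct = ct_target - mean(ct over housekeeping genes)`. The
#' arithmetic mean of housekeeping Cts is exactly the geometric mean of
#' housekeeping expression on the 2^-Ct scale. Passing a single
#' housekeeping id gives the single-reference mode used for miRNA assays
#' (e.g. normalization to RNU6B).
#'
#' @param ct_table Long-format data frame with columns `sample_id`,
#'   `group`, `target_id`, `replicate`, `ct` (cycles, finite, > 0).
#' @param housekeeping Character vector of housekeeping target ids; every
#'   measurement unit must carry a Ct for each of them.
#' @return Data frame with columns `sample_id`, `group`, `replicate`,
#'   `target_id`, `delta_ct`.
#' @export
delta_ct <- function(ct_table, housekeeping = c("GAPDH", "RPL32")) {
  check_columns(ct_table, c("sample_id", "group", "target_id", "replicate",
                            "ct"))
  if (any(!is.finite(ct_table$ct)) || any(ct_table$ct <= 0)) {
    gm_stop("ct values must be finite and > 0")
  }
  if (!length(housekeeping)) gm_stop("at least one housekeeping id required")
  unit <- interaction(ct_table$sample_id, ct_table$replicate, drop = TRUE)
  out <- lapply(split(ct_table, unit), function(block) {
    hk <- block$ct[match(housekeeping, block$target_id)]
    if (any(is.na(hk))) {
      gm_stop("sample '", block$sample_id[1L],
              "' (replicate ", block$replicate[1L],
              ") is missing housekeeping measurement(s): ",
              paste(housekeeping[is.na(hk)], collapse = ", "))
    }
    tgt <- block[!(block$target_id %in% housekeeping), , drop = FALSE]
    data.frame(sample_id = tgt$sample_id, group = tgt$group,
               replicate = tgt$replicate, target_id = tgt$target_id,
               delta_ct = tgt$ct - mean(hk), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Delta-delta-Ct fold change between groups
#'
#' `ddct = mean(treated delta_ct) - mean(control delta_ct)` and
#' `fold = 2^-ddct` for one target, assuming the ideal PCR efficiency of 2.
#'
#' @param control,treated Data frames of delta-Ct records (see
#'   [delta_ct()]), or one combined data frame with a `group` column passed
#'   as `control` with `treated = NULL`.
#' @param target_id Target to contrast; must appear in both groups.
#' @return List with `target_id`, `ddct`, `fold`.
#' @export
ddct_fold <- function(control, treated = NULL, target_id) {
  if (is.null(treated)) {
    treated <- control[control$group == "treated", , drop = FALSE]
    control <- control[control$group == "control", , drop = FALSE]
  }
  dc <- control$delta_ct[control$target_id == target_id]
  dt <- treated$delta_ct[treated$target_id == target_id]
  if (!length(dc) || !length(dt)) {
    gm_stop("target '", target_id, "' absent from ",
            if (!length(dc)) "control" else "treated", " group")
  }
  ddct <- mean(dt) - mean(dc)
  list(target_id = target_id, ddct = ddct, fold = 2^(-ddct))
}

#' Propagate Ct replicate SDs to the fold-change scale
#'
#' Independent-error quadrature through the ddCt chain followed by a
#' first-order delta method for the exponential transform:
#' `sd_dct = sqrt(sd_target^2 + sd_ref^2)` within each group,
#' `sd_ddct = sqrt(sd_dct_control^2 + sd_dct_treated^2)`, and
#' `fold_sd = fold * ln(2) * sd_ddct`.
#'
#' @param fold Point-estimate fold change (> 0).
#' @param sd_target_control,sd_ref_control Control-group SDs (cycles) of
#'   the target Ct and of the housekeeping reference mean.
#' @param sd_target_treated,sd_ref_treated Same for the treated group.
#' @return List with `sd_dct_control`, `sd_dct_treated`, `sd_ddct`,
#'   `fold_sd`.
#' @export
propagate_fold_sd <- function(fold, sd_target_control, sd_ref_control = 0,
                              sd_target_treated, sd_ref_treated = 0) {
  sds <- c(sd_target_control, sd_ref_control, sd_target_treated,
           sd_ref_treated)
  if (any(!is.finite(sds)) || any(sds < 0)) gm_stop("SDs must be >= 0")
  check_scalar(fold, "fold", positive = TRUE)
  sd_dct_c <- sqrt(sd_target_control^2 + sd_ref_control^2)
  sd_dct_t <- sqrt(sd_target_treated^2 + sd_ref_treated^2)
  sd_ddct <- sqrt(sd_dct_c^2 + sd_dct_t^2)
  list(sd_dct_control = sd_dct_c, sd_dct_treated = sd_dct_t,
       sd_ddct = sd_ddct, fold_sd = fold * log(2) * sd_ddct)
}

#' Welch test on replicate delta-Ct values
#'
#' Two-sided Welch two-sample t-test contrasting the replicate-level
#' delta-Ct values of the two groups (see [welch_t()]).
#'
#' @param control_dct,treated_dct Numeric vectors of delta-Ct replicates
#'   (at least 2 values each).
#' @return The two-sided p-value.
#' @export
welch_on_dct <- function(control_dct, treated_dct) {
  welch_t(control_dct, treated_dct)$p
}

#' Twofold expression-change flag
#'
#' `"up"` when fold >= 2, `"down"` when fold <= 0.5 (both boundaries
#' inclusive), `"none"` otherwise.
#'
#' @param fold Fold change(s), > 0; vectorized.
#' @return Character vector in `{"up", "down", "none"}`.
#' @export
flag_threshold <- function(fold) {
  if (any(!is.finite(fold)) || any(fold <= 0)) gm_stop("fold must be > 0")
  ifelse(fold >= 2, "up", ifelse(fold <= 0.5, "down", "none"))
}

#' Full per-target fold-change table from a Ct table
#'
#' Runs the complete ddCt workflow: housekeeping normalization, per-target
#' ddCt and fold, replicate-SD error propagation, Welch significance test,
#' twofold threshold flag, and (when predictions are supplied) alignment
#' with predicted directions.
#'
#' @param ct_table Long-format Ct table (see [delta_ct()]).
#' @param housekeeping Housekeeping target ids.
#' @param predictions Optional named character vector of predicted
#'   directions per target (`"up"`/`"down"`, or `+1`/`-1`).
#' @param alpha Significance level for the Welch test. Default 0.05.
#' @return Data frame with one row per target: `target_id`, `ddct`, `fold`,
#'   `fold_sd`, `p_welch`, `threshold_flag`, `prediction`, `alignment`.
#' @export
fold_change_table <- function(ct_table, housekeeping = c("GAPDH", "RPL32"),
                              predictions = NULL, alpha = 0.05) {
  dct <- delta_ct(ct_table, housekeeping)
  targets <- unique(dct$target_id)
  rows <- lapply(targets, function(tg) {
    sub <- dct[dct$target_id == tg, , drop = FALSE]
    ctrl <- sub$delta_ct[sub$group == "control"]
    trt <- sub$delta_ct[sub$group == "treated"]
    fc <- ddct_fold(sub, target_id = tg)
    # replicate delta-Ct SDs already contain the housekeeping contribution,
    # so the reference terms of the quadrature are not double-counted here
    prop <- propagate_fold_sd(fc$fold,
                              sd_target_control = stats::sd(ctrl),
                              sd_target_treated = stats::sd(trt))
    p <- if (length(ctrl) >= 2 && length(trt) >= 2) {
      welch_on_dct(ctrl, trt)
    } else NA_real_
    data.frame(target_id = tg, ddct = fc$ddct, fold = fc$fold,
               fold_sd = prop$fold_sd, p_welch = p,
               threshold_flag = flag_threshold(fc$fold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  align <- alignment_vs_prediction(out, predictions, alpha = alpha)
  out$prediction <- align$per_target$prediction
  out$alignment <- align$per_target$alignment
  rownames(out) <- NULL
  out
}

normalize_direction <- function(x) {
  if (is.numeric(x)) return(ifelse(x > 0, "up", ifelse(x < 0, "down", "none")))
  x <- tolower(as.character(x))
  ifelse(x %in% c("up", "increase", "increased", "activated", "+1", "1"), "up",
         ifelse(x %in% c("down", "decrease", "decreased", "inhibited", "-1"),
                "down", "none"))
}

#' Alignment of observed fold changes with network predictions
#'
#' A target is `aligned` when its change is significant (Welch p < alpha)
#' and the observed direction (fold above or below 1) matches the
#' prediction; `misaligned` when significant and opposite;
#' `not_significant` otherwise; `no_prediction` when no direction was
#' supplied. The condition summary is `aligned` if all significant
#' predicted targets align, `misaligned` if none do, `mixed` otherwise.
#'
#' @param results Data frame with `target_id`, `fold`, `p_welch`.
#' @param predictions Named vector of predicted directions, or `NULL`.
#' @param alpha Significance level. Default 0.05.
#' @return List with `per_target` (data frame `target_id`, `prediction`,
#'   `alignment`) and `summary` (one of `"aligned"`, `"misaligned"`,
#'   `"mixed"`, `"no_prediction"`).
#' @export
alignment_vs_prediction <- function(results, predictions = NULL,
                                    alpha = 0.05) {
  check_columns(results, c("target_id", "fold", "p_welch"))
  pred <- rep("none", nrow(results))
  if (!is.null(predictions)) {
    m <- match(results$target_id, names(predictions))
    pred[!is.na(m)] <- normalize_direction(predictions[m[!is.na(m)]])
  }
  observed <- ifelse(results$fold > 1, "up", ifelse(results$fold < 1, "down",
                                                    "none"))
  signif <- !is.na(results$p_welch) & results$p_welch < alpha
  alignment <- ifelse(pred == "none", "no_prediction",
                      ifelse(!signif, "not_significant",
                             ifelse(observed == pred, "aligned",
                                    "misaligned")))
  judged <- alignment[alignment %in% c("aligned", "misaligned")]
  summary <- if (!length(judged)) {
    if (all(pred == "none")) "no_prediction" else "not_significant"
  } else if (all(judged == "aligned")) {
    "aligned"
  } else if (all(judged == "misaligned")) {
    "misaligned"
  } else "mixed"
  list(per_target = data.frame(target_id = results$target_id,
                               prediction = pred, alignment = alignment,
                               stringsAsFactors = FALSE),
       summary = summary)
}
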