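#' Read a schema-checked delimited table
#'
#' CSV (comma) or TSV (tab, for `.tsv`/`.tab` extensions), UTF-8, header
#' required. Missing required columns raise an error naming both the
#' column and the file; declared numeric columns are coerced and checked.
#'
#' @param path File path.
#' @param schema Named character vector mapping required column names to
#'   types (`"numeric"`, `"integer"`, `"character"`). Extra columns in the
#'   file are kept as read.
#' @return Data frame of typed rows.
#' @export
read_table <- function(path, schema = NULL) {
  if (!file.exists(path)) gm_stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          encoding = "UTF-8")
  if (!is.null(schema)) {
    check_columns(df, names(schema), file = path)
    for (col in names(schema)) {
      df[[col]] <- switch(schema[[col]],
                          numeric = as.numeric(df[[col]]),
                          integer = as.integer(df[[col]]),
                          character = as.character(df[[col]]),
                          gm_stop("unknown schema type: ", schema[[col]]))
      if (schema[[col]] %in% c("numeric", "integer") &&
          anyNA(df[[col]]) && !anyNA(utils::type.convert(df[[col]],
                                                         as.is = TRUE))) {
        gm_stop("column '", col, "' in '", path, "' is not numeric")
      }
    }
  }
  df
}

#' Write a delimited table losslessly
#'
#' Writes CSV (or TSV for `.tsv`/`.tab` paths) with a header row; numeric
#' columns are serialized with 17 significant digits so finite doubles
#' round-trip within 1 ulp through [read_table()].
#'
#' @param df Data frame.
#' @param path Output path; parent directories are created.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  out <- df
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# fixed per-stage seed offsets: every stage derives its own stream from the
# single pipeline seed so stages stay independently reproducible
.stage_seed_offsets <- c(curves = 101L, omics = 202L, ct = 303L,
                         network = 404L, perms = 505L)

stage_seed <- function(seed, stage) {
  unname(seed + .stage_seed_offsets[[stage]])
}

#' Pipeline configuration
#'
#' Validates a (possibly nested) configuration for [run_pipeline()]
#' against the known keys; unknown keys raise an error naming every
#' offender.
#'
#' @param config Named list, or path to a JSON file holding one. Top-level
#'   keys: `seed` (non-negative integer), `out_dir`, `n_curves`,
#'   `mechanics` (keys of [mechanics_config()]), `curve` (keys of
#'   [curve_sim_config()], minus seed), `expression_sim` (keys of
#'   [expression_sim_config()], minus seed), `ct_sim` (keys of
#'   [ct_sim_config()], minus seed), `network_sim` (keys of
#'   [network_sim_config()], minus seed), `regulators` (`z_min`, `p_max`,
#'   `n_perm`), `alpha`.
#' @return Validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  allowed <- list(
    seed = NULL, out_dir = NULL, n_curves = NULL, alpha = NULL,
    mechanics = names(formals(mechanics_config)),
    curve = setdiff(names(formals(curve_sim_config)), "seed"),
    expression_sim = setdiff(names(formals(expression_sim_config)), "seed"),
    ct_sim = setdiff(names(formals(ct_sim_config)), "seed"),
    network_sim = setdiff(names(formals(network_sim_config)), "seed"),
    regulators = c("z_min", "p_max", "n_perm"))
  bad <- setdiff(names(config), names(allowed))
  for (section in intersect(names(config), names(allowed))) {
    keys <- allowed[[section]]
    if (!is.null(keys) && is.list(config[[section]])) {
      extra <- setdiff(names(config[[section]]), keys)
      if (length(extra)) bad <- c(bad, paste0(section, ".", extra))
    }
  }
  if (length(bad)) {
    gm_stop("invalid configuration key(s): ", paste(bad, collapse = ", "))
  }
  config$seed <- config$seed %||% 1L
  if (config$seed < 0 || config$seed != round(config$seed)) {
    gm_stop("seed must be a non-negative integer")
  }
  config$out_dir <- config$out_dir %||% tempfile("genomechanics_run_")
  config$n_curves <- config$n_curves %||% 5L
  config$alpha <- config$alpha %||% 0.05
  class(config) <- "pipeline_config"
  config
}

#' Run the demonstration pipeline end to end
#'
#' Executes the stages in dependency order on simulated inputs: force-curve
#' simulation, mechanical fitting (Hertz + SLS), coupled
#' expression/mechanics simulation, the Spearman screen with set
#' partitioning, Ct-table simulation with ddCt fold changes, network
#' simulation with regulator scoring and filtering. Every intermediate
#' table is written under `out_dir`, and a JSON manifest records the
#' package version, the seed, the derived per-stage seeds, the thresholds
#' applied, and every output file. All randomness flows from the single
#' pipeline seed through fixed per-stage offsets; rerunning with the same
#' configuration reproduces byte-identical tables.
#'
#' @param config A [pipeline_config()] (or list/JSON path coercible to
#'   one).
#' @return The manifest, invisibly; also written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- vapply(names(.stage_seed_offsets), function(s)
    stage_seed(cfg$seed, s), numeric(1))
  outputs <- character(0)
  emit <- function(df, name) {
    p <- file.path(cfg$out_dir, name)
    write_table(df, p)
    outputs <<- c(outputs, name)
  }

  # stage 1: simulate and fit force curves
  mech_cfg <- do.call(mechanics_config, cfg$mechanics %||% list())
  curves <- lapply(seq_len(cfg$n_curves), function(i) {
    args <- cfg$curve %||% list()
    args$seed <- seeds[["curves"]] + i
    simulate_force_curve(do.call(curve_sim_config, args))
  })
  mech_records <- analyze_curves(curves, config = mech_cfg)
  emit(mech_records, "mechanics.csv")

  # stage 2: simulate coupled expression/mechanics and screen correlations
  eargs <- cfg$expression_sim %||% list()
  eargs$seed <- seeds[["omics"]]
  omics <- simulate_expression_mechanics(do.call(expression_sim_config, eargs))
  emit(omics$expression, "expression.csv")
  emit(omics$mechanics, "cell_mechanics.csv")
  records <- spearman_screen(omics$expression, omics$mechanics,
                             alpha = cfg$alpha)
  emit(records, "correlations.csv")
  sets <- classify_sets(records, alpha = cfg$alpha)
  jsonlite::write_json(sets[c("significant", "partition", "counts")],
                       file.path(cfg$out_dir, "gene_sets.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  outputs <- c(outputs, "gene_sets.json")

  # stage 3: simulate a Ct table and quantify fold changes
  cargs <- cfg$ct_sim %||% list(replicate_sd = 0.3)
  cargs$seed <- seeds[["ct"]]
  ct <- simulate_ct_table(do.call(ct_sim_config, cargs))
  emit(ct, "ct_table.csv")
  emit(fold_change_table(ct, alpha = cfg$alpha), "fold_changes.csv")

  # stage 4: simulate a signed network and score regulators against the
  # directions of the significant stiffness correlations
  nargs <- cfg$network_sim %||% list()
  nargs$seed <- seeds[["network"]]
  net <- simulate_network(do.call(network_sim_config, nargs))
  stiff <- records[records$property == "stiffness", , drop = FALSE]
  sig <- stiff[stiff$significant & stiff$gene %in% net$universe, ,
               drop = FALSE]
  observed <- if (nrow(sig)) {
    data.frame(gene = sig$gene, direction = ifelse(sig$rho > 0, 1L, -1L),
               stringsAsFactors = FALSE)
  } else {  # degenerate screen: fall back to the strongest correlations
    top <- stiff[order(stiff$p)[seq_len(min(5L, nrow(stiff)))], ,
                 drop = FALSE]
    data.frame(gene = top$gene, direction = ifelse(top$rho > 0, 1L, -1L),
               stringsAsFactors = FALSE)
  }
  observed <- observed[observed$gene %in% net$universe, , drop = FALSE]
  rargs <- cfg$regulators %||% list()
  scores <- score_regulators(net, observed,
                             n_perm = rargs$n_perm %||% 1000L,
                             seed = seeds[["perms"]])
  emit(scores, "regulator_scores.csv")
  emit(filter_significant(scores, z_min = rargs$z_min %||% 2,
                          p_max = rargs$p_max %||% 0.01),
       "control_nodes.csv")

  manifest <- list(
    package = "genomechanics",
    version = as.character(utils::packageVersion("genomechanics")),
    seed = cfg$seed, stage_seeds = as.list(seeds),
    thresholds = list(alpha = cfg$alpha,
                      z_min = rargs$z_min %||% 2,
                      p_max = rargs$p_max %||% 0.01,
                      rss_threshold_n2 = mech_cfg$rss_threshold_n2),
    n_curves = cfg$n_curves, outputs = outputs)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
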