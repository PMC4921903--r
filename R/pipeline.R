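#' Run the full analysis pipeline from a config
#'
#' Orchestrates the stages — optional synthetic-data simulation, fold-change
#' classification, TF activity inference per condition, and the
#' two-condition coherence analysis — into one reproducible run. All stage
#' outputs are written as deterministic TSV (see [write_table()]) together
#' with a manifest (config hash, seed, package version) and a `warnings.tsv`
#' collecting dropped TFs, non-convergence and omitted coherence points, so
#' a rerun with an identical config reproduces every file draw-for-draw.
#'
#' The config (YAML file or equivalent list) supports the keys:
#' `schema_version` (must be 1), `seed` (mandatory), `output_dir`,
#' `simulate` (passed to [tfa_sim_config()]; generates the inputs),
#' `expression` (named paths `A` and optionally `B`), `regulon` (path),
#' `categories` (path, optional), `genes_of_interest` (optional, exported as
#' time strips), `diffexpr` (`up_threshold`, `down_threshold`), `model`
#' (arguments of [tfa_control()] plus `chains`), `coherence` (`d_threshold`,
#' `m_threshold`). Unknown keys are errors, not silently ignored.
#'
#' @param config path to a YAML config file, or a list with the same
#'   structure.
#' @param output_dir overrides the config's output directory.
#' @return the output directory, invisibly; the written files are
#'   `calls_<cond>.tsv`, `fractions_<cond>.tsv`, `categories_<cond>.tsv`,
#'   `strips_<cond>.tsv` (if requested), `activities_<cond>.tsv`,
#'   `diagnostics_<cond>.tsv`, `coherence.tsv` (two conditions),
#'   `manifest.tsv` and `warnings.tsv`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  known <- c("schema_version", "seed", "output_dir", "simulate", "expression",
             "regulon", "categories", "genes_of_interest", "diffexpr",
             "model", "coherence")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(cfg$schema_version) && cfg$schema_version != 1)
    stop("unsupported config schema_version: ", cfg$schema_version)
  if (is.null(cfg$seed)) stop("config must set 'seed'")
  out <- output_dir %||% cfg$output_dir
  if (is.null(out)) stop("config must set 'output_dir' (or pass output_dir)")
  if (is.null(cfg$simulate)) {
    if (is.null(cfg$expression) || is.null(cfg$expression$A))
      stop("config must set expression paths (expression: A: ...) or a 'simulate' block")
    if (is.null(cfg$regulon)) stop("config must set 'regulon'")
    for (p in c(unlist(cfg$expression), cfg$regulon, cfg$categories))
      if (!file.exists(p)) stop("input file does not exist: ", p)
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  warn_log <- data.frame(stage = character(), message = character(),
                         stringsAsFactors = FALSE)
  note <- function(stage, msg) {
    warn_log[nrow(warn_log) + 1L, ] <<- list(stage, msg)
  }
  run_stage <- function(stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)),
      warning = function(w) {
        note(stage, conditionMessage(w)); invokeRestart("muffleWarning")
      },
      message = function(m) {
        note(stage, trimws(conditionMessage(m))); invokeRestart("muffleMessage")
      })
  }

  # --- inputs: simulate or read ---
  if (!is.null(cfg$simulate)) {
    sim <- run_stage("simulate", {
      sargs <- if (is.list(cfg$simulate)) cfg$simulate else list()
      sargs$seed <- sargs$seed %||% seed
      simulate_tfa_data(do.call(tfa_sim_config, sargs))
    })
    exprs <- sim$expr
    network <- sim$network
    run_stage("simulate", {
      for (cond in names(exprs)) {
        df <- data.frame(gene = exprs[[cond]]$genes, exprs[[cond]]$values,
                         check.names = FALSE)
        write_table(df, file.path(out, paste0("expr", cond, ".tsv")),
                    provenance = list(seed = seed))
      }
      ed <- network$edges
      ed$sign <- ifelse(is.na(ed$sign), "?", ifelse(ed$sign > 0, "+", "-"))
      write_table(ed, file.path(out, "regulon.tsv"), provenance = list(seed = seed))
      truth <- data.frame(tf = rep(rownames(sim$activities$A),
                                   times = 2 * ncol(sim$activities$A)),
                          condition = rep(c("A", "B"),
                                          each = length(sim$activities$A)),
                          minute = rep(rep(scfg_time(sim), each = nrow(sim$activities$A)), 2),
                          activity = c(as.vector(sim$activities$A),
                                       as.vector(sim$activities$B)))
      write_table(truth, file.path(out, "truth.tsv"), provenance = list(seed = seed))
    })
    categories <- NULL
  } else {
    exprs <- lapply(seq_along(cfg$expression), function(i)
      run_stage("read_expression",
                read_expression_table(cfg$expression[[i]], names(cfg$expression)[i])))
    names(exprs) <- names(cfg$expression)
    network <- run_stage("read_regulon", read_regulon_table(cfg$regulon))
    categories <- if (!is.null(cfg$categories))
      run_stage("read_categories", read_category_map(cfg$categories)) else NULL
  }

  # --- diffexpr ---
  de <- cfg$diffexpr %||% list()
  for (cond in names(exprs)) {
    run_stage("diffexpr", {
      calls <- classify_regulation(exprs[[cond]],
                                   up_threshold = de$up_threshold %||% 2.0,
                                   down_threshold = de$down_threshold %||% 0.5)
      write_table(as.data.frame(calls),
                  file.path(out, paste0("calls_", cond, ".tsv")),
                  provenance = list(seed = seed, condition = cond))
      fr <- data.frame(minute = calls$time,
                       fraction_changed = vapply(calls$time, function(tp)
                         fraction_changed(calls, tp), numeric(1)))
      write_table(fr, file.path(out, paste0("fractions_", cond, ".tsv")),
                  provenance = list(seed = seed, condition = cond))
      if (!is.null(categories))
        write_table(category_summary(calls, categories, calls$time[length(calls$time)]),
                    file.path(out, paste0("categories_", cond, ".tsv")),
                    provenance = list(seed = seed, condition = cond))
      if (!is.null(cfg$genes_of_interest)) {
        st <- time_strip(exprs[[cond]], cfg$genes_of_interest)
        if (length(attr(st, "not_found")))
          warning("genes not found for strips: ",
                  paste(attr(st, "not_found"), collapse = ", "))
        write_table(data.frame(gene = rownames(st), st, check.names = FALSE),
                    file.path(out, paste0("strips_", cond, ".tsv")),
                    provenance = list(seed = seed, condition = cond))
      }
    })
  }

  # --- TF activity inference per condition ---
  mdl <- cfg$model %||% list()
  chains <- mdl$chains %||% 2
  mdl$chains <- NULL
  control <- do.call(tfa_control, mdl)
  fits <- list()
  for (i in seq_along(exprs)) {
    cond <- names(exprs)[i]
    fits[[cond]] <- run_stage("infer-tfa", {
      fit <- tfa(exprs[[cond]], network, control = control, chains = chains,
                 seed = seed + i)
      if (length(fit$connectivity$dropped_tfs))
        warning("dropped TFs: ", paste(fit$connectivity$dropped_tfs, collapse = ", "))
      bad <- fit$posterior$rhat[!is.na(fit$posterior$rhat) & fit$posterior$rhat > 1.1]
      if (length(bad))
        warning("non-converged TFs (split-Rhat > 1.1): ",
                paste(names(bad), collapse = ", "))
      write_table(as.data.frame(fit$posterior),
                  file.path(out, paste0("activities_", cond, ".tsv")),
                  provenance = list(seed = seed, condition = cond))
      write_table(data.frame(tf = names(fit$posterior$rhat),
                             split_rhat = unname(fit$posterior$rhat),
                             sigma_mean = mean(fit$sigma_draws)),
                  file.path(out, paste0("diagnostics_", cond, ".tsv")),
                  provenance = list(seed = seed, condition = cond))
      fit
    })
  }

  # --- coherence (needs two conditions) ---
  if (length(fits) >= 2) {
    run_stage("coherence", {
      co <- cfg$coherence %||% list()
      tab <- coherence_table(fits[[1]], fits[[2]],
                             d_threshold = co$d_threshold %||% 0.5,
                             m_threshold = co$m_threshold,
                             seed = seed)
      if (any(tab$omitted))
        warning("omitted coherence points (|r| CI half-width > 0.15): ",
                paste(tab$tf[tab$omitted], collapse = ", "))
      write_table(tab, file.path(out, "coherence.tsv"),
                  provenance = list(seed = seed,
                                    d_threshold = attr(tab, "d_threshold"),
                                    m_threshold = format(attr(tab, "m_threshold"),
                                                         digits = 15)))
    })
  }

  # --- manifest + warnings ---
  cfg_norm <- file.path(out, "config_used.yaml")
  yaml::write_yaml(cfg, cfg_norm)
  manifest <- data.frame(
    key = c("package_version", "seed", "config_md5", "n_conditions"),
    value = c(as.character(packageVersion("tfactivity")), as.character(seed),
              unname(tools::md5sum(cfg_norm)), as.character(length(exprs))))
  write_table(manifest, file.path(out, "manifest.tsv"),
              provenance = list(seed = seed))
  write_table(warn_log, file.path(out, "warnings.tsv"),
              provenance = list(seed = seed))
  invisible(out)
}

scfg_time <- function(sim) as.numeric(colnames(sim$activities$A))

`%||%` <- function(a, b) if (is.null(a)) b else a
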