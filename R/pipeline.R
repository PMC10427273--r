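#' Run the full analysis pipeline from one configuration
#'
#' prepare -> score -> design -> fit -> compare -> report. The
#' configuration is a list (or a path to a JSON file with the same
#' structure) holding exactly one input source:
#' \describe{
#'   \item{simulation}{a list of [sim_config()] arguments — the corpus is
#'     generated, and the matching synthetic lexicon is used.}
#'   \item{chart_csv / bow / bow_meta}{paths to real input files, together
#'     with `lexicon_pos` / `lexicon_neg` paths.}
#' }
#' plus `polarities` (default both), `models` (names from
#' [standard_model_set()]), `window`, `top_k`, `prestige_threshold`,
#' sampler settings (`chains`, `iter`, `warmup`), `seed` and `out_dir`.
#'
#' @param config list or JSON path.
#' @return the output directory, invisibly; artifacts written there:
#'   design CSVs, per-model draws/diagnostics, comparison tables,
#'   coefficient summaries, trend CSVs/plots and `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- validate_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # ---- prepare ----------------------------------------------------------
  if (!is.null(cfg$simulation)) {
    sim_args <- cfg$simulation
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    scfg <- stage("prepare", do.call(sim_config, sim_args))
    sim <- stage("prepare", simulate_corpus(scfg))
    corpus <- sim$corpus
    chart <- corpus
    lexicon <- synthetic_vocabulary(scfg)$lexicon
    jsonlite::write_json(
      list(alpha = as.list(sim$truth$alpha),
           beta_pos = as.list(sim$truth$beta_pos),
           beta_neg = as.list(sim$truth$beta_neg),
           sigma = as.list(sim$truth$sigma), seed = sim$truth$seed),
      file.path(cfg$out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  } else {
    lexicon <- stage("prepare",
                     load_lexicon(cfg$lexicon_pos, cfg$lexicon_neg))
    if (!is.null(cfg$chart_csv)) {
      corpus <- stage("prepare", read_chart_csv(cfg$chart_csv))
    } else {
      corpus <- stage("prepare", read_bow_corpus(cfg$bow, cfg$bow_meta))
      corpus <- stage("prepare", filter_english(corpus))
      corpus <- stage("prepare",
                      filter_years(corpus, cfg$min_songs_per_year))
    }
    corpus <- stage("prepare", resolve_artists(corpus))
    chart <- if (!is.null(cfg$chart_csv)) corpus else {
      stop("bag-of-words runs need a chart_csv for success/prestige")
    }
  }

  # ---- trends -----------------------------------------------------------
  for (pol in cfg$polarities) {
    tr <- stage("report", yearly_valence_proportion(corpus, lexicon, pol))
    export_trend(tr, file.path(cfg$out_dir, paste0("trend_", pol, ".csv")),
                 plot_path = file.path(cfg$out_dir,
                                       paste0("trend_", pol, ".pdf")),
                 main = paste(pol, "emotion words"))
  }

  # ---- design / fit / compare ------------------------------------------
  manifest_models <- list()
  for (pol in cfg$polarities) {
    design <- stage("design", build_design(
      corpus, chart, lexicon, pol, window = cfg$window, top_k = cfg$top_k,
      min_appearances = cfg$prestige_threshold))
    write_design(design,
                 file.path(cfg$out_dir, paste0("design_", pol, ".csv")),
                 file.path(cfg$out_dir, paste0("design_", pol, ".json")))
    mset <- standard_model_set(pol, has_rank = "rank" %in% names(design))
    mset <- mset[intersect(cfg$models, names(mset))]
    if (length(mset) == 0L) stop("no applicable models for ", pol)
    waics <- list(); summaries <- list()
    for (mn in names(mset)) {
      spec <- model_spec(pol, effects = mset[[mn]], chains = cfg$chains,
                         iter = cfg$iter, warmup = cfg$warmup)
      f <- stage("fit", suppressWarnings(
        fit_model(spec, design, seed = cfg$seed)))
      write_fit(f, file.path(cfg$out_dir, paste0("fit_", pol, "_", mn)))
      waics[[mn]] <- waic(f$loglik)
      s <- summarize_fit(f)
      s$model <- mn
      summaries[[mn]] <- s
    }
    if (length(waics) > 1L) {
      tab <- suppressWarnings(compare_waic(waics))
      write_comparison(tab, file.path(cfg$out_dir,
                                      paste0("compare_", pol, ".csv")))
    }
    utils::write.csv(do.call(rbind, summaries),
                     file.path(cfg$out_dir, paste0("coef_", pol, ".csv")),
                     row.names = FALSE)
    manifest_models[[pol]] <- names(mset)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("lyricbias")),
    r_version = R.version.string,
    seed = cfg$seed,
    config = cfg,
    filter_log = corpus_log(corpus),
    models = manifest_models,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(cfg$out_dir)
}

validate_run_config <- function(config) {
  defaults <- list(polarities = c("positive", "negative"),
                   models = c("null", "success", "prestige", "content",
                              "full", "full_unbiased"),
                   window = 3L, top_k = 10L, prestige_threshold = 10L,
                   min_songs_per_year = 500L,
                   chains = 2L, iter = 300L, warmup = 300L,
                   seed = 1L, out_dir = "lyricbias_run")
  cfg <- utils::modifyList(defaults, config)
  has_sim <- !is.null(cfg$simulation)
  has_real <- !is.null(cfg$chart_csv) || !is.null(cfg$bow)
  if (has_sim == has_real) {
    stop("config must contain exactly one of a 'simulation' block or real ",
         "input paths")
  }
  if (has_real && (is.null(cfg$lexicon_pos) || is.null(cfg$lexicon_neg))) {
    stop("real-data runs need lexicon_pos and lexicon_neg paths")
  }
  if (length(cfg$models) == 0L) stop("model list must be non-empty")
  bad <- setdiff(cfg$polarities, c("positive", "negative"))
  if (length(bad) > 0L) stop("unknown polarity: ", paste(bad, collapse = ", "))
  cfg
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `run-all` (and `recover` for parameter-recovery
#' experiments). Invoked by the `inst/cli/lyricbias` script:
#' \preformatted{Rscript inst/cli/lyricbias run-all --config cfg.json}
#'
#' @param args character vector of command-line arguments.
#' @return exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: lyricbias <simulate|run-all|recover> --config cfg.json",
    "[--seed N] [--out dir]", sep = " ")
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- list(seed = 1L, out = NULL, config = NULL, replicates = 5L)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (i + 1L > length(args)) stop("missing value for --", key)
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  if (is.null(opts$config)) stop("--config is required")
  cfg <- jsonlite::read_json(opts$config, simplifyVector = TRUE)
  if (!is.null(opts$out)) cfg$out_dir <- opts$out
  cfg$seed <- as.integer(opts$seed)
  if (cmd == "run-all") {
    run_pipeline(cfg)
  } else if (cmd == "simulate") {
    sim_args <- cfg$simulation
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    sim <- simulate_corpus(do.call(sim_config, sim_args))
    out <- cfg$out_dir %||% "lyricbias_sim"
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_chart_csv(sim$corpus, file.path(out, "corpus_chart.csv"))
    write_bow_corpus(sim$corpus, file.path(out, "corpus_bow.txt"),
                     file.path(out, "corpus_meta.csv"))
    jsonlite::write_json(
      list(alpha = as.list(sim$truth$alpha),
           beta_pos = as.list(sim$truth$beta_pos),
           beta_neg = as.list(sim$truth$beta_neg),
           sigma = as.list(sim$truth$sigma), seed = sim$truth$seed),
      file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)
  } else if (cmd == "recover") {
    scfg <- do.call(sim_config,
                    utils::modifyList(cfg$simulation %||% list(),
                                      list(seed = cfg$seed)))
    rep <- recovery_experiment(scfg, as.integer(opts$replicates))
    print(rep)
  } else {
    message(usage); return(invisible(1L))
  }
  invisible(0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
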