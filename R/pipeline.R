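#' Run a pipeline stage from a configuration list
#'
#' The programmatic core of the command-line interface: dispatches on
#' `config$subcommand` and orchestrates simulation, quantification and
#' differential testing through the package functions, writing TSV outputs
#' whose headers record the seed and package version. Stages:
#'
#' * `sim`: coverage benchmark ([simulate_coverage_benchmark()]); writes
#'   `truth.tsv`, `evidence.tsv`, `features.tsv` into `out_dir`.
#' * `quant`: [quant_psi()] on an evidence and a feature TSV; writes the fit
#'   summary to `out`.
#' * `diff`: quantifies two evidence TSVs with a common feature table and
#'   writes the per-event Bayes factors to `out`.
#'
#' @param config Named list: `subcommand` (`"sim"`, `"quant"` or `"diff"`)
#'   plus the fields that stage needs (`n_events`, `rpk`, `dropout_frac`,
#'   `out_dir` for sim; `evidence`, `features`, `out`, `n_total`, `burn_in`
#'   for quant; additionally `evidence_b`, `epsilon`, `bf_threshold`, `M` for
#'   diff; `seed` everywhere).
#' @return Invisibly, a named list of the paths written.
#' @export
run_pipeline <- function(config) {
  sub <- config$subcommand %||% abort("`config$subcommand` is required")
  seed <- config$seed
  paths <- switch(
    sub,
    sim = {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      sim <- simulate_coverage_benchmark(
        n_events = config$n_events %||% 1000L,
        rpk = config$rpk %||% 100,
        dropout_frac = config$dropout_frac %||% 0,
        seed = seed)
      meta <- list(seed = seed %||% "none")
      p <- file.path(config$out_dir, c("truth.tsv", "evidence.tsv", "features.tsv"))
      write_tsv_meta(sim$truth, p[1], meta)
      write_evidence_tsv(sim$evidence, p[2], meta)
      write_tsv_meta(sim$features, p[3], meta)
      message(sprintf("sim: %d events at RPK %s -> %s",
                      nrow(sim$truth), config$rpk %||% 100, config$out_dir))
      list(truth = p[1], evidence = p[2], features = p[3])
    },
    quant = {
      evidence <- read_evidence_tsv(config$evidence)
      features <- read_tsv_meta(config$features)
      cfg <- sampler_config(n_total = config$n_total %||% 3000L,
                            burn_in = config$burn_in %||% 1000L, seed = seed)
      prior <- if (!is.null(config$fixed_prior)) read_prior_tsv(config$fixed_prior)
      fit <- quant_psi(evidence, features, config = cfg, prior = prior)
      write_fit_tsv(fit, config$out)
      message(sprintf("quant: %d unit(s), %d with zero reads -> %s",
                      nrow(fit$summary), sum(fit$summary$dropout), config$out))
      list(fit = config$out)
    },
    diff = {
      features <- read_tsv_meta(config$features)
      cfg <- sampler_config(n_total = config$n_total %||% 3000L,
                            burn_in = config$burn_in %||% 1000L, seed = seed)
      fit_a <- quant_psi(read_evidence_tsv(config$evidence), features, config = cfg)
      fit_b <- quant_psi(read_evidence_tsv(config$evidence_b), features, config = cfg)
      res <- diff_splicing(fit_a, fit_b,
                           epsilon = config$epsilon %||% 0.05,
                           M = config$M %||% 10000L,
                           bf_threshold = config$bf_threshold %||% 10,
                           seed = seed)
      write_tsv_meta(res, config$out, list(seed = seed %||% "none"))
      message(sprintf("diff: %d event(s), %d called at BF >= %s -> %s",
                      nrow(res), sum(res$called),
                      config$bf_threshold %||% 10, config$out))
      list(diff = config$out)
    },
    abort(sprintf("unknown subcommand '%s'", sub))
  )
  invisible(paths)
}
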