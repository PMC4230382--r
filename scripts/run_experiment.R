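#!/usr/bin/env Rscript

# Thin command-line front end over the commonsgame package.
#
#   Rscript scripts/run_experiment.R simulate  [--config cfg.yaml] --out DIR
#   Rscript scripts/run_experiment.R analyze   --trials trials.csv --out DIR
#   Rscript scripts/run_experiment.R run       [--config cfg.yaml] --out DIR
#   Rscript scripts/run_experiment.R reproduce-targets
#
# A config file (YAML or JSON, see write_run_config()) overrides the
# defaults; otherwise the packaged default configuration is used.

suppressMessages({
  library(optparse)
  library(commonsgame)
})

parser <- OptionParser(
  usage = "%prog <simulate|analyze|run|reproduce-targets> [options]",
  option_list = list(
    make_option("--config", type = "character", default = NULL,
                help = "run configuration file (.yaml/.json)"),
    make_option("--trials", type = "character", default = NULL,
                help = "tidy trial CSV (for 'analyze')"),
    make_option("--out", type = "character", default = "commonsgame_out",
                help = "output directory [default %default]"),
    make_option("--n-boot", type = "integer", default = NULL, dest = "n_boot",
                help = "override bootstrap resamples"),
    make_option("--seed", type = "integer", default = NULL,
                help = "override the cohort seed"),
    make_option("--quiet", action = "store_true", default = FALSE)
  )
)
args <- parse_args(parser, positional_arguments = 1L)
cmd <- args$args
opt <- args$options

cfg <- if (!is.null(opt$config)) read_run_config(opt$config) else run_config()
if (!is.null(opt$n_boot)) cfg$n_boot <- opt$n_boot
if (!is.null(opt$seed)) cfg$cohort_seed <- opt$seed

if (cmd == "simulate") {
  cs <- simulate_cohort(cfg$n_per_group, cfg$params_T_plus,
                        cfg$params_T_minus, config = cfg$engine,
                        seed = cfg$cohort_seed, jitter = cfg$jitter,
                        offsets = cfg$offsets)
  dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
  write.csv(cs$trials, file.path(opt$out, "trials.csv"), row.names = FALSE)
  write.csv(cs$outcomes, file.path(opt$out, "outcomes.csv"),
            row.names = FALSE)
  if (!opt$quiet) print(cs)
} else if (cmd == "analyze") {
  if (is.null(opt$trials)) stop("analyze needs --trials", call. = FALSE)
  rows <- read.csv(opt$trials, stringsAsFactors = FALSE)
  dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
  for (m in c("model1", "model2")) {
    fit <- harvest_lm(rows, model = m, n_boot = cfg$n_boot,
                      seed = cfg$boot_seed)
    write.csv(summarize_fit(fit),
              file.path(opt$out, paste0(m, "_report.csv")),
              row.names = FALSE)
    if (!opt$quiet) print(summary(fit))
  }
} else if (cmd == "run") {
  run_full_analysis(cfg, dir = opt$out, quiet = opt$quiet)
} else if (cmd == "reproduce-targets") {
  print(reproduce_targets())
} else {
  stop("unknown command: ", cmd, call. = FALSE)
}
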