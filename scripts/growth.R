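#!/usr/bin/env Rscript
# Thin command-line wrapper over the growth module:
#   Rscript scripts/growth.R fit <table.csv> [--out dir]
#   Rscript scripts/growth.R envelope <table.csv> --variable temperature_C \
#       [--rate-floor 0.1] [--fold-floor 4] [--out dir]

suppressPackageStartupMessages(library(sparsegrowth))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 2L)
  stop("usage: growth.R fit|envelope <table> [options]", call. = FALSE)
cmd <- args[1L]
path <- args[2L]
opt <- function(flag, default) {
  i <- match(flag, args)
  if (!is.na(i) && i < length(args)) args[i + 1L] else default
}
outdir <- opt("--out", ".")
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

curves <- read_growth_table(path)

if (cmd == "fit") {
  rates <- do.call(rbind, lapply(curves, function(gc) {
    f <- growth_fit(gc)
    cbind(strain = gc$strain_id, replicate = gc$replicate_id,
          f$rates[c("time", "median_rate")])
  }))
  names(rates)[3:4] <- c("time_days", "median_rate_doublings_per_day")
  write.csv(rates, file.path(outdir, "instantaneous_rates.csv"),
            row.names = FALSE)
  cat("wrote", file.path(outdir, "instantaneous_rates.csv"), "\n")
} else if (cmd == "envelope") {
  variable <- opt("--variable", "temperature_C")
  rf <- as.numeric(opt("--rate-floor", "0.1"))
  ff <- as.numeric(opt("--fold-floor", "4"))
  key <- vapply(curves, function(g) as.character(g$condition[[variable]]),
                character(1))
  summaries <- lapply(split(curves, key), summarize_condition,
                      rate_floor = rf, fold_floor = ff)
  env <- growth_envelope(summaries, variable)
  print(env)
  write.csv(env$table, file.path(outdir, "growth_envelope.csv"),
            row.names = FALSE)
  cat("wrote", file.path(outdir, "growth_envelope.csv"), "\n")
} else {
  stop("unknown subcommand: ", cmd, call. = FALSE)
}
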