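#!/usr/bin/env Rscript

# Command-line surface for the replicoex package.
#
# Usage:
#   Rscript scripts/replicoex.R simulate --sequences AAAA,BBBB [options]
#   Rscript scripts/replicoex.R scan   --config cfg.yaml --out prefix
#   Rscript scripts/replicoex.R matrix --config cfg.yaml --out prefix
#
# Exit codes: 0 success (including non-coexistence outcomes),
#             2 validation/configuration error, 3 solver failure.

suppressPackageStartupMessages({
  library(optparse)
  library(replicoex)
})

EXIT_OK <- 0L
EXIT_CONFIG <- 2L
EXIT_SOLVER <- 3L

die <- function(status, ...) {
  message(...)
  quit(save = "no", status = status)
}

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L || !args[1] %in% c("simulate", "scan", "matrix"))
  die(EXIT_CONFIG,
      "usage: replicoex.R <simulate|scan|matrix> [options]; see --help")
cmd <- args[1]
rest <- args[-1]

pick_alphabet <- function(spec) {
  switch(spec,
         binary = binary_alphabet(),
         rna = rna_alphabet(),
         monomer_alphabet(strsplit(spec, "", fixed = TRUE)[[1]]))
}

run_guarded <- function(expr) {
  tryCatch(expr,
           validation_error = function(e) die(EXIT_CONFIG, conditionMessage(e)),
           error = function(e) {
             msg <- conditionMessage(e)
             if (grepl("integrator|eigen|solver", msg))
               die(EXIT_SOLVER, "solver failure: ", msg)
             die(EXIT_CONFIG, msg)
           })
}

if (cmd == "simulate") {
  parser <- OptionParser(
    usage = "replicoex.R simulate [options]",
    option_list = list(
      make_option("--sequences", type = "character", default = NULL,
                  help = "comma-separated template strands"),
      make_option("--fasta", type = "character", default = NULL,
                  help = "FASTA file of template strands (alternative)"),
      make_option("--pairing", type = "character", default = "complementary"),
      make_option("--polarity", type = "character", default = "antiparallel"),
      make_option("--alphabet", type = "character", default = NULL,
                  help = "binary | rna | explicit symbols (default: inferred)"),
      make_option("--elongation", type = "double", default = 1),
      make_option("--influx", type = "double", default = 1),
      make_option("--monomer-decay", type = "double", default = 1),
      make_option("--intermediate-decay", type = "character", default = "0.01",
                  help = paste("uniform rate, or comma-separated rates",
                               "recycled over (pair, strand, stage) slots")),
      make_option("--eps-conv", type = "double", default = 1e-9),
      make_option("--eps-ext", type = "double", default = 1e-8),
      make_option("--t-max", type = "double", default = 1e7),
      make_option("--json", type = "character", default = NULL,
                  help = "write the run manifest to this file")))
  opt <- parse_args(parser, args = rest)
  if (is.null(opt$sequences) && is.null(opt$fasta))
    die(EXIT_CONFIG, "simulate: give --sequences or --fasta")
  seqs <- run_guarded({
    if (!is.null(opt$fasta)) unname(read_sequences(opt$fasta))
    else strsplit(opt$sequences, ",", fixed = TRUE)[[1]]
  })
  run <- run_guarded({
    alphabet <- if (is.null(opt$alphabet)) detect_alphabet(seqs)
      else pick_alphabet(opt$alphabet)
    scheme <- pairing_scheme(opt$pairing, opt$polarity)
    params <- rate_parameters(alphabet,
                              elongation = opt$elongation,
                              monomer_influx = opt$influx,
                              monomer_decay = opt$`monomer-decay`,
                              intermediate_decay = as.numeric(strsplit(
                                opt$`intermediate-decay`, ",")[[1]]))
    simulate_competition(seqs, scheme, alphabet, params,
                         eps_conv = opt$`eps-conv`, eps_ext = opt$`eps-ext`,
                         t_max = opt$`t-max`)
  })
  print(run)
  if (!is.null(opt$json)) run_manifest(run, opt$json)
  quit(save = "no", status = EXIT_OK)
}

if (cmd == "scan") {
  parser <- OptionParser(
    usage = "replicoex.R scan --config cfg.yaml --out prefix",
    option_list = list(
      make_option("--config", type = "character", default = NULL),
      make_option("--out", type = "character", default = "scan")))
  opt <- parse_args(parser, args = rest)
  if (is.null(opt$config)) die(EXIT_CONFIG, "scan: --config is required")
  survey <- run_guarded({
    cfg <- read_survey_config(opt$config)
    # dispatch M1-M4 from the scheme and replicate count
    if (cfg$scheme$pairing == "complementary") {
      if (cfg$replicates > 1L) run_m2(cfg) else run_m1(cfg)
    } else {
      if (cfg$replicates > 1L) run_m4(cfg) else run_m3(cfg)
    }
  })
  print(survey)
  write_survey_csv(survey, paste0(opt$out, ".csv"))
  run_manifest(survey, paste0(opt$out, "_manifest.json"))
  quit(save = "no", status = EXIT_OK)
}

if (cmd == "matrix") {
  parser <- OptionParser(
    usage = "replicoex.R matrix --config cfg.yaml --out prefix",
    option_list = list(
      make_option("--config", type = "character", default = NULL),
      make_option("--engine", type = "character", default = "analytic"),
      make_option("--order", type = "character", default = "lexicographic"),
      make_option("--png", type = "character", default = NULL,
                  help = "optionally render the heatmap to this PNG file"),
      make_option("--out", type = "character", default = "matrix")))
  opt <- parse_args(parser, args = rest)
  if (is.null(opt$config)) die(EXIT_CONFIG, "matrix: --config is required")
  mat <- run_guarded({
    cfg <- read_survey_config(opt$config)
    coexistence_matrix(cfg, engine = opt$engine, order = opt$order)
  })
  print(mat)
  write_matrix_csv(mat, paste0(opt$out, ".csv"))
  run_manifest(mat, paste0(opt$out, "_manifest.json"))
  if (!is.null(opt$png)) {
    grDevices::png(opt$png, width = 900, height = 900)
    plot(mat)
    grDevices::dev.off()
  }
  quit(save = "no", status = EXIT_OK)
}
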