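#!/usr/bin/env Rscript
# Thin shell entry point for the budget-impact model; all logic lives in
# plwhcost::run_model_cli(). See --help for flags.
suppressPackageStartupMessages(library(plwhcost))
quit(status = run_model_cli(), save = "no")
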