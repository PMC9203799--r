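#!/usr/bin/env Rscript
## Long-tier reproduction runner (several CPU-hours; see the installed
## script for details).  Forwards to the copy shipped inside the package so
## the logic lives in one place.
path <- system.file("scripts", "long_reproduction.R", package = "neurofield")
if (!nzchar(path)) stop("install the package first")
args <- commandArgs(trailingOnly = TRUE)
system2("Rscript", c(path, args))
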