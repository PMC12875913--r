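#!/usr/bin/env Rscript
# Stage 3: orient the exposure to the HbA1c-lowering allele and harmonize
# each outcome against the selected instruments. All downstream effects are
# expressed per 1% lower HbA1c; the dropped-variant ledger records
# palindromic ambiguities and variants absent from an outcome.

suppressPackageStartupMessages(library(targetmr))

sim_dir <- "results/sim"
out_dir <- "results/analysis"
outcome_names <- c("memory_loss", "t2d", "intelligence", "prospective_memory")
binary <- c(memory_loss = TRUE, t2d = TRUE, intelligence = FALSE,
            prospective_memory = FALSE)

for (label in c("cis", "gw")) {
  inst <- sumstats(read.table(
    file.path(out_dir, paste0("instruments_", label, ".tsv")),
    header = TRUE, sep = "\t", colClasses = c(chrom = "character")))
  oriented <- orient_to_lowering(inst)
  for (nm in outcome_names) {
    outc <- read_sumstats(
      file.path(sim_dir, paste0("outcome_", nm, "_", label, ".tsv")),
      trait_name = nm)
    h <- harmonize(oriented, outc,
                   outcome_type = if (binary[[nm]]) "binary" else "continuous")
    write_harmonized(h, file.path(out_dir,
                                  paste0("harmonized_", nm, "_", label, ".tsv")))
    dropped <- attr(h, "dropped")
    cat(sprintf("%s / %-18s %2d pairs harmonized, %d dropped%s\n",
                label, nm, nrow(h), nrow(dropped),
                if (nrow(dropped)) paste0(" (",
                  paste(unique(dropped$reason), collapse = ", "), ")") else ""))
  }
}
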