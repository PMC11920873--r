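#!/usr/bin/env Rscript
# Interpret the transcriptome's molecule-eigenvectors: gene-set enrichment
# by rank-sum scoring of the loadings, marker molecules by randomization of
# the sample-eigenvector, and the phase-contribution decomposition (with
# CV) of the epigenome signal across the four transcriptomic eigen-phases.
# Reads results/sim/, writes results/interpret/.

suppressPackageStartupMessages(library(eigenphase))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

indir <- "results/sim"
outdir <- "results/interpret"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

tmat <- read_omics_table(file.path(indir, "transcriptome.tsv"),
                         file.path(indir, "transcriptome_meta.tsv"),
                         omics_label = "transcriptome")
tdec <- stratify(tmat)
sets <- read_gmt(file.path(indir, "gene_sets.gmt"))

for (k in 1:2) {
  u <- tdec$u[, k + 1]
  names(u) <- tdec$molecule_ids
  enr <- wilcoxon_enrich(u, sets)
  write.table(enr, file.path(outdir, sprintf("enrichment_level%d.tsv", k)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  hit <- enr[enr$set_id == "marker_block", ]
  cat(sprintf("level %d: marker_block strongest pole q = %.3g (z = %+0.2f)\n",
              k, min(hit$q), hit$z[1]))
}

mk <- marker_randomization(tdec, k = 1, R = 1000, seed = seed + 40000L)
write.table(mk, file.path(outdir, "markers_level1.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sum(mk$marker), "marker molecules at level 1",
    sprintf("(p <= %.2g, |loading| >= %.3g)\n",
            attr(mk, "p_max"), attr(mk, "u_min")))

emat <- read_omics_table(file.path(indir, "epigenome.tsv"),
                         file.path(indir, "epigenome_meta.tsv"),
                         omics_label = "epigenome")
ct <- phase_contributions(emat, tdec)
cat("epigenome phase contributions:",
    paste(sprintf("%s %.2f", names(ct$contributions), ct$contributions),
          collapse = ", "), sprintf(" (CV %.3f)\n", ct$cv))
write.table(data.frame(phase = names(ct$contributions),
                       contribution = ct$contributions, cv = ct$cv),
            file.path(outdir, "phase_contributions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Interpretation tables written to", outdir, "\n")
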