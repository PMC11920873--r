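#!/usr/bin/env Rscript
# Place the epigenome and metabolome samples on the transcriptome's
# timeline by derivative dynamic time warping of the dissolved-oxygen
# curves. The reference curve is cropped to each query's span (like-span
# alignment), warped, and the query sample times are mapped through the
# smoothed warp. Reads results/sim/, writes results/timelines/.

suppressPackageStartupMessages(library(eigenphase))

indir <- "results/sim"
outdir <- "results/timelines"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

ref_curve <- read_curve(file.path(indir, "transcriptome_oxygen.tsv"),
                        "transcriptome")
for (nm in c("epigenome", "metabolome")) {
  qc <- read_curve(file.path(indir, paste0(nm, "_oxygen.tsv")), nm)
  meta <- read.table(file.path(indir, paste0(nm, "_meta.tsv")), header = TRUE)
  rc <- crop_curve(ref_curve, min(qc$times), max(qc$times))
  path <- ddtw_align(resample_curve(rc), resample_curve(qc))
  tl <- map_sample_times(path, resample_curve(rc), resample_curve(qc),
                         sort(meta$time_h), smooth_window = 9)
  write.table(tl$map, file.path(outdir, paste0(nm, "_timeline.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(path$pairs, file.path(outdir, paste0(nm, "_warp_path.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%-11s DDTW cost %.4g; mean |mapped - original| = %.3f h\n",
              nm, path$total_cost,
              mean(abs(tl$map$mapped_time_h - tl$map$original_time_h))))
}
cat("Timelines written to", outdir, "\n")
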