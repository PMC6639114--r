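#!/usr/bin/env Rscript
# Derive the PC1 composite of psychometric-function shape: correlation-matrix
# PCA of (slope, threshold, lower asymptote, upper-asymptote offset) pooled
# over both duration conditions, signed so higher PC1 = steeper, more
# categorical labeling.

library(phonocat)
fits <- read.csv("results/fits.csv")

pca <- fit_shape_pca(fits)
fits$pc1 <- project_pc1(fits, pca)
write.csv(fits, "results/fits.csv", row.names = FALSE)
write_shape_pca(pca, "results/shape_pca.json")

cat(sprintf("PC1 explains %.1f%% of the parameter variance\n",
            100 * pca$variance_fraction_pc1))
cat("loadings:",
    paste(sprintf("%s %.3f", names(pca$loadings), pca$loadings),
          collapse = ", "), "\n")
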