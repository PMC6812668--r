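#!/usr/bin/env Rscript
# Step 1: load the packaged rotamer catalog and family schemes; tabulate
# family counts and inter-rotamer distances.
suppressPackageStartupMessages(library(rotasuite))
dir.create("results", showWarnings = FALSE)

cat46 <- load_catalog()
fmap <- load_family_map()
cat("Catalog:", nrow(cat46), "rotamers;",
    "total observation frequency", sum(cat46$frequency), "\n")

counts <- data.frame(
  scheme = family_schemes(),
  n_families = vapply(family_schemes(), count_families, integer(1),
                      family_map = fmap))
print(counts, row.names = FALSE)
write.table(counts, "results/family_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

D <- rotasuite:::rotamer_distance_matrix(cat46)
cat("Median inter-rotamer torsion distance:",
    round(median(D[upper.tri(D)]), 1), "deg;",
    "minimum:", round(min(D[upper.tri(D)]), 1), "deg\n")
cat("A-form singleton check: family 'a' of A_noA =",
    fmap$rotamer_id[fmap$A_noA == "a"], "\n")
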