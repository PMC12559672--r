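#!/usr/bin/env Rscript
# Stage 2: classic diversity indices per patch and per subregion.
#
# Abundance, richness, Shannon-Wiener diversity and Pielou evenness for
# every (period, patch) and (period, subregion) community, plus the
# Bray-Curtis dissimilarity between the river system and the surrounding
# lakes within each period.

library(metapatch)

s <- read_survey_table("results/survey.tsv",
                       dialect = list(period_order = c("ER", "LR", "NR", "ED")))

write_table(diversity_table(s, "patch"), "results/diversity_patch.tsv")
div_region <- diversity_table(s, "subregion")
write_table(div_region, "results/diversity_subregion.tsv")

message("subregion diversity by period:")
for (i in seq_len(nrow(div_region))) {
  message(sprintf("  %s %-4s abundance %7.0f richness %2d SHDI %.3f evenness %.3f",
                  div_region$period[i], div_region$unit[i],
                  div_region$abundance[i], div_region$richness[i],
                  div_region$shdi[i], div_region$pielou[i]))
}

bc <- do.call(rbind, lapply(s$periods, function(p) {
  m <- to_abundance_matrix(s, p)
  sub <- s$records$subregion[match(colnames(m), s$records$patch_id)]
  x <- rowSums(m[, sub == "DTL", drop = FALSE])
  y <- rowSums(m[, sub == "SLS", drop = FALSE])
  data.frame(period = p, bray_curtis_dtl_sls = bray_curtis(x, y))
}))
write_table(bc, "results/bray_curtis_subregions.tsv")
message("Bray-Curtis river-vs-stable dissimilarity: ",
        paste(sprintf("%s=%.3f", bc$period, bc$bray_curtis_dtl_sls),
              collapse = " "))
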