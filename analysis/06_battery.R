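#!/usr/bin/env Rscript
# The full battery: one report row per method, mirroring a
# method x controls x robust? summary table, followed by the PGLS
# fragility checks (influence diagnostics and trait permutations).

suppressPackageStartupMessages(library(galton))
dir.create("results", showWarnings = FALSE)
sc <- simulate_scenario(seed = 42)

report <- run_battery(sc, config = list(n_perm = 999,
                                        n_reps_indep = 10000), seed = 11)
print(report)
write_battery_report(report, "results/06_battery")

# fragility of the PGLS result
meta <- sc$meta
details <- attr(report, "details")
res_tab <- language_residuals(details$residual_fit, min_n = 1)
res_v <- setNames(res_tab$residual, res_tab$language_id)
ftr01 <- setNames(as.integer(meta$ftr == "weak"), meta$language_id)

inf <- pgls_influence(sc$tree, res_v, ftr01, cov_model = "pagel")
cat(sprintf("\n%d of %d tips exceed the dfbeta cutoff %.3f: %s\n",
            length(inf$flagged), nrow(inf$dfbeta), inf$cutoff,
            paste(inf$flagged, collapse = ", ")))
write.csv(inf$dfbeta, "results/06_influence.csv", row.names = FALSE)

perm <- permute_trait_test(sc$tree, res_v, ftr01, cov_model = "pagel",
                           permute = "both", scope = "within_family",
                           families = setNames(meta$family,
                                               meta$language_id),
                           n_perm = 999, seed = 12)
print(perm)
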