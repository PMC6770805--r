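#!/usr/bin/env Rscript
# Stage 4: REML variance components for the genotype-inclusive and
# -exclusive animal models (univariate per trait), plus a bivariate
# fat-protein fit for the genetic and phenotypic correlation.
source(file.path("analysis", "00_common.R"))

d <- get_dataset()
traits <- c("milk", "fat", "protein", "dm")

rows <- list()
for (variant in c("incl_genotype", "excl_genotype")) {
  inc <- variant == "incl_genotype"
  for (tr in traits) {
    dm <- suppressMessages(build_design_matrices(
      d$records, model_spec(tr, include_genotype = inc), d$ped))
    fit <- reml_fit(dm, d$Ainv, max_iter = 100L, tol = 1e-10)
    message(sprintf(
      "%s %s: sigma_a2 %.4g, sigma_pe2 %.4g, sigma_e2 %.4g, h2 %.2f +/- %.2f, rep %.2f (%s, %d it)",
      variant, tr, fit$vc[["sigma_a2"]], fit$vc[["sigma_pe2"]],
      fit$vc[["sigma_e2"]], fit$h2, fit$h2_se, fit$repeatability,
      if (fit$converged) "converged" else "max_iter", fit$iterations))
    rows[[paste(variant, tr)]] <- data.frame(
      model_variant = variant, trait = tr,
      sigma_a2 = fit$vc[["sigma_a2"]], sigma_p2 = fit$vc[["sigma_p2"]],
      sigma_pe2 = fit$vc[["sigma_pe2"]], sigma_e2 = fit$vc[["sigma_e2"]],
      h2 = fit$h2, h2_se = fit$h2_se, repeatability = fit$repeatability,
      converged = fit$converged, iterations = fit$iterations)
  }
}
tab <- do.call(rbind, rows)
write_tsv(tab, "04_variance_components")

# two-model heritability contrast per trait
for (tr in traits) {
  dh <- tab$h2[tab$model_variant == "incl_genotype" & tab$trait == tr] -
    tab$h2[tab$model_variant == "excl_genotype" & tab$trait == tr]
  message(sprintf("h2 delta (incl - excl) for %s: %+.3f", tr, dh))
}

message("bivariate fat-protein fit (correlations):")
dmb <- suppressMessages(build_design_matrices(
  d$records, model_spec(c("fat", "protein")), d$ped))
fb <- reml_fit(dmb, d$Ainv, max_iter = 40L, tol = 1e-8)
cr <- correlations(fb)
message(sprintf("  r_G = %.3f +/- %.3f, r_P = %.3f +/- %.3f (%s after %d it)",
                cr$r_G, cr$r_G_se, cr$r_P, cr$r_P_se,
                if (fb$converged) "converged" else "criterion not yet met",
                fb$iterations))
write_tsv(data.frame(pair = "fat-protein", r_G = cr$r_G, r_G_se = cr$r_G_se,
                     r_P = cr$r_P, r_P_se = cr$r_P_se,
                     converged = fb$converged),
          "04_bivariate_fat_protein")
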