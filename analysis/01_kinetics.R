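#!/usr/bin/env Rscript
# Inhibition-kinetics analysis: simulate initial-velocity grids for an
# IMPDH-like enzyme under its three guanine-nucleotide inhibitors, run the
# global mixed-type regression, classify each mechanism, and tabulate the
# recovered constants next to the generating truths.
#
# Finding (seed 1): GMP-like data come back competitive (Ki ~ 0.6 mM); GDP-
# and GTP-like data come back mixed-type with alpha > 1 and beta << 1 --
# i.e. partial allosteric inhibition that lowers apparent substrate
# affinity and caps residual turnover, matching the generating models.

suppressMessages(library(allokin))
dir.create("results", showWarnings = FALSE)
seed <- 1L

truths <- list(
  GMP = list(mechanism = "competitive", Vmax = 1, Km = 51, Ki = 600),
  GDP = list(mechanism = "mixed", Vmax = 1, Km = 51, Ki = 210,
             alpha = 6.5, beta = 0.033),
  GTP = list(mechanism = "mixed", Vmax = 1, Km = 51, Ki = 160,
             alpha = 4.1, beta = 0.24))

rows <- list()
for (nm in names(truths)) {
  tr <- truths[[nm]]
  d <- gen_kinetics_dataset(tr, seed = seed, inhibitor_id = nm,
                            enzyme_id = "IMPDH")
  f <- fit_inhibition_global(d)
  hw <- hanes_woolf(d)
  p <- as.list(f$parameters); s <- as.list(f$se)
  cat(sprintf("%s: mechanism %s (truth %s)%s\n", nm, f$mechanism,
              tr$mechanism, if (f$ambiguous) " [ambiguous]" else ""))
  cat(sprintf("   Km = %.1f +- %.1f uM | Ki = %.3g +- %.2g mM", p$Km, s$Km,
              p$Ki / 1000, s$Ki / 1000))
  if (f$mechanism == "mixed")
    cat(sprintf(" | alpha = %.2f +- %.2f | beta = %.3f +- %.3f",
                p$alpha, s$alpha, p$beta, s$beta))
  cat(sprintf("\n   Hanes-Woolf slope-equality F = %.1f (p = %.2g)\n",
              hw$slope_test$F, hw$slope_test$p_value))
  rows[[nm]] <- data.frame(
    inhibitor = nm, mechanism = f$mechanism,
    Km_uM = round(p$Km, 1), Ki_mM = signif(p$Ki / 1000, 2),
    alpha = if (is.null(p$alpha)) NA else signif(p$alpha, 2),
    beta = if (is.null(p$beta)) NA else signif(p$beta, 2),
    Ki_truth_mM = tr$Ki / 1000,
    alpha_truth = if (is.null(tr$alpha)) NA else tr$alpha,
    beta_truth = if (is.null(tr$beta)) NA else tr$beta)
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/kinetics_fits.csv", row.names = FALSE)
cat("\nwrote results/kinetics_fits.csv\n")
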