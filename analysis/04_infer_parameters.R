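#!/usr/bin/env Rscript

# Step 4: invert the generative model. Sweeps the projection jitter sigma
# (0-50 um) and the input convergence lambda (1-10), then reads off the
# parameter values whose simulated tiling match equals the experimentally
# observed levels (84% for RGC axons, 77% for SC somata). Writes the sweep
# curves, the estimates, and a figure to results/inference/.

suppressPackageStartupMessages({
  library(retinotile)
  library(ggplot2)
})

seed <- 20260929L
reps <- 500L
out_dir <- "results/inference"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config()
observed_axon_match <- 84
observed_soma_match <- 77

message("sweeping sigma (0-50 um, ", reps, " repetitions) ...")
sw_s <- sweep_sigma(0:50, repetitions = reps, config = cfg,
                    seed = derive_seed(seed, "sigma"))
est_s <- invert_curve(sw_s, observed_axon_match)
write_sweep_csv(sw_s, file.path(out_dir, "sweep_sigma.csv"))

message("sweeping lambda (1-10, sigma = ",
        sprintf("%.1f", est_s$estimate), " um) ...")
sw_l <- sweep_lambda(seq(1, 10, by = 0.25), sigma_fixed = est_s$estimate,
                     repetitions = reps, config = cfg,
                     seed = derive_seed(seed, "lambda"))
est_l <- invert_curve(sw_l, observed_soma_match)
write_sweep_csv(sw_l, file.path(out_dir, "sweep_lambda.csv"))

cat(sprintf("sigma  = %.1f um (95%% CI %.1f-%.1f) at %.0f%% axon match\n",
            est_s$estimate, est_s$ci_lo, est_s$ci_hi, observed_axon_match))
cat(sprintf("lambda = %.2f (95%% CI %.2f-%.2f) at %.0f%% soma match\n",
            est_l$estimate, est_l$ci_lo, est_l$ci_hi, observed_soma_match))

jsonlite::write_json(list(
  sigma = list(estimate = est_s$estimate, ci_lo = est_s$ci_lo,
               ci_hi = est_s$ci_hi, observed = observed_axon_match),
  lambda = list(estimate = est_l$estimate, ci_lo = est_l$ci_lo,
                ci_hi = est_l$ci_hi, observed = observed_soma_match),
  repetitions = reps, seed = seed
), file.path(out_dir, "estimates.json"), auto_unbox = TRUE, digits = NA)

plot_sweep <- function(sw, est, xlab) {
  df <- data.frame(x = sw$grid, med = sw$median, lo = sw$lo95, hi = sw$hi95)
  ggplot(df, aes(x, med)) +
    geom_ribbon(aes(ymin = lo, ymax = hi), fill = "grey80") +
    geom_line(linewidth = 0.7) +
    geom_hline(yintercept = est$observed_match, linetype = "dotted") +
    geom_vline(xintercept = est$estimate, color = "orange") +
    labs(x = xlab, y = "tiling match (%)") +
    theme_classic()
}
fig <- cowplot::plot_grid(
  plot_sweep(sw_s, est_s, expression(sigma ~ "(µm)")),
  plot_sweep(sw_l, est_l, expression(lambda ~ "(RGC inputs)")),
  nrow = 1)
ggsave(file.path(out_dir, "inversion_curves.png"), fig,
       width = 8, height = 3.2, dpi = 150)
cat(sprintf("outputs in %s\n", out_dir))
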