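#!/usr/bin/env Rscript
# Membrane tension readout and high-tension point mapping.
#
# The Flipper-TR probe's dominant FLIM lifetime tau1 rises with membrane
# tension: ~4.7 ns in quiescent cells, ~+12% right after compression
# (T0), recovered ~10 min later (T1). High-tension points (tau ~6.5 ns,
# red in the lifetime colour map) cluster on the cell rim in one
# 45-degree sector, marking the expected pore site.

suppressMessages(library(mechanopore))
dir.create("results", showWarnings = FALSE)
set.seed(42)

# -- lifetimes per condition (16 cells each, one mean decay per cell) ----
conds <- c(Ctrl = 4.7, T0 = 4.7 * 1.12, T1 = 4.7)
flim <- do.call(rbind, lapply(names(conds), function(cond) {
  tau_true <- conds[[cond]] * (1 + rnorm(16, 0, 0.02))
  est <- vapply(tau_true, function(tau) {
    d <- gen_decay(tau1 = tau, tau2 = 1.2, i1 = 9, i2 = 1, n_photons = 1e5)
    fit_biexponential(d)$tau1
  }, numeric(1))
  data.frame(condition = cond, cell_id = paste0(cond, "_", 1:16),
             tau1_ns = est)
}))
write.csv(flim, "results/flim_lifetimes.csv", row.names = FALSE)

means <- tapply(flim$tau1_ns, flim$condition, mean)
cat(sprintf("tau1: Ctrl %.2f ns, T0 %.2f ns (+%.1f%%), T1 %.2f ns\n",
            means["Ctrl"], means["T0"],
            100 * (means["T0"] - means["Ctrl"]) / means["Ctrl"],
            means["T1"]))
kw <- compare_conditions(flim$tau1_ns, flim$condition, "Ctrl", "T0")
cat(sprintf("Ctrl vs T0: Kruskal-Wallis H = %.1f, p = %.2g %s\n",
            kw$H, kw$p_value, kw$stars))

# -- high-tension point concentration (T0 cells, one sector each) --------
tension <- do.call(rbind, lapply(1:16, function(i) {
  start <- runif(1, 0, 360)
  g <- gen_tension_image(cell_radius = 60,
                         point_angles = (start + runif(16, 0, 40)) %% 360)
  seg <- segment_cell_circle(g$image[, , 1] + g$image[, , 2])
  pm <- polarize_points(detect_high_tension_points(g$image),
                        seg$centroid, seg$cell_radius)
  ac <- angular_concentration(pm)
  data.frame(cell_id = paste0("T0_", i),
             mean_norm_r = mean(pm$norm_r),
             max_bin_pct = ac$max_bin_fraction, baseline_pct = ac$baseline)
}))
write.csv(tension, "results/tension_points.csv", row.names = FALSE)
cat(sprintf("high-tension points: mean normalized radius %.2f (rim),\n",
            mean(tension$mean_norm_r)))
cat(sprintf("max 45-degree bin holds %.0f%% of points on average (baseline 12.5%%)\n",
            mean(tension$max_bin_pct)))
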