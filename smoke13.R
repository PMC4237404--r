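library(cardiomap)
t0 <- proc.time()
bms <- list(); tms <- list()
for (s in 1:30) {
  set.seed(s*7)
  p <- make_phantom(seed=s*7, infarct_fraction=runif(1,.15,.45), core_fraction=runif(1,.3,.6))
  stk <- render_mri_stack(p, seed=s+500)
  seg <- segment_2sd(stk)
  tms[[s]] <- transmurality_map(seg$scar_mask, stk)
  mdl <- voltage_model(noise_sd_mV=0.1)
  bms[[s]] <- build_polar_map(dense_mapping_points(p, mdl, seed=s+900), "bipv")
}
sw <- threshold_sweep(bms, tms)
print(sw$best)
cat("noisy sweep elapsed:", (proc.time()-t0)[3], "\n")

# realistic run_cohort, small n
t0 <- proc.time()
cc <- cohort_config(n_subjects=10, seed=11)
res <- run_cohort(cc)
print(res)
cat("AUC:", res$roc$auc, " CI:", res$roc$auc_ci, "\n")
if (!is.null(res$sweep)) print(res$sweep$best)
cat("cohort(10) elapsed:", (proc.time()-t0)[3], "\n")
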