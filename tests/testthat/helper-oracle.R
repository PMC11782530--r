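# Independent brute-force oracle for full-conversion residual pressures:
# advances each reaction's extent in progressively halved numeric steps
# until a reactant is exhausted, never using the closed-form min-ratio
# the implementation relies on.
oracle_residual <- function(parts, reactions, p0_abs) {
  all_sp <- c("H2", "CO2", "N2", "CH4", "NH3")
  full <- setNames(numeric(length(all_sp)), all_sp)
  full[names(parts)] <- parts
  parts <- full
  init_total <- sum(parts)
  for (rx in reactions) {
    reac <- rx$gas[rx$gas < 0]
    if (any(parts[names(reac)] <= 0)) next
    step <- init_total
    while (step > 1e-13 * init_total) {
      trial <- parts[names(reac)] + reac * step
      if (all(trial >= 0)) {
        parts[names(rx$gas)] <- parts[names(rx$gas)] + rx$gas * step
      } else {
        step <- step / 2
      }
    }
    parts[parts < 0] <- 0
  }
  list(threshold_abs_bar = p0_abs * sum(parts) / init_total, parts = parts)
}

# random mixture part tables for property tests
random_parts <- function() {
  sp <- c("H2", "CO2", "N2")
  if (stats::runif(1) < 0.3) sp <- c(sp, "CH4")
  parts <- setNames(sample(0:20, length(sp), replace = TRUE), sp)
  if (sum(parts) == 0) parts[["H2"]] <- 1
  parts
}
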