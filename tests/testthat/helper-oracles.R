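# Independent oracles kept deliberately naive: they recompute quantities
# from first principles so the implementation is checked against a
# different code path.

# two-pass CV: mean first, then explicit squared deviations with n - 1
cv_oracle <- function(x) {
  m <- sum(x) / length(x)
  s2 <- sum((x - m)^2) / (length(x) - 1)
  sqrt(s2) / m * 100
}

# brute-force one-way ANOVA by explicit sums of squares
anova_oracle <- function(values, groups) {
  groups <- as.character(groups)
  gm <- mean(values)
  ssb <- 0
  ssw <- 0
  for (g in unique(groups)) {
    v <- values[groups == g]
    ssb <- ssb + length(v) * (mean(v) - gm)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  df_b <- length(unique(groups)) - 1
  df_w <- length(values) - length(unique(groups))
  f <- (ssb / df_b) / (ssw / df_w)
  list(ssb = ssb, ssw = ssw, df_b = df_b, df_w = df_w, f = f,
       p = stats::pf(f, df_b, df_w, lower.tail = FALSE))
}

# the four structure radii of one accession from the reference panel
fixture_structure <- function(fx, acc, struct) {
  r <- fx$radii
  r$radius_um[r$accession == acc & r$structure == struct]
}

noise_free_truth <- function() {
  synth_truth(cv_technical = 0, cv_radius = 0, accession_cv = 0)
}
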