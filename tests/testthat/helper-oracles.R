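# Shared fixtures and independent oracles used across the suite.

# small, fast session template for property sweeps
quick_params <- function(seed, ...) {
  args <- list(session_duration_s = 30, fps = 10, n_events = 3,
               dwell_mean_s = 0.8, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_params, args)
}

# a tiny hand-built track set: head-center walks a straight line past the
# rod; all other markers placed explicitly
manual_track_set <- function(hc_x, hc_y, rod_x = 0, rod_y = 0,
                             hl_x = hc_x - 1, hl_y = hc_y,
                             hr_x = hc_x + 1, hr_y = hc_y,
                             lik = 1, fps = 10, pixels_per_cm = 1) {
  n <- length(hc_x)
  rep_n <- function(v) if (length(v) == 1L) rep(v, n) else v
  coords <- data.frame(
    head_left_x = rep_n(hl_x), head_left_y = rep_n(hl_y),
    head_left_likelihood = rep_n(lik),
    head_center_x = hc_x, head_center_y = rep_n(hc_y),
    head_center_likelihood = rep_n(lik),
    head_right_x = rep_n(hr_x), head_right_y = rep_n(hr_y),
    head_right_likelihood = rep_n(lik),
    caudal_x = rep_n(hc_x), caudal_y = rep_n(hc_y) + 2,
    caudal_likelihood = rep_n(lik),
    rod_x = rep_n(rod_x), rod_y = rep_n(rod_y), rod_likelihood = rep_n(lik)
  )
  track_set(coords, fps = fps, pixels_per_cm = pixels_per_cm)
}

# match detected events to ground-truth events by interval overlap;
# returns precision, recall, and side agreement among matched pairs
match_events <- function(detected, truth) {
  overlap <- function(a1, a2, b1, b2) max(a1, b1) <= min(a2, b2)
  used <- rep(FALSE, nrow(detected))
  matched <- 0L; side_ok <- 0L
  for (i in seq_len(nrow(truth))) {
    for (j in seq_len(nrow(detected))) {
      if (!used[j] && overlap(truth$entry_frame[i], truth$exit_frame[i],
                              detected$entry_frame[j], detected$exit_frame[j])) {
        used[j] <- TRUE
        matched <- matched + 1L
        if (detected$side[j] == truth$side[i]) side_ok <- side_ok + 1L
        break
      }
    }
  }
  list(
    precision = if (nrow(detected) == 0L) 1 else matched / nrow(detected),
    recall = if (nrow(truth) == 0L) 1 else matched / nrow(truth),
    side_agreement = if (matched == 0L) 1 else side_ok / matched
  )
}

# O(n^2) pair-counting Kendall tau-b oracle (tie-corrected)
tau_b_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
      if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- sum(choose(table(x), 2))
  ty <- sum(choose(table(y), 2))
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# exact two-sided Kendall p-value by full enumeration over permutations of y
# (no ties assumed); p = P(|tau_perm| >= |tau_obs|) under the uniform null
tau_perm_p_oracle <- function(x, y) {
  n <- length(x)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  t_obs <- abs(tau_b_oracle(x, y))
  taus <- vapply(perms(y), function(p) tau_b_oracle(x, p), 0)
  mean(abs(taus) >= t_obs - 1e-12)
}

# independent ICC mean squares via stats::aov on the long layout
aov_icc_oracle <- function(m) {
  d <- data.frame(y = as.vector(m),
                  subj = factor(as.vector(row(m))),
                  rater = factor(as.vector(col(m))))
  ms <- summary(stats::aov(y ~ subj + rater, data = d))[[1]][["Mean Sq"]]
  n <- nrow(m); k <- ncol(m)
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  list(
    f = msr / mse,
    consistency = (msr - mse) / (msr + (k - 1) * mse),
    agreement = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  )
}
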