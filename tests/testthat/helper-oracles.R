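# Independent brute-force oracles used across tests.

# Exhaustive Otsu: best between-class variance over all candidate
# thresholds taken from the observed gray levels (classes v < t / v >= t).
otsu_bruteforce <- function(vals) {
  cand <- sort(unique(vals))
  best <- list(bcv = -Inf, threshold = NA_real_)
  n <- length(vals)
  for (t in cand[-1]) {            # at least one value below threshold
    lo <- vals < t
    w0 <- mean(lo); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    bcv <- w0 * w1 * (mean(vals[lo]) - mean(vals[!lo]))^2
    if (bcv > best$bcv) best <- list(bcv = bcv, threshold = t)
  }
  best
}

between_class_variance <- function(vals, thr) {
  hi <- vals >= thr
  if (!any(hi) || all(hi)) return(0)
  mean(hi) * mean(!hi) * (mean(vals[hi]) - mean(vals[!hi]))^2
}

# Mann-Whitney U by pair counting (ties count one half).
mw_u_bruteforce <- function(a, b) {
  u <- 0
  for (x in a) u <- u + sum(x > b) + 0.5 * sum(x == b)
  u
}

# Exact two-sided Wilcoxon signed-rank p-value by enumerating all 2^n sign
# assignments (assumes no zero differences and no tied |d|).
wilcoxon_exact_p <- function(x, y) {
  d <- x - y
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# Builds a small slice phantom and measures it with given config.
measure_brain <- function(params, config = slice_config()) {
  gen <- generate_brain(params)
  rows <- lapply(gen$images, measure_slice, config = config)
  list(bm = suppressWarnings(aggregate_slices(do.call(rbind, rows))),
       truth = gen$truth)
}

# Random per-slice integer area tables for formula-exactness checks.
random_area_table <- function(n_slices = 6) {
  left <- sample(500:2000, n_slices, replace = TRUE)
  right <- sample(500:2000, n_slices, replace = TRUE)
  data.frame(
    slice_index = seq_len(n_slices),
    left_area_px = left, right_area_px = right,
    infarct_area_px = vapply(right, function(r) sample(0:r, 1), integer(1)),
    blue_area_px = vapply(right, function(r) sample(0:r, 1), integer(1)))
}
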