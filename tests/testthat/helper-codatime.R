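# shared fixtures: random compositions and a small analysis cohort

random_composition <- function(D = 3, total = 1440) {
  closure(exp(stats::rnorm(D)), total = total,
          names = paste0("p", seq_len(D)))
}

random_composition_matrix <- function(n, D = 3, total = 1440) {
  m <- exp(matrix(stats::rnorm(n * D), n, D))
  m <- m / rowSums(m) * total
  colnames(m) <- paste0("p", seq_len(D))
  m
}

# tiny cohort with known geometry: rows are symmetric perturbations of a
# chosen center, so the compositional center equals it exactly
cohort_with_center <- function(center, n_pairs = 3, spread = 0.2, seed = 42) {
  set.seed(seed)
  D <- length(center)
  rows <- matrix(NA_real_, 2 * n_pairs, D)
  for (i in seq_len(n_pairs)) {
    p <- closure(exp(stats::rnorm(D, sd = spread)), total = 1,
                 names = names(center))
    rows[2 * i - 1, ] <- as.numeric(perturb(center, p))
    rows[2 * i, ] <- as.numeric(perturb(center, comp_inverse(p)))
  }
  colnames(rows) <- names(center)
  composition_set(rows, total = comp_total(center))
}

table1_center <- function() {
  composition(c(Sleep = 617.5, SB = 553.1, PA = 269.4), total = 1440)
}

small_cohort <- function(n = 400, seed = 7, sigma = 1.1768) {
  generate_cohort(generator_config(n = n, sigma = sigma), seed = seed)
}
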