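# Shared fixtures built in code: small cohort/metric tables and planted
# two-block designs used across the module tests.

tracts4 <- c("uncinate_fasciculus", "dorsal_cingulum", "ventral_cingulum",
             "fornix")

# a tiny, fully explicit cohort table
toy_cohort_df <- function() {
  data.frame(
    subject_id = c("S01", "S02", "S03"),
    age = c(5.5, 8.0, 11.2),
    sex = c("F", "M", "F"),
    sdfr = c(6, 8, 11),
    ldfr = c(5, 9, 12),
    ldcr = c(7, 10, 13),
    discrimination = c(0.1, 0.4, 0.6),
    stringsAsFactors = FALSE
  )
}

write_toy_cohort <- function(df = toy_cohort_df(), delim = ",") {
  path <- tempfile(fileext = ".csv")
  utils::write.table(df, path, sep = delim, quote = FALSE,
                     row.names = FALSE)
  path
}

# complete metrics table for the given subjects (values are arbitrary but
# valid and non-constant)
toy_metrics_df <- function(ids = c("S01", "S02", "S03"),
                           tracts = tracts4) {
  g <- expand.grid(hemisphere = c("left", "right"), tract = tracts,
                   subject_id = ids, stringsAsFactors = FALSE)
  set.seed(42)
  data.frame(
    subject_id = g$subject_id, tract = g$tract, hemisphere = g$hemisphere,
    fa = round(runif(nrow(g), 0.3, 0.5), 6),
    rd = round(runif(nrow(g), 5e-4, 7e-4), 10),
    ad = round(runif(nrow(g), 1.1e-3, 1.4e-3), 10),
    stringsAsFactors = FALSE
  )
}

# planted rank-1 design: x_j = b_j * t + noise, y = a * t + noise, so the
# population LV1 predictor salience is b / ||b||
planted_design <- function(n, b, a = 0.9, q = 1, seed = 1) {
  set.seed(seed)
  t <- rnorm(n)
  X <- sapply(b, function(bj) bj * t + sqrt(1 - bj^2) * rnorm(n))
  Y <- sapply(rep(a, q), function(aj) aj * t + sqrt(1 - aj^2) * rnorm(n))
  list(X = X, Y = as.matrix(Y), t = t, v = b / sqrt(sum(b^2)))
}

# all permutations of 1..n (tiny n only), for exhaustive permutation nulls
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}
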