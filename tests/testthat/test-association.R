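test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(c(0.3, 0.3, 0.3)), c(0.3, 0.3, 0.3))
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  # order-invariance and monotonicity
  p <- c(0.04, 0.01, 0.02)
  expect_equal(fdr_adjust(p), c(0.04, 0.03, 0.03))
  set.seed(1)
  q <- runif(20)
  adj <- fdr_adjust(q)
  expect_true(all(adj >= q - 1e-15))
  expect_true(all(diff(adj[order(q)]) >= -1e-15))
  expect_error(fdr_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("metric-age correlation table mirrors the 24-cell layout and a Pearson oracle", {
  sim <- generate_cohort(sim_config(seed = 3))
  tab <- correlate_with_age(sim$metrics, sim$cohort)
  expect_equal(nrow(tab), 24L)
  expect_equal(unique(paste(tab$tract)), tracts4)
  ages <- setNames(sim$cohort$age, sim$cohort$subject_id)
  for (i in sample(24, 8)) {
    sel <- sim$metrics$tract == tab$tract[i] &
      sim$metrics$hemisphere == tab$hemisphere[i]
    v <- sim$metrics[[tab$metric[i]]][sel]
    expect_equal(tab$r[i], cor(v, ages[sim$metrics$subject_id[sel]]),
                 tolerance = 1e-12)
  }
  # uncinate and fornix cells use 36 subjects, others 37
  expect_true(all(tab$n[tab$tract %in% c("uncinate_fasciculus",
                                         "fornix")] == 36))
  expect_true(all(tab$n[tab$tract %in% c("dorsal_cingulum",
                                         "ventral_cingulum")] == 37))
  expect_true(all(tab$p_fdr >= tab$p_raw - 1e-15))
})

test_that("a metric equal to age correlates perfectly; degenerate cells leave the FDR family", {
  co <- as_cohort(data.frame(
    subject_id = sprintf("S%02d", 1:12), age = seq(4, 12, length.out = 12),
    sex = "F", sdfr = 5, ldfr = 6, ldcr = 7, stringsAsFactors = FALSE))
  me <- toy_metrics_df(ids = co$subject_id, tracts = "fornix")
  me$fa[me$hemisphere == "left"] <- co$age / 20   # fa proportional to age
  me$rd[me$hemisphere == "right"] <- 5e-4         # constant: degenerate
  tab <- correlate_with_age(as_tract_metrics(me), co)
  expect_equal(tab$r[tab$hemisphere == "left" & tab$metric == "fa"], 1)
  dg <- tab$degenerate[tab$hemisphere == "right" & tab$metric == "rd"]
  expect_true(dg)
  expect_true(is.na(tab$p_fdr[tab$hemisphere == "right" &
                                tab$metric == "rd"]))
})

test_that("age regression satisfies its exact identities and a normal-equations oracle", {
  age <- c(4, 6, 7, 8, 10, 12)
  y <- 2 * age + 1
  r <- suppressWarnings(regress_on_age(y, age))  # exact fit by design
  expect_equal(r$r_squared, 1)
  expect_equal(r$beta_std, 1)
  # noisy fixed toy set against an explicit least-squares oracle
  y2 <- c(7.9, 13.2, 14.8, 17.5, 20.4, 25.6)
  r2 <- regress_on_age(y2, age)
  Xd <- cbind(1, age)
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y2)
  fitted <- Xd %*% beta
  ss_res <- sum((y2 - fitted)^2)
  ss_tot <- sum((y2 - mean(y2))^2)
  r2_oracle <- 1 - ss_res / ss_tot
  expect_equal(r2$r_squared, r2_oracle, tolerance = 1e-9)
  expect_equal(r2$F, (6 - 2) * r2_oracle / (1 - r2_oracle),
               tolerance = 1e-9)
  expect_equal(r2$beta_std, beta[2] * sd(age) / sd(y2), tolerance = 1e-9)
  expect_equal(r2$beta_std^2, r2_oracle, tolerance = 1e-9)
  # covariates: F for age becomes the squared t of the age term
  sexn <- c(0, 1, 0, 1, 0, 1)
  r3 <- regress_on_age(y2, age, covariates = data.frame(sex = sexn))
  sm <- summary(lm(y2 ~ age + sexn))
  expect_equal(r3$F, unname(coef(sm)["age", "t value"]^2),
               tolerance = 1e-9)
  expect_error(regress_on_age(y2, age,
                              covariates = data.frame(dup = age)),
               "collinear")
})

test_that("the F/R2 identity reproduces the printed worked examples", {
  f_of <- function(r2, n) (n - 2) * r2 / (1 - r2)
  expect_equal(f_of(0.251, 37), 11.71, tolerance = 0.01 * 11.71)
  expect_equal(f_of(0.239, 37), 11.02, tolerance = 0.01 * 11.02)
  expect_equal(f_of(0.35, 37), 18.98, tolerance = 0.01)
})

test_that("correlation Bayes factor matches an independent quadrature oracle", {
  # oracle: numerical integration of Hotelling's sampling density of r
  # against the stretched-beta prior, written independently of the
  # closed-form implementation
  hyp_oracle <- function(a, b, c, z) {
    term <- 1; s <- 1
    for (k in 0:10000) {
      term <- term * (a + k) * (b + k) / ((c + k) * (k + 1)) * z
      s <- s + term
      if (abs(term) < 1e-15 * abs(s)) break
    }
    s
  }
  dens_r <- function(r, rho, n)
    exp(log(n - 2) + lgamma(n - 1) + ((n - 1) / 2) * log1p(-rho^2) +
          ((n - 4) / 2) * log1p(-r^2) - 0.5 * log(2 * pi) -
          lgamma(n - 0.5) - (n - 1.5) * log1p(-rho * r)) *
      hyp_oracle(0.5, 0.5, n - 0.5, (rho * r + 1) / 2)
  bf_quad <- function(r, n, kappa = 1) {
    prior <- function(rho)
      (1 - rho^2)^(1 / kappa - 1) / (2^(2 / kappa - 1) *
                                       beta(1 / kappa, 1 / kappa))
    num <- integrate(function(v) vapply(v, function(rho)
      dens_r(r, rho, n) * prior(rho), numeric(1)), -1, 1,
      rel.tol = 1e-10)$value
    num / dens_r(r, 0, n)
  }
  for (case in list(c(0.3, 50), c(0.46, 37), c(0.51, 36), c(-0.2, 20))) {
    bf <- bayes_factor_correlation(case[1], case[2])
    expect_equal(bf, bf_quad(case[1], case[2]), tolerance = 1e-4)
  }
  # a non-default prior width agrees with the oracle too
  expect_equal(bayes_factor_correlation(0.4, 30, kappa = 2),
               bf_quad(0.4, 30, kappa = 2), tolerance = 1e-3)
})

test_that("Bayes factor symmetry, monotonicity and edge handling", {
  expect_identical(bayes_factor_correlation(-0.37, 41),
                   bayes_factor_correlation(0.37, 41))
  bfs <- vapply(c(0.1, 0.3, 0.5, 0.7), bayes_factor_correlation,
                numeric(1), n = 30)
  expect_true(all(diff(bfs) > 0))
  bfn <- vapply(c(10, 20, 40, 80), function(n)
    bayes_factor_correlation(0.4, n), numeric(1))
  expect_true(all(diff(bfn) > 0))
  expect_lt(bayes_factor_correlation(0.01, 40), 1)
  expect_warning(bf1 <- bayes_factor_correlation(1, 20), "infinite")
  expect_identical(bf1, Inf)
  expect_error(bayes_factor_correlation(0.5, 3), "at least 4")
  # large n and strong r must not overflow the series
  expect_true(is.finite(bayes_factor_correlation(0.5, 1000)))
})

test_that("maturity-memory association table: FDR families, BF attachment, specificity panel", {
  sim <- generate_cohort(sim_config(seed = 12))
  am <- suppressMessages(
    build_analysis_matrix(sim$cohort, sim$metrics, "dorsal_cingulum",
                          "age"))
  ms <- suppressMessages(maturity_scores(am, n_perm = 300, n_boot = 150,
                                         seed = 2, force = TRUE))
  tab <- maturity_em_association(ms, sim$cohort)
  expect_equal(nrow(tab), 4L)  # 3 recall + 1 discrimination
  expect_setequal(tab$panel, c("em", "specificity"))
  em_rows <- tab$panel == "em"
  expect_equal(tab$p_fdr[em_rows], fdr_adjust(tab$p_raw[em_rows]))
  for (i in seq_len(nrow(tab)))
    expect_equal(tab$bf10[i],
                 bayes_factor_correlation(tab$r[i], tab$n[i]))
  # a maturity score identical to a memory column gives r = 1 and
  # survives any FDR
  co <- sim$cohort
  ms2 <- ms
  ms2$score <- co$sdfr[match(ms$subject_ids, co$subject_id)]
  tab2 <- suppressWarnings(
    maturity_em_association(ms2, co, specificity = FALSE))
  expect_equal(tab2$r[tab2$behavior == "sdfr"], 1)
  expect_true(tab2$pass_fdr[tab2$behavior == "sdfr"])
  # missing discrimination column: panel skipped with a warning
  co$discrimination <- NULL
  expect_warning(tab3 <- maturity_em_association(ms, co), "specificity")
  expect_false("specificity" %in% tab3$panel)
})

test_that("age-group interaction: null case, grouping rule and power on a planted slope difference", {
  # identical slope and intercept in both groups: interaction exactly 0
  age <- c(seq(4, 6.8, length.out = 10), seq(7, 12, length.out = 10))
  score <- rep(seq(-2, 2, length.out = 10), 2)
  em <- 3 + 1.5 * score
  ir <- suppressWarnings(age_group_interaction(score, em, age))  # exact fit
  expect_lt(abs(ir$interaction_coefficient), 1e-9)
  expect_equal(ir$slope_younger, 1.5, tolerance = 1e-9)
  expect_equal(ir$slope_older, 1.5, tolerance = 1e-9)
  # age exactly 7 joins the older group
  expect_equal(ir$n_older, 10L)
  expect_error(age_group_interaction(score, em, age, cutoff = 3),
               "grouping error")

  # planted slope difference 0.5 vs 0.0 at n = 200 is detected reliably
  hits <- 0L
  for (i in 1:20) {
    set.seed(300 + i)
    agei <- runif(200, 4, 12)
    sci <- rnorm(200)
    emi <- ifelse(agei >= 7, 0.5 * sci, 0) + rnorm(200, sd = 0.5)
    hits <- hits + (age_group_interaction(sci, emi, agei)$interaction_p
                    < 0.05)
  }
  expect_gte(hits / 20, 0.9)

  # equal slopes at n = 37: interaction significant only at chance level
  fp <- 0L
  for (i in 1:100) {
    set.seed(600 + i)
    agei <- runif(37, 4, 12)
    sci <- rnorm(37)
    emi <- 0.5 * sci + rnorm(37, sd = 0.7)
    fp <- fp + (age_group_interaction(sci, emi, agei)$interaction_p < 0.05)
  }
  expect_lte(fp / 100, 0.12)
})
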