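# reverse-correlation analysis: kernels, ANOVA, double pass, convergence

make_trials <- function(n, k = 4L, seed = 1L, choice = NULL) {
  set.seed(seed)
  A <- matrix(rnorm(n * k), n, k)
  B <- matrix(rnorm(n * k), n, k)
  if (is.null(choice)) choice <- sample(c("A", "B"), n, replace = TRUE)
  response_set("p1", seq_len(n), A, B, choice)
}

profile_matrix_for_test <- function(tr, which) {
  unname(as.matrix(tr[, grep(paste0("^", which, "_"), names(tr))]))
}

test_that("first-order kernel is mean(selected) - mean(rejected)", {
  # one trial, log domain: ln 2 - ln 0.5
  tr <- response_set("p", 1L, matrix(2), matrix(0.5), "A")
  k <- compute_first_order_kernel(tr, domain = "log")
  expect_equal(k$values, log(2) - log(0.5), tolerance = 1e-12)
  expect_equal(k$values, 1.3863, tolerance = 1e-4)

  # direct check against the defining formula on random data
  tr2 <- make_trials(200, seed = 21)
  A <- as.matrix(tr2[, paste0("A_", 1:4)])
  B <- as.matrix(tr2[, paste0("B_", 1:4)])
  sel <- tr2$choice == "A"
  manual <- colMeans(rbind(A[sel, ], B[!sel, ])) -
    colMeans(rbind(B[sel, ], A[!sel, ]))
  expect_equal(compute_first_order_kernel(tr2)$values,
               unname(manual), tolerance = 1e-12)

  # coin-flip responder: every element within 3 SEs of zero
  tr3 <- make_trials(10000, seed = 31)
  k3 <- compute_first_order_kernel(tr3)$values
  se <- sqrt(2 / 10000) * 2                  # var of a mean difference
  expect_true(all(abs(k3) < 3 * se))

  expect_error(compute_first_order_kernel(tr3[0, ]), "empty")
  trneg <- response_set("p", 1L, matrix(-1), matrix(1), "A")
  expect_error(compute_first_order_kernel(trneg, "log"), "positive")
})

test_that("kernel sign and interval symmetries hold", {
  tr <- make_trials(500, seed = 41)
  k <- compute_first_order_kernel(tr)$values
  flipped <- tr
  flipped$choice <- ifelse(tr$choice == "A", "B", "A")
  expect_equal(compute_first_order_kernel(flipped)$values, -k,
               tolerance = 1e-12)

  # swapping the A/B columns together with the choice leaves it intact
  swapped <- response_set("p1", tr$trial,
                          as.matrix(tr[, paste0("B_", 1:4)]),
                          as.matrix(tr[, paste0("A_", 1:4)]),
                          ifelse(tr$choice == "A", "B", "A"))
  expect_equal(compute_first_order_kernel(swapped)$values, k,
               tolerance = 1e-12)
})

test_that("normalize_kernel divides by the absolute sum", {
  expect_equal(normalize_kernel(c(2, -2))$values, c(0.5, -0.5))
  expect_error(normalize_kernel(c(0, 0)), "zero")
  set.seed(51)
  for (i in 1:20) {
    k <- normalize_kernel(rnorm(7))
    expect_equal(sum(abs(k$values)), 1, tolerance = 1e-12)
    expect_true(k$normalized)
  }
})

test_that("rm_anova matches the aov sums-of-squares oracle", {
  # identical columns: zero between-segment variance
  flat <- matrix(rep(rnorm(4), 3), 4, 3)
  expect_equal(rm_anova(flat)$F, 0, tolerance = 1e-12)

  set.seed(61)
  for (i in 1:10) {
    m <- matrix(rnorm(35), 5, 7)
    r <- rm_anova(m)
    d <- data.frame(y = as.vector(m), subj = factor(row(m)),
                    seg = factor(col(m)))
    a <- summary(stats::aov(y ~ seg + Error(subj / seg), data = d))
    strat <- a[["Error: subj:seg"]][[1]]
    expect_equal(r$F, strat["seg", "F value"], tolerance = 1e-9)
    expect_equal(r$p, strat["seg", "Pr(>F)"], tolerance = 1e-9)
    expect_equal(r$df, c(6L, 24L))
  }
  expect_error(rm_anova(matrix(c(1, NA, 2, 3), 2, 2)), "complete")
  expect_error(rm_anova(matrix(1:3, 1, 3)), ">= 2")
})

test_that("mixed_anova matches aov and behaves under the null", {
  set.seed(71)
  for (sizes in list(c(3, 3), c(3, 5))) {
    n <- sum(sizes)
    m <- matrix(rnorm(n * 4), n, 4)
    g <- rep(c("g1", "g2"), sizes)
    mx <- mixed_anova(m, g)
    d <- data.frame(y = as.vector(m), subj = factor(row(m)),
                    seg = factor(col(m)), g = factor(g[row(m)]))
    a <- summary(stats::aov(y ~ g * seg + Error(subj / seg), data = d))
    strat <- a[["Error: subj:seg"]][[1]]
    expect_equal(mx$F_within, strat["seg", "F value"], tolerance = 1e-9)
    expect_equal(mx$F_interaction, strat["g:seg", "F value"],
                 tolerance = 1e-9)
  }

  # duplicated groups: interaction vanishes
  base <- matrix(rnorm(12), 3, 4)
  dup <- rbind(base, base)
  mx0 <- mixed_anova(dup, rep(c("a", "b"), each = 3))
  expect_lt(mx0$F_interaction, 1e-20)

  # permuted labels: mean interaction F near 1
  set.seed(81)
  m <- matrix(rnorm(10 * 5), 10, 5)
  fs <- replicate(200, mixed_anova(m, sample(rep(c("a", "b"), 5)))
                  $F_interaction)
  expect_gt(mean(fs), 0.7)
  expect_lt(mean(fs), 1.4)

  expect_error(mixed_anova(m, rep(c("a", "b"), c(9, 1))), ">= 2")
})

test_that("double_pass_agreement pairs the repeated block", {
  A <- matrix(rnorm(20), 10, 2); B <- matrix(rnorm(20), 10, 2)
  same <- rbind(
    response_set("p", 1:10, A, B, rep("A", 10), pass = "double1"),
    response_set("p", 11:20, A, B, rep("A", 10), pass = "double2"))
  expect_equal(double_pass_agreement(same)$agreement, 1)
  expect_equal(double_pass_agreement(same)$prop_a, 1)

  rev <- same
  rev$choice[rev$pass == "double2"] <- "B"
  expect_equal(double_pass_agreement(rev)$agreement, 0)
  expect_equal(double_pass_agreement(rev)$prop_a, 0.5)

  # a deterministic unbiased observer agrees with itself
  obs <- observer_model(c(1, -1), internal_noise_sd = 0)
  ch1 <- simulate_observer(obs, A, B, scale = 1)
  ch2 <- simulate_observer(obs, A, B, scale = 1)
  both <- rbind(
    response_set("p", 1:10, A, B, ch1, pass = "double1"),
    response_set("p", 11:20, A, B, ch2, pass = "double2"))
  expect_equal(double_pass_agreement(both)$agreement, 1)

  unpaired <- same[-1, ]
  expect_error(double_pass_agreement(unpaired), "pair")
})

test_that("internal-noise estimator inverts its own model", {
  # noiseless, unbiased limit
  est <- estimate_internal_noise(1.0, 0.5)
  expect_lt(est$sigma, 0.05)
  expect_true(est$reliable)

  # analytic prediction at sigma = 1, b = 0 (evidence difference has
  # variance 2; sigma counts in per-interval units) inverts to sigma = 1
  xs <- seq(-8, 8, length.out = 4001)
  w <- dnorm(xs); w <- w / sum(w)
  p <- pnorm(sqrt(2) * xs / 1)
  agree1 <- sum(w * (p^2 + (1 - p)^2))
  expect_gt(agree1, 0.70); expect_lt(agree1, 0.85)
  est1 <- estimate_internal_noise(agree1, 0.5)
  expect_equal(est1$sigma, 1, tolerance = 0.051)

  expect_warning(est_bad <- estimate_internal_noise(0.3, 0.5),
                 "unreliable")
  expect_false(est_bad$reliable)
  expect_error(estimate_internal_noise(1.2, 0.5), "\\[0, 1\\]")
})

test_that("internal-noise recovery is within 30% at case-2 size", {
  set.seed(91)
  tmpl <- c(0.2, -0.1, 1, 0.4, 0, -0.3)
  for (sigma in c(0.5, 1, 2)) {
    est <- replicate(60, {
      obs <- observer_model(tmpl, internal_noise_sd = sigma)
      res <- simulate_experiment("case2", obs, n_trials = 60,
                                 double_pass_n = 33L)
      dp <- double_pass_agreement(res)
      suppressWarnings(
        estimate_internal_noise(dp$agreement, dp$prop_a)$sigma)
    })
    expect_lt(abs(median(est) - sigma) / sigma, 0.30)
  }
})

test_that("kernel_convergence rises toward 1", {
  set.seed(101)
  tmpl <- c(-0.1, 0, 0.1, 0.2, 1, 0.3)
  obs <- observer_model(tmpl, internal_noise_sd = 1)
  res <- simulate_experiment("case1", obs, 700, double_pass_n = 0L)
  cv <- kernel_convergence(res, step = 70)
  expect_equal(tail(cv$correlation, 1), 1, tolerance = 1e-12)
  expect_equal(tail(cv$n, 1), 700L)

  # later estimates beat early ones in most replicates
  wins <- replicate(30, {
    r <- simulate_experiment("case1", obs, 350, double_pass_n = 0L)
    cc <- kernel_convergence(r, step = 70)
    cc$correlation[cc$n == 280] >= cc$correlation[cc$n == 70]
  })
  expect_gte(mean(wins), 0.7)

  expect_error(kernel_convergence(res[1:30, ], step = 20), "2 \\* step")
})

test_that("response tables round trip through CSV with mapping", {
  tr <- make_trials(25, seed = 111)
  tr$pass[1:10] <- c(rep("double1", 5), rep("double2", 5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_response_table(tr, f)
  back <- read_response_table(f)
  expect_equal(as.data.frame(back), as.data.frame(tr))

  # foreign layout via explicit mapping
  df <- utils::read.csv(f)
  names(df) <- sub("^A_", "int1_seg", names(df))
  names(df) <- sub("^B_", "int2_seg", names(df))
  names(df)[names(df) == "choice"] <- "resp"
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f2, row.names = FALSE)
  mapped <- read_response_table(f2, mapping = list(
    participant = "participant", trial = "trial", choice = "resp",
    pass = "pass", a_prefix = "int1_seg", b_prefix = "int2_seg"))
  expect_equal(profile_matrix_for_test(mapped, "A"),
               profile_matrix_for_test(tr, "A"))
})
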