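test_that("sampled sojourns follow the exponential exit-rate law", {
  Q <- three_state_Q(ab = 300, ba = 50, bc = 120, cb = 70)
  # absorbing state: single sojourn spans the whole duration
  Qa <- matrix(0, 2, 2, dimnames = list(c("s", "t"), c("s", "t")))
  Qa["s", "t"] <- 0  # no exits at all from either state
  p <- sample_ctmc_path(Qa, 123.4, p0 = c(1, 0), seed = 1)
  expect_equal(nrow(p), 1L)
  expect_equal(p$sojourn_ms, 123.4)
  expect_identical(p$state, "s")
  # mean sojourn in a state ~ 1 / total exit rate
  p <- sample_ctmc_path(Q, 60000, seed = 2)
  expect_gt(sum(p$state == "a"), 1000)
  complete <- p[-nrow(p), ]  # last sojourn is truncated
  m_a <- mean(complete$sojourn_ms[complete$state == "a"])
  expect_equal(m_a, 1000 / 300, tolerance = 0.1)
  m_b <- mean(complete$sojourn_ms[complete$state == "b"])
  expect_equal(m_b, 1000 / 170, tolerance = 0.1)
  # sojourns are positive and sum to the duration
  expect_true(all(p$sojourn_ms > 0))
  expect_equal(sum(p$sojourn_ms), 60000, tolerance = 1e-9)
  expect_error(sample_ctmc_path(Q, 100, p0 = c(1, 1, 1)), "initial")
})

test_that("jump targets follow the off-diagonal rate proportions", {
  Q <- three_state_Q(ab = 300, ba = 50, bc = 120, cb = 70)
  p <- sample_ctmc_path(Q, 120000, seed = 3)
  # from b, jumps to a vs c should split 50:120
  from_b <- which(p$state[-nrow(p)] == "b")
  nxt <- p$state[from_b + 1L]
  n <- length(nxt)
  phat <- mean(nxt == "a")
  p0 <- 50 / 170
  expect_lt(abs(phat - p0), 3 * sqrt(p0 * (1 - p0) / n))
})

test_that("path discretization preserves occupancy and handles aliasing", {
  # constant path
  p1 <- data.frame(state = "x", sojourn_ms = 10)
  expect_identical(discretize_path(p1, 0.2), rep("x", 50))
  # sojourn shorter than dt straddling no sampling instant leaves no sample
  p2 <- data.frame(state = c("x", "y", "x"), sojourn_ms = c(0.3, 0.05, 9.65))
  expect_false("y" %in% discretize_path(p2, 0.2))
  # occupancy fractions track continuous occupancy on long paths
  Q <- three_state_Q()
  path <- sample_ctmc_path(Q, 50000, seed = 4)
  st <- discretize_path(path, 0.2)
  cont <- tapply(path$sojourn_ms, path$state, sum) / sum(path$sojourn_ms)
  disc <- table(st) / length(st)
  expect_equal(as.numeric(disc[names(cont)]), as.numeric(cont),
               tolerance = 0.02)
})

test_that("emitted traces have the configured group levels and noise", {
  em <- emission_model()
  states <- c("M", "M*", "M2*", "M3**", "M0", "M1")
  # zero-noise emission reproduces the exact group means
  em0 <- emission_model(sigma = 1e-12)
  tr0 <- emit_trace(states, em0)
  expect_equal(tr0$current_pA,
               unname(em$mu[c("M", "M", "M2", "M3", "M0", "M1")]),
               tolerance = 1e-6)
  # default levels derive from residual-current fractions of I_o = -433.3 pA
  expect_equal(unname(em$mu["M"]), -199.3, tolerance = 0.05)
  expect_equal(unname(em$mu["M1"]), -211.0, tolerance = 0.05)
  expect_equal(unname(em$mu["M2"]), -221.0, tolerance = 0.05)
  expect_equal(unname(em$mu["M3"]), -233.1, tolerance = 0.05)
  expect_equal(unname(em$mu["M0"]), -180)
  # sample sd tracks the configured sigma (default 8, within 7-10)
  tr <- emit_trace(rep("M2*", 20000), em, seed = 6)
  expect_equal(sd(tr$current_pA), 8, tolerance = 0.05)
  expect_true(em$sigma[["M2"]] >= 7 && em$sigma[["M2"]] <= 10)
})

test_that("simulate_experiment honours the design and is reproducible", {
  expect_length(simulate_experiment(design = experiment_design(
    data.frame(atp_mM = numeric(), amp_mM = numeric(), adp_mM = numeric(),
               n_replicates = integer(), duration_ms = numeric())),
    seed = 1), 0L)
  # default design: the six ATP/AMP concentration pairs
  d <- experiment_design()
  expect_equal(nrow(d$conditions), 6L)
  expect_equal(d$conditions$atp_mM, c(0.01, 0.10, 1.00, 1.00, 1.00, 1.00))
  expect_equal(d$conditions$amp_mM, c(0.00, 0.00, 0.00, 0.01, 0.10, 1.00))
  # ADP titration: seven concentrations
  expect_equal(adp_design()$conditions$adp_mM,
               c(0.01, 0.02, 0.05, 0.10, 0.20, 0.50, 1.00))
  small <- experiment_design(data.frame(
    atp_mM = c(0.1, 1), amp_mM = 0, adp_mM = 0, n_replicates = 2L,
    duration_ms = 300))
  tr1 <- simulate_experiment(rate_vector(), "V3", small, seed = 11)
  tr2 <- simulate_experiment(rate_vector(), "V3", small, seed = 11)
  expect_length(tr1, 4L)
  expect_identical(lapply(tr1, `[[`, "current_pA"),
                   lapply(tr2, `[[`, "current_pA"))
  tr3 <- simulate_experiment(rate_vector(), "V3", small, seed = 12)
  expect_false(identical(tr1[[1]]$current_pA, tr3[[1]]$current_pA))
})

test_that("artifact injection creates the excursions segment selection removes", {
  set.seed(8)
  tr <- ak_trace(rnorm(5000, -210, 8), conc = ligand_conc(atp_mM = 1))
  # zero artifacts: unchanged
  expect_identical(inject_artifacts(tr, data.frame()), tr)
  # one 100 ms open-pore insertion: exactly one deep stretch
  art <- data.frame(type = "open_pore", at_ms = 400, duration_ms = 100)
  tr2 <- inject_artifacts(tr, art, seed = 9)
  idx <- 2001:2500  # 400-500 ms at 0.2 ms
  expect_lt(mean(tr2$current_pA[idx]), -400)
  expect_gt(mean(tr2$current_pA[-idx]), -240)
  # reproducible random placement
  artr <- data.frame(type = "shallow", at_ms = NA, duration_ms = 50)
  a1 <- inject_artifacts(tr, artr, seed = 10)
  a2 <- inject_artifacts(tr, artr, seed = 10)
  expect_identical(a1$current_pA, a2$current_pA)
})

test_that("dose-response generator reproduces the Hill curve exactly at zero noise", {
  cc <- c(10, 20, 50, 100, 200, 500, 1000)
  d <- simulate_dose_response(K_D = 45.4, n = 2.3, y_max = 100, conc = cc)
  expect_equal(d$response, 100 * cc^2.3 / (45.4^2.3 + cc^2.3))
  # midpoint identity at c = K_D for any n
  d2 <- simulate_dose_response(K_D = 50, n = 1.7, y_max = 80, conc = 50)
  expect_equal(d2$response, 40)
  # determinism
  d3 <- simulate_dose_response(45.4, 2.3, 100, cc, noise_sd = 3,
                               replicates = 3, seed = 14)
  d4 <- simulate_dose_response(45.4, 2.3, 100, cc, noise_sd = 3,
                               replicates = 3, seed = 14)
  expect_identical(d3, d4)
  expect_true(all(d3$response >= 0 & d3$response <= 100))
  expect_error(simulate_dose_response(45, 2, 100, conc = c(-1, 10)),
               "positive")
})

test_that("simulated paths reach the stationary occupancy of the generator", {
  r <- rate_vector()
  conc <- ligand_conc(atp_mM = 1, amp_mM = 0.1)
  Q <- build_generator(r, conc, "V3")
  path <- sample_ctmc_path(Q, 200000, seed = 15)
  lid_closed <- c("M2*", "M2**", "M3**")
  occ <- sum(path$sojourn_ms[path$state %in% lid_closed]) /
    sum(path$sojourn_ms)
  d <- stationary_distribution(discretize(Q, 0.2))
  expect_lt(abs(occ - sum(d[lid_closed])), 0.02)
})

test_that("traces carry more likelihood at generating than perturbed rates", {
  truth <- rate_vector()
  design <- experiment_design(data.frame(
    atp_mM = c(0.1, 1), amp_mM = c(0, 1), adp_mM = 0, n_replicates = 1L,
    duration_ms = 1500))
  traces <- simulate_experiment(truth, "V3", design, seed = 16)
  em <- emission_model()
  ll <- joint_loglik(truth, em, traces, "V3")
  perturbed <- truth
  perturbed[c("r1", "rm1")] <- perturbed[c("r1", "rm1")] * c(0.1, 10)
  expect_gt(ll, joint_loglik(perturbed, em, traces, "V3"))
})
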