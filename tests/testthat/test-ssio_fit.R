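test_that("PLS weight initialisation normalises and ranks regulators", {
  # single-regulator target: the weight is +/-1 after L1 normalisation
  net1 <- regulatory_network(c("x", "t"), rbind(regulation("x", "t", 1)))
  set.seed(31)
  xv <- stats::runif(20, 50, 150)
  es1 <- expression_series(rbind(x = xv, t = 30 + 2 * xv), 0:19)
  w1 <- initialize_weights(es1, net1)
  expect_equal(w1$q[w1$target == "t"], 1)

  # a target identical to its activator is explained with near-zero residual
  es2 <- expression_series(rbind(x = xv, t = xv), 0:19)
  pls <- fit_pls(normalize_features(rbind(x = xv))$values, xv)
  expect_lt(sqrt(min(pls$rss)), 1e-8)
  expect_equal(initialize_weights(es2, net1)$q[2 - 1], 1)

  # three independent regulators with weights 0.6/0.3/0.1: the recovered
  # ranking preserves the generating order
  net3 <- regulatory_network(
    c("x1", "x2", "x3", "t"),
    rbind(regulation("x1", "t", 1), regulation("x2", "t", 1),
          regulation("x3", "t", 1)))
  set.seed(32)
  X <- matrix(stats::runif(60, 50, 150), 3, 20,
              dimnames = list(c("x1", "x2", "x3"), NULL))
  y <- 50 + drop(c(0.6, 0.3, 0.1) %*% X)
  es3 <- expression_series(rbind(X, t = y), 0:19)
  w3 <- initialize_weights(es3, net3)
  q3 <- w3$q[order(w3$source)]
  expect_true(q3[1] > q3[2] && q3[2] > q3[3])
})

test_that("kinetics fitting recovers degradation on dense constitutive data", {
  net <- regulatory_network("g", NULL)
  times <- seq(0, 12, by = 0.5)
  Fd <- 50 / 0.4
  es <- expression_series(
    rbind(g = Fd + (30 - Fd) * exp(-0.4 * times)), times)
  w <- weight_vector(net)
  kin <- fit_kinetics(es, net, w)
  expect_equal(kin["g", "d"], 0.4, tolerance = 0.05)
  # the implied basal rate is recovered too (k1, k2 only enter via k1/(1+k2))
  expect_equal(constitutive_rate(as.list(kin["g", ])), 50,
               tolerance = 0.05 * 50)
})

test_that("a perfect initialisation is a fixed point of kinetics fitting", {
  cs <- make_recovery_case("cascade3")
  kin <- fit_kinetics(cs$series, cs$net, cs$weights,
                      kinetics_init = cs$kinetics)
  # degradation rates and the basal rate are identified; k1 and k2 of a
  # constitutive gene only enter through k1/(1+k2)
  expect_equal(kin$d, cs$kinetics$d, tolerance = 1e-3)
  expect_equal(constitutive_rate(as.list(kin["g1", ])),
               constitutive_rate(as.list(cs$kinetics["g1", ])),
               tolerance = 0.01)
  expect_equal(kin["g2", "k3"], cs$kinetics["g2", "k3"], tolerance = 0.02)
  m <- grn_model(cs$net, kin, cs$weights)
  expect_lt(one_step_residual(cs$series, m)$residual_sq,
            1e-4 * sum(cs$series$values^2))
})

test_that("two-point kinetics fitting matches a grid search over d", {
  net <- regulatory_network("g", NULL)
  es <- expression_series(rbind(g = c(100, 80)), c(0, 1))
  # pin k1 and k2 so the shooting error is one-dimensional in d
  b <- default_kinetics_bounds(es)
  b$k1 <- c(60 - 1e-9, 60 + 1e-9)
  b$k2 <- c(1 - 1e-9, 1 + 1e-9)
  kin <- fit_kinetics(es, net, weight_vector(net),
                      kinetics_init = gene_kinetics("g", 60, 1, 1, 0.5),
                      config = ssio_config(bounds = b))
  # oracle: dense grid over the closed-form one-step prediction
  ds <- seq(0.01, 3, by = 1e-4)
  pred <- 30 / ds + (100 - 30 / ds) * exp(-ds)
  d_star <- ds[which.min((pred - 80)^2)]
  expect_equal(kin["g", "d"], d_star, tolerance = 1e-3)
})

test_that("effective parameter count follows the arctangent change rule", {
  net <- regulatory_network(c("a", "t"), rbind(regulation("a", "t", 1)))
  w0 <- weight_vector(net, q = 0)
  w1 <- weight_vector(net, q = 1)
  expect_equal(effective_parameters(w1, w1, 5), 0)     # no change
  expect_equal(effective_parameters(w1, w0, 1), 0)     # ln(1) = 0
  expect_equal(effective_parameters(w1, w0, 3), (pi / 4) * log(3),
               tolerance = 1e-12)
  net2 <- regulatory_network(c("b", "t"), rbind(regulation("b", "t", 1)))
  expect_error(effective_parameters(w1, weight_vector(net2, q = 1), 2),
               "KeyMismatch")
})

test_that("the BIC combines residual and penalty monotonically", {
  expect_equal(bic_score(10, 2, 10), 10 * log(1) + 2 * log(10),
               tolerance = 1e-12)
  expect_lt(bic_score(5, 2, 10), bic_score(10, 2, 10))
  expect_gt(bic_score(10, 3, 10), bic_score(10, 2, 10))
  expect_error(bic_score(1, 0, 0), "N must be")
  # zero residual is floored, not -Inf
  expect_true(is.finite(bic_score(0, 0, 5)))
})

test_that("weight updates leave a converged solution unchanged", {
  cs <- make_recovery_case("cascade3")
  fit <- run_ssio(cs$series, cs$net, ssio_config(max_iterations = 10))
  w2 <- update_weights(cs$series, cs$net, fit$best$weights,
                       fit$best$kinetics)
  expect_equal(w2$q, fit$best$weights$q, tolerance = 1e-6)
})

test_that("masked timepoints do not influence the masked target's weights", {
  cs <- make_recovery_case("adipo_mini5")
  cfg <- ssio_config(schedule = cs$schedule, masks = list(mB = 3:5))
  w_ref <- initialize_weights(cs$series, cs$net, cfg)
  # perturb the masked target's samples inside the masked window
  pert <- cs$series
  pert$values["mB", 3:5] <- pert$values["mB", 3:5] * 3
  w_pert <- initialize_weights(pert, cs$net, cfg)
  expect_equal(w_pert$q[w_pert$target == "mB"],
               w_ref$q[w_ref$target == "mB"], tolerance = 1e-12)
  u_ref <- update_weights(cs$series, cs$net, w_ref, cs$kinetics, cfg)
  u_pert <- update_weights(pert, cs$net, w_ref, cs$kinetics, cfg)
  expect_equal(u_pert$q[u_pert$target == "mB"],
               u_ref$q[u_ref$target == "mB"], tolerance = 1e-9)
})

test_that("the SSIO loop records history, selects by BIC and is deterministic", {
  cs <- make_recovery_case("cascade3")
  f1 <- run_ssio(cs$series, cs$net, ssio_config(max_iterations = 1))
  expect_length(f1$history, 1)
  expect_identical(f1$best$index, 1L)
  expect_identical(f1$stop_reason,
                   if (f1$converged) "weight_convergence" else "max_iterations")

  fit <- run_ssio(cs$series, cs$net, ssio_config(max_iterations = 5))
  bics <- vapply(fit$history, `[[`, 0, "bic")
  expect_equal(fit$best$bic, min(bics))
  # the selected iterate does not fit worse than the first
  expect_lte(fit$best$residual_sq, fit$history[[1]]$residual_sq)

  # bitwise-identical serialisation on re-run
  d1 <- tempfile(); d2 <- tempfile()
  write_fit_result(run_ssio(cs$series, cs$net,
                            ssio_config(max_iterations = 3)), d1)
  write_fit_result(run_ssio(cs$series, cs$net,
                            ssio_config(max_iterations = 3)), d2)
  for (f in c("kinetics.tsv", "weights.tsv", "fit.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("sign constraint and penalty can be disabled for the over-fitting demo", {
  cs <- make_recovery_case("adipo_mini5")
  cfg <- ssio_config(max_iterations = 2, schedule = cs$schedule,
                     sign_constraints = FALSE, penalty = FALSE)
  fit <- run_ssio(cs$series, cs$net, cfg)
  expect_s3_class(fit, "ssio_fit")
  # with the constraint off, the repressor's weight is no longer forced
  # to its declared sign by construction (it may still come out negative,
  # but the machinery must accept either)
  expect_true(is.finite(fit$best$residual_sq))
})

test_that("the stimulus-response diagnostic separates on and off behaviour", {
  cs <- make_recovery_case("adipo_mini5")
  m <- grn_model(cs$net, cs$kinetics, cs$weights, cs$schedule)
  chk <- check_signal_response(m, cs$series, markers = cs$truth$markers)
  expect_true(chk$ok)
  # zeroed regulatory weights cannot respond
  m0 <- grn_model(cs$net, cs$kinetics,
                  weight_vector(cs$net, q = rep(0, nrow(cs$net$regulations))),
                  cs$schedule)
  expect_false(check_signal_response(m0, cs$series,
                                     markers = cs$truth$markers)$ok)
})
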