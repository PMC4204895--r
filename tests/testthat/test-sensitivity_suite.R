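test_that("prior ranges follow the role rules", {
  theta <- c(w1 = 0.7, d1 = 0.5, o_big = 0.3, o_small = 0.1)
  roles <- c(w1 = "weight", d1 = "degradation", o_big = "other",
             o_small = "other")
  pr <- build_prior(theta, roles)
  expect_equal(pr$lo, c(0, 0.4, 0, 0))
  expect_equal(pr$hi, c(1, 0.6, 0.6, 0.5))
  # degradation range is floored above zero
  pr2 <- build_prior(c(d = 0.05), c(d = "degradation"))
  expect_gt(pr2$lo, 0)
  expect_error(build_prior(c(a = 1), c(a = "banana")), "ConfigError")
})

test_that("metropolis acceptance matches the analytic ratio", {
  prior <- build_prior(c(x = 0.5), c(x = "weight"))
  # an improving proposal is always accepted
  set.seed(41)
  st <- metropolis_step(c(x = 0.5), err_n = 2,
                        prior = prior, err_fn = function(t) 1)
  expect_true(st$accepted)
  expect_equal(st$alpha, 1)

  # flat landscape: long-run acceptance tends to 1
  set.seed(42)
  acc <- replicate(2000, metropolis_step(c(x = 0.5), 1, prior,
                                         function(t) 1)$accepted)
  expect_equal(mean(acc), 1)

  # err_n = 1, err* = 2: acceptance frequency 0.5 within 3 sigma binomial
  set.seed(43)
  n <- 1e4
  acc <- replicate(n, metropolis_step(c(x = 0.5), 1, prior,
                                      function(t) 2)$accepted)
  expect_lt(abs(mean(acc) - 0.5), 3 * sqrt(0.25 / n))

  # a non-finite proposal error is rejected with diagnostics
  st2 <- metropolis_step(c(x = 0.5), 1, prior, function(t) NaN)
  expect_false(st2$accepted)
  expect_equal(st2$alpha, 0)
})

test_that("the chain is seed-reproducible and handles empty runs", {
  prior <- build_prior(c(a = 0.5, b = 0.5), c(a = "weight", b = "other"))
  err_fn <- function(theta) 1 + sum(theta^2)
  t1 <- run_mcmc(err_fn, prior, 200, seed = 7, burn_in = 0)
  t2 <- run_mcmc(err_fn, prior, 200, seed = 7, burn_in = 0)
  expect_identical(t1$samples, t2$samples)
  expect_identical(t1$accepted, t2$accepted)
  expect_warning(t0 <- run_mcmc(err_fn, prior, 0, seed = 1),
                 "empty trace")
  expect_equal(nrow(t0$samples), 0)

  f <- tempfile(fileext = ".tsv")
  write_trace(t1, f)
  expect_true(file.exists(f) && file.exists(paste0(f, ".json")))
})

test_that("K-S sensitivity calibrates under null and signal", {
  p <- 3
  prior <- build_prior(stats::setNames(rep(0.5, p), paste0("w", 1:p)),
                       stats::setNames(rep("weight", p), paste0("w", 1:p)))
  n <- 12000; burn <- 2000
  set.seed(44)
  S <- matrix(stats::runif(n * p), n, p,
              dimnames = list(NULL, prior$parameter))
  # independence null: a fair coin unrelated to the parameters
  tr <- structure(list(samples = S, err = rep(1, n),
                       accepted = rep(TRUE, n),
                       behavioral = stats::runif(n) < 0.5,
                       burn_in = burn, prior = prior, seed = 44),
                  class = "mcmc_trace")
  tab <- ks_sensitivity(tr, bins = 10)
  expect_true(all(tab$statistic < 0.05))
  expect_equal(tab$n_behavioral + tab$n_nonbehavioral, rep(n - burn, p))

  # behavioural iff parameter 1 exceeds its prior median: near-maximal
  # statistic for w1, null-level for the others
  tr$behavioral <- S[, 1] > 0.5
  tab2 <- ks_sensitivity(tr, bins = 10)
  expect_gte(tab2$statistic[1], 0.95)
  expect_true(all(tab2$statistic[2:3] < 0.05))

  # one empty class: undefined, reported not raised
  tr$behavioral <- rep(TRUE, n)
  expect_true(all(is.na(ks_sensitivity(tr)$statistic)))
})

test_that("behavioural classification applies the midpoint rule strictly", {
  cs <- make_recovery_case("adipo_mini5")
  model <- grn_model(cs$net, cs$kinetics, cs$weights, cs$schedule)
  fl <- flatten_parameters(model, which = "weights")
  expect_true(all(fl$roles == "weight"))
  # the reference parameters pass their own criteria
  expect_true(classify_behavioral(fl$theta, model, cs$series,
                                  markers = cs$truth$markers))
  # zeroed weights do not respond
  expect_false(classify_behavioral(0 * fl$theta, model, cs$series,
                                   markers = cs$truth$markers))

  # a marker exactly at its threshold fails (strict inequality):
  # a constitutive gene frozen at its steady state has pre = post =
  # threshold = end level with and without stimuli
  net <- regulatory_network("g", NULL)
  m1 <- grn_model(net, gene_kinetics("g", k1 = 100, k2 = 1, d = 0.4),
                  weight_vector(net))
  es <- expression_series(rbind(g = rep(125, 5)), 0:4, floor = 0)
  expect_false(check_signal_response(m1, es, markers = "g")$ok)
})

test_that("parameter flattening and patching are inverse operations", {
  cs <- make_recovery_case("adipo_mini5")
  model <- grn_model(cs$net, cs$kinetics, cs$weights, cs$schedule)
  fl <- flatten_parameters(model, which = "all")
  m2 <- patch_parameters(model, fl$theta)
  expect_equal(m2$weights$q, model$weights$q)
  expect_equal(as.data.frame(m2$kinetics), as.data.frame(model$kinetics))
  # patched weights keep the declared sign
  th <- fl$theta
  th["q.mP.mR"] <- 0.3   # magnitude; the edge represses
  m3 <- patch_parameters(model, th)
  expect_equal(m3$weights$q[m3$weights$target == "mP" &
                              m3$weights$source == "mR"], -0.3)
  expect_error(patch_parameters(model, c(q.zz.yy = 1)), "KeyMismatch")
})

test_that("bistability scans locate the saddle-node and order branches", {
  cs <- make_recovery_case("feedback_bistable2")
  m <- grn_model(cs$net, cs$kinetics, cs$weights)
  grid <- cs$truth$scan_grid
  sc <- bistability_scan(m, list(gene = "gA", param = "k1"), grid,
                         cs$truth$init_low, cs$truth$init_high)
  # brute-force oracle: smallest grid value with a single stable root
  n_stable <- vapply(grid, function(k)
    length(stable_roots_selfact(k, 150, 0.05, 0.12)), 0L)
  truth_trigger <- grid[which(n_stable == 1)[1]]
  expect_equal(sc$trigger_level, truth_trigger)
  expect_lte(abs(sc$trigger_level - truth_trigger), diff(grid)[1])
  # hysteresis: the low branch sits below the high branch wherever bistable
  bi <- which(sc$bistable)
  expect_true(all(sc$low[bi, "gA"] < sc$high[bi, "gA"]))
  # branch levels agree with the enumerated stable roots
  for (i in bi) {
    r <- stable_roots_selfact(grid[i], 150, 0.05, 0.12)
    expect_equal(unname(sc$low[i, "gA"]), r[1], tolerance = 1e-4)
    expect_equal(unname(sc$high[i, "gA"]), r[length(r)], tolerance = 1e-4)
  }

  # monostable control: identical branches everywhere, no trigger
  mono <- toy_two_gene(k1A = 10)
  sc0 <- bistability_scan(mono, list(gene = "gB", param = "k1"),
                          seq(10, 50, by = 10),
                          c(gA = 5, gB = 5), c(gA = 800, gB = 400))
  expect_false(any(sc0$bistable))
  expect_true(is.na(sc0$trigger_level))
  expect_equal(sc0$low, sc0$high, tolerance = 1e-5)
})

test_that("local sensitivity reports bistability loss and trigger shifts", {
  cs <- make_recovery_case("feedback_bistable2")
  m <- grn_model(cs$net, cs$kinetics, cs$weights)
  grid <- cs$truth$scan_grid
  ls <- local_sensitivity(m, list(gene = "gA", param = "k1"), grid,
                          cs$truth$init_low, cs$truth$init_high,
                          param = list(target = "gA", source = "gA"),
                          deltas = c(0, -1))
  # delta 0 reproduces the reference scan
  ref <- attr(ls, "reference")
  expect_true(ls$bistable[1])
  expect_equal(ls$trigger_level[1], ref$trigger_level)
  expect_equal(ls$trigger_shift[1], 0)
  # removing the self-activation (weight -> 0) destroys bistability:
  # brute force confirms a single root without feedback
  expect_false(ls$bistable[2])
  expect_length(stable_roots_selfact(30, 150, 0.05, 0.12, q = 0), 1)
})

test_that("importance ranking matches finite differences and zero weights rank last", {
  cs <- make_recovery_case("adipo_mini5")
  model <- grn_model(cs$net, cs$kinetics, cs$weights, cs$schedule)
  set.seed(45)
  lv <- stats::setNames(stats::runif(5, 30, 400), cs$net$genes)
  tab <- importance_rank(model, list(s = lv))

  # oracle: central finite differences of the target's rhs in the
  # regulator's level, times the level
  for (g in c("mA", "mP")) {
    wr <- weights_of(model$weights, g)
    for (i in seq_len(nrow(wr))) {
      src <- wr$source[i]
      if (!src %in% names(lv)) next
      h <- 1e-4 * max(lv[[src]], 1)
      up <- lv; up[[src]] <- up[[src]] + h
      dn <- lv; dn[[src]] <- dn[[src]] - h
      fd <- (grn_rhs(model, up, 10)[[g]] - grn_rhs(model, dn, 10)[[g]]) /
        (2 * h)
      got <- tab$importance[tab$target == g & tab$regulator == src]
      expect_equal(got, abs(fd) * lv[[src]],
                   tolerance = 1e-6 * max(abs(fd) * lv[[src]], 1e-12),
                   info = paste(g, src))
    }
  }

  # a zero-weight regulator scores zero and ranks last
  w0 <- model$weights
  w0$q[w0$target == "mP" & w0$source == "mR"] <- 0
  m0 <- grn_model(cs$net, cs$kinetics, w0, cs$schedule)
  t0 <- importance_rank(m0, list(s = lv))
  row <- t0[t0$target == "mP" & t0$regulator == "mR", ]
  expect_equal(row$importance, 0)
  expect_equal(row$rank, max(t0$rank[t0$target == "mP"]))

  # doubling a regulator's level in the linear regime raises its importance
  lv2 <- lv; lv2[["mB"]] <- 2 * lv[["mB"]]
  # keep A in the near-linear range for this check
  small <- stats::setNames(rep(5, 5), cs$net$genes)
  small2 <- small; small2[["mB"]] <- 10
  ta <- importance_rank(model, list(s = small))
  tb <- importance_rank(model, list(s = small2))
  expect_gt(tb$importance[tb$target == "mA" & tb$regulator == "mB"],
            ta$importance[ta$target == "mA" & ta$regulator == "mB"])
})

test_that("weighted-expression comparison matches a hand-rolled K-S test", {
  genes <- c("r1", "r2", "r3", "r4", "t")
  reg <- do.call(rbind, lapply(genes[1:4], function(s)
    regulation(s, "t", 1)))
  net <- regulatory_network(genes, reg)
  stages <- c(proliferating = -2, preadipocyte = 0, immature = 3,
              mature = 9)
  mk <- function(seed, shift = 0) {
    set.seed(seed)
    v <- matrix(stats::runif(5 * 4, 50, 150), 5, 4,
                dimnames = list(genes, NULL))
    v[1:4, 3:4] <- v[1:4, 3:4] + shift
    expression_series(v, c(-2, 0, 3, 9))
  }
  wa <- weight_vector(net, q = rep(0.5, 4))
  sa <- mk(51); sb <- mk(52, shift = 40)
  out <- weighted_expression_compare(wa, sa, wa, sb, "t", stages, stages)
  expect_equal(nrow(out), 3)

  # identical inputs: D = 0, p = 1
  same <- weighted_expression_compare(wa, sa, wa, sa, "t", stages, stages)
  expect_equal(same$D, rep(0, 3))
  expect_equal(same$p_value, rep(1, 3))

  # oracle: recompute D and the asymptotic p by hand for each transition
  zc <- function(series) {
    lev <- series$values[genes[1:4], ]
    wx <- 0.5 * lev
    ch <- wx[, -1] - wx[, -4]
    (ch - mean(ch)) / stats::sd(ch)
  }
  za <- zc(sa); zb <- zc(sb)
  for (k in 1:3) {
    hk <- ks2_hand(za[, k], zb[, k])
    expect_equal(out$D[k], hk$D, tolerance = 1e-12)
    expect_equal(out$p_value[k], hk$p, tolerance = 1e-6)
  }

  # fewer than two regulators: undefined
  net1 <- regulatory_network(c("r1", "t"), rbind(regulation("r1", "t", 1)))
  out1 <- weighted_expression_compare(weight_vector(net1, q = 1), sa,
                                      weight_vector(net1, q = 1), sb,
                                      "t", stages, stages)
  expect_true(all(is.na(out1$D)))
})
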