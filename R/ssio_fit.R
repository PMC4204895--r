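#' Configuration for the SSIO loop
#'
#' @param max_iterations cap on outer iterations (default 100).
#' @param tol convergence threshold on the relative L1 change of the weight
#'   vector between iterations (default 1e-8).
#' @param epsilon_sign magnitude used when flipping a sign-violating weight
#'   (default 1e-3).
#' @param c_max half-width of the search interval for the Step-7 update
#'   scalar (default 1).
#' @param lambda penalty weight of the log-penalized PLS component choice;
#'   `NULL` uses the sample variance of the output.
#' @param penalty set `FALSE` to keep every PLS component (over-fitting
#'   demonstration mode).
#' @param sign_constraints set `FALSE` to skip sign enforcement (same
#'   demonstration mode).
#' @param schedule optional [signal_schedule()].
#' @param masks named list: target gene -> integer indices of timepoints to
#'   exclude from that target's weight regression and scalar objective
#'   (e.g. the interval between preadipocyte and immature adipocyte for
#'   CEBPB, whose stimuli dominate there).
#' @param bounds kinetics box constraints, see [default_kinetics_bounds()].
#' @param kinetics_init optional [gene_kinetics()] starting point.
#' @param exclude_times optional integer indices of timepoints (e.g.
#'   interpolated ones) excluded from the reported residual.
#' @return list of class `ssio_config`.
#' @export
ssio_config <- function(max_iterations = 100, tol = 1e-8,
                        epsilon_sign = 1e-3, c_max = 1, lambda = NULL,
                        penalty = TRUE, sign_constraints = TRUE,
                        schedule = NULL, masks = NULL, bounds = NULL,
                        kinetics_init = NULL, exclude_times = NULL) {
  structure(list(max_iterations = max_iterations, tol = tol,
                 epsilon_sign = epsilon_sign, c_max = c_max,
                 lambda = lambda, penalty = penalty,
                 sign_constraints = sign_constraints, schedule = schedule,
                 masks = masks, bounds = bounds,
                 kinetics_init = kinetics_init,
                 exclude_times = exclude_times),
            class = "ssio_config")
}

#' Default box constraints for the kinetics parameters
#'
#' k1 is bounded by ten times the largest observed level (rates live on the
#' data's scale), k2 by 100, k3 by 10 and the degradation constant d by
#' 5/day with a small positive lower bound.
#'
#' @param series an [expression_series()].
#' @return list with elements k1, k2, k3, d, each `c(lower, upper)`.
#' @export
default_kinetics_bounds <- function(series) {
  list(k1 = c(1e-6, 10 * max(series$values)),
       k2 = c(1e-6, 100),
       k3 = c(1e-6, 10),
       d = c(1e-4, 5))
}

# regulator rows (training data for genes, schedule levels for signals)
# evaluated at the series timepoints; returns n_reg x K matrix in the
# order of the target's regulation rows
.regulator_knots <- function(series, net, target, schedule) {
  w <- regulators_of(net, target)
  K <- length(series$times)
  if (nrow(w) == 0L) return(matrix(0, 0, K))
  X <- matrix(0, nrow(w), K, dimnames = list(w$source, NULL))
  for (i in seq_len(nrow(w))) {
    s <- w$source[i]
    if (s %in% series$genes) X[i, ] <- series$values[s, ]
    else if (s %in% net$signals) {
      if (!is.null(schedule))
        X[i, ] <- signal_level(schedule, s, series$times)
    } else stop("MissingRegulator: '", s, "' absent from series and signals")
  }
  X
}

# pairs (t_k, t_{k+1}) whose endpoints avoid the masked timepoints
.kept_pairs <- function(K, mask_idx) {
  keep <- rep(TRUE, K - 1L)
  if (length(mask_idx)) {
    for (k in seq_len(K - 1L))
      if ((k %in% mask_idx) || ((k + 1L) %in% mask_idx)) keep[k] <- FALSE
  }
  which(keep)
}

# one-step-ahead predictions for a single regulated gene: start from the
# training value at each timepoint and integrate the gene's own ODE to the
# next timepoint, with the regulator sum A interpolated linearly between
# its knot values.  All timepoint pairs are integrated at once on a
# rescaled unit interval.
.one_step_gene <- function(kin, q, X, obs, times, pairs = NULL,
                           rtol = 1e-8, atol = 1e-10) {
  K <- length(times)
  dt <- diff(times)
  A <- if (nrow(X)) drop(q %*% X) else numeric(K)
  a0 <- A[seq_len(K - 1L)]
  b <- A[2:K] - a0
  y0 <- obs[seq_len(K - 1L)]
  if (!is.null(pairs)) {
    dt <- dt[pairs]; a0 <- a0[pairs]; b <- b[pairs]; y0 <- y0[pairs]
  }
  k1 <- kin[["k1"]]; k2 <- kin[["k2"]]; k3 <- kin[["k3"]]; d <- kin[["d"]]
  deriv <- function(s, y, p) {
    a <- a0 + b * s
    u <- exp(-k3 * a)
    Fv <- ifelse(a < 0, k1 * k2 / (u + k2), k1 / (1 + k2 * u))
    list(dt * (Fv - d * y))
  }
  sol <- deSolve::ode(y = y0, times = c(0, 1), func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  as.numeric(sol[2L, -1L])
}

# closed-form one-step prediction for a constitutive gene
.one_step_constitutive <- function(kin, obs, times) {
  dt <- diff(times)
  y0 <- obs[-length(obs)]
  eq <- constitutive_rate(kin) / kin[["d"]]
  eq + (y0 - eq) * exp(-kin[["d"]] * dt)
}

#' Initialize regulatory weights by sign-constrained PLS
#'
#' For every regulated gene, fits a PLS regression of the (mean/sd scaled)
#' regulator levels against the target's observed levels, keeps the
#' log-penalized number of components, recovers the coefficients on the
#' raw scale, enforces the declared regulation signs and normalises each
#' target's weights to unit L1 norm.  Frozen regulations stay at zero.
#'
#' @param series an [expression_series()] covering all regulator genes.
#' @param net a [regulatory_network()].
#' @param config an [ssio_config()].
#' @return a [weight_vector()].
#' @export
initialize_weights <- function(series, net, config = ssio_config()) {
  q <- net$regulations$sign * config$epsilon_sign
  q[net$regulations$frozen] <- 0
  for (g in setdiff(net$genes, constitutive_genes(net))) {
    rows <- which(net$regulations$target == g)
    w <- net$regulations[rows, , drop = FALSE]
    X <- .regulator_knots(series, net, g, config$schedule)
    y <- series$values[g, ]
    mask <- config$masks[[g]]
    keep <- setdiff(seq_along(y), mask)
    beta <- .pls_weights(X[, keep, drop = FALSE], y[keep], w, config)
    s <- sum(abs(beta[!w$frozen]))
    if (s > 0) beta <- beta / s
    q[rows] <- beta
  }
  weight_vector(net, q = q)
}

# shared PLS -> raw-scale, sign-enforced coefficient step
.pls_weights <- function(X, y, w, config) {
  if (nrow(X) == 0L) return(numeric(0))
  nf <- normalize_features(X)
  pls <- fit_pls(nf$values, y)
  m <- if (config$penalty) penalized_component_count(pls, config$lambda)
       else pls$n_components
  beta <- if (m > 0) coef(pls, m) * nf$scale$factor else numeric(nrow(X))
  beta[w$frozen] <- 0
  if (config$sign_constraints) {
    free <- !w$frozen
    beta[free] <- enforce_sign_constraints(beta[free], w$sign[free],
                                           config$epsilon_sign)
  }
  beta
}

#' Fit the sigmoid kinetics of every gene by one-step shooting
#'
#' For each gene, finds (k1, k2, k3, d) minimising the squared deviation
#' between the training value at each timepoint and the one-step-ahead
#' simulation started from the training data at the previous timepoint
#' (regulator levels follow the training data within the step).  The
#' bound-constrained least-squares problems are solved per gene by damped
#' Levenberg-Marquardt (trust-region style); a gene whose optimisation
#' fails keeps its initial kinetics and is reported in the
#' `fit_errors` attribute.
#'
#' @param series an [expression_series()].
#' @param net a [regulatory_network()].
#' @param weights current [weight_vector()].
#' @param kinetics_init starting [gene_kinetics()]; `NULL` uses
#'   [default_kinetics_init()].
#' @param config an [ssio_config()].
#' @return a [gene_kinetics()].
#' @export
fit_kinetics <- function(series, net, weights, kinetics_init = NULL,
                         config = ssio_config()) {
  if (is.null(kinetics_init))
    kinetics_init <- default_kinetics_init(series, net, weights)
  bounds <- config$bounds
  if (is.null(bounds)) bounds <- default_kinetics_bounds(series)
  kin <- kinetics_init
  errors <- character()
  for (g in net$genes) {
    obs <- series$values[g, ]
    cons <- g %in% constitutive_genes(net)
    X <- if (cons) NULL else .regulator_knots(series, net, g, config$schedule)
    q <- if (cons) NULL else weights$q[weights$target == g]
    par0 <- as.numeric(kin[g, c("k1", "k2", "k3", "d")])
    pad <- function(r, n) if (length(r) < n) c(r, numeric(n - length(r))) else r
    if (cons) {
      resid_fn <- function(p)
        pad(.one_step_constitutive(list(k1 = p[1], k2 = p[2], d = p[3]),
                                   obs, series$times) - obs[-1L], 3L)
      lower <- c(bounds$k1[1], bounds$k2[1], bounds$d[1])
      upper <- c(bounds$k1[2], bounds$k2[2], bounds$d[2])
      par <- par0[c(1, 2, 4)]
    } else {
      resid_fn <- function(p)
        pad(.one_step_gene(list(k1 = p[1], k2 = p[2], k3 = p[3], d = p[4]),
                           q, X, obs, series$times) - obs[-1L], 4L)
      lower <- c(bounds$k1[1], bounds$k2[1], bounds$k3[1], bounds$d[1])
      upper <- c(bounds$k1[2], bounds$k2[2], bounds$k3[2], bounds$d[2])
      par <- par0
    }
    fit <- try(suppressWarnings(minpack.lm::nls.lm(
      par = par, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 60))), silent = TRUE)
    if (inherits(fit, "try-error")) {
      errors <- c(errors, sprintf("FitError(%s): %s", g,
                                  attr(fit, "condition")$message))
      next
    }
    p <- fit$par
    if (cons) kin[g, c("k1", "k2", "d")] <- p
    else kin[g, c("k1", "k2", "k3", "d")] <- p
  }
  out <- gene_kinetics(rownames(kin), kin$k1, kin$k2, kin$k3, kin$d)
  attr(out, "fit_errors") <- errors
  out
}

#' Default kinetics initialisation
#'
#' k1 starts at the target's largest observed level, k2 at 1, k3 at
#' 1/sd(A) with A the weighted regulator sum over the training samples
#' (1 if degenerate), and d at ln(2)/2 per day (a two-day mRNA half-life).
#'
#' @param series an [expression_series()].
#' @param net a [regulatory_network()].
#' @param weights a [weight_vector()].
#' @param schedule optional [signal_schedule()].
#' @return a [gene_kinetics()].
#' @export
default_kinetics_init <- function(series, net, weights, schedule = NULL) {
  genes <- net$genes
  k1 <- apply(series$values[genes, , drop = FALSE], 1L, max)
  k3 <- rep(1, length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    if (g %in% constitutive_genes(net)) next
    X <- .regulator_knots(series, net, g, schedule)
    A <- drop(weights$q[weights$target == g] %*% X)
    sa <- stats::sd(A)
    if (is.finite(sa) && sa > 0) k3[i] <- 1 / sa
  }
  gene_kinetics(genes, k1 = k1, k2 = 1, k3 = pmin(k3, 10), d = log(2) / 2)
}

# full-system one-step residual: initialise the whole system with the
# training data at each timepoint, integrate one step, and compare with
# the training data at the next timepoint.  All pairs are stacked into one
# integration on a rescaled unit interval.
.one_step_full <- function(series, model, rtol = 1e-8, atol = 1e-10) {
  cm <- .compile_model(model)
  genes <- cm$genes
  V <- series$values[genes, , drop = FALSE]
  times <- series$times
  K <- length(times)
  np <- K - 1L
  dt <- diff(times)
  n <- length(genes)
  k1 <- cm$kin[, "k1"]; k2 <- cm$kin[, "k2"]
  k3 <- cm$kin[, "k3"]; d <- cm$kin[, "d"]
  dtb <- rep(dt, each = n)
  deriv <- function(s, y, p) {
    Y <- matrix(y, nrow = n)
    tvec <- times[seq_len(np)] + s * dt
    Fv <- matrix(0, n, np)
    for (i in seq_len(n)) {
      pg <- cm$per_gene[[i]]
      if (pg$constitutive) { Fv[i, ] <- k1[i] / (1 + k2[i]); next }
      a <- if (length(pg$gene_idx))
        colSums(Y[pg$gene_idx, , drop = FALSE] * pg$q_gene)
      else numeric(np)
      if (length(pg$sig_ids) && !is.null(cm$schedule))
        for (j in seq_along(pg$sig_ids))
          a <- a + pg$q_sig[j] *
            signal_level(cm$schedule, pg$sig_ids[j], tvec)
      u <- exp(-k3[i] * a)
      Fv[i, ] <- ifelse(a < 0, k1[i] * k2[i] / (u + k2[i]),
                        k1[i] / (1 + k2[i] * u))
    }
    list(as.numeric(Fv - d * matrix(y, nrow = n)) * dtb)
  }
  sol <- deSolve::ode(y = as.numeric(V[, seq_len(np), drop = FALSE]),
                      times = c(0, 1), func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  pred <- matrix(sol[2L, -1L], nrow = n, dimnames = list(genes, NULL))
  list(pred = pred, obs = V[, 2:K, drop = FALSE])
}

#' One-step-ahead residual of a fitted model
#'
#' The model-evaluation residual: the ODE system is initialised with the
#' training data at every timepoint, simulated one step, and the squared
#' deviations from the training data at the next timepoint are summed over
#' genes and steps.
#'
#' @param series an [expression_series()].
#' @param model a [grn_model()].
#' @param exclude_times optional timepoint indices (e.g. interpolated
#'   points) whose pairs are excluded.
#' @return list with `residual_sq` (scalar), `per_gene` (named vector),
#'   `n_obs` (number of contributing observations).
#' @export
one_step_residual <- function(series, model, exclude_times = NULL) {
  os <- .one_step_full(series, model)
  res <- os$pred - os$obs
  if (!is.null(exclude_times)) {
    K <- length(series$times)
    drop_pairs <- setdiff(seq_len(K - 1L),
                          .kept_pairs(K, exclude_times))
    if (length(drop_pairs)) res[, drop_pairs] <- 0
    n_obs <- nrow(res) * (K - 1L - length(drop_pairs))
  } else n_obs <- length(res)
  list(residual_sq = sum(res^2), per_gene = rowSums(res^2), n_obs = n_obs)
}

#' Update the regulatory weights along a PLS direction
#'
#' Implements one weight-refinement pass: (i) simulate the full system from
#' the first timepoint; (ii) per regulated gene, run PLS with the
#' *simulated* regulator trajectories as input and the observed target as
#' output; (iii) move the target's weights along the unit-normalised
#' recovered coefficient vector by a scalar chosen to minimise the
#' one-step-ahead squared deviation (1-D bounded search), then re-enforce
#' the sign constraints.  Masked timepoints contribute neither to the PLS
#' nor to the scalar objective.
#'
#' @param series an [expression_series()].
#' @param net a [regulatory_network()].
#' @param weights previous [weight_vector()].
#' @param kinetics current [gene_kinetics()].
#' @param config an [ssio_config()].
#' @return updated [weight_vector()].
#' @export
update_weights <- function(series, net, weights, kinetics,
                           config = ssio_config()) {
  model <- grn_model(net, kinetics, weights, schedule = config$schedule)
  sim <- simulate_grn(model,
                      init = stats::setNames(series$values[, 1L],
                                             series$genes),
                      times = series$times)
  simT <- t(sim)  # genes x timepoints
  qout <- weights$q
  K <- length(series$times)
  for (g in setdiff(net$genes, constitutive_genes(net))) {
    rows <- which(weights$target == g)
    w <- weights[rows, , drop = FALSE]
    if (all(w$frozen)) next
    # PLS input: simulated gene trajectories, schedule levels for signals
    Xs <- matrix(0, nrow(w), K, dimnames = list(w$source, NULL))
    for (i in seq_len(nrow(w))) {
      s <- w$source[i]
      if (s %in% net$genes) Xs[i, ] <- simT[s, ]
      else if (!is.null(config$schedule))
        Xs[i, ] <- signal_level(config$schedule, s, series$times)
    }
    y <- series$values[g, ]
    mask <- config$masks[[g]]
    keep_s <- setdiff(seq_len(K), mask)
    beta <- .pls_weights(Xs[, keep_s, drop = FALSE], y[keep_s], w, config)
    nrm <- sqrt(sum(beta^2))
    if (!is.finite(nrm) || nrm == 0) next
    u <- beta / nrm
    u[w$frozen] <- 0
    # 1-D scalar search on the one-step objective
    Xd <- .regulator_knots(series, net, g, config$schedule)
    kin_g <- as.list(kinetics[g, c("k1", "k2", "k3", "d")])
    keep_p <- .kept_pairs(K, mask)
    q_prev <- w$q
    obj <- function(cc) {
      qc <- q_prev + cc * u
      qc[w$frozen] <- 0
      if (config$sign_constraints)
        qc[!w$frozen] <- enforce_sign_constraints(qc[!w$frozen],
                                                  w$sign[!w$frozen],
                                                  config$epsilon_sign)
      pred <- .one_step_gene(kin_g, qc, Xd, y, series$times,
                             pairs = keep_p)
      sum((pred - y[-1L][keep_p])^2)
    }
    opt <- stats::optimize(obj, interval = c(-config$c_max, config$c_max),
                           tol = 1e-7)
    cc <- if (opt$objective <= obj(0)) opt$minimum else 0
    qn <- q_prev + cc * u
    qn[w$frozen] <- 0
    if (config$sign_constraints)
      qn[!w$frozen] <- enforce_sign_constraints(qn[!w$frozen],
                                                w$sign[!w$frozen],
                                                config$epsilon_sign)
    qout[rows] <- qn
  }
  weight_vector(net, q = qout)
}

#' Effective number of parameters of one SSIO iteration
#'
#' P = [sum over weights of |atan(q_t) - atan(q_{t-1})|] * ln(iteration):
#' the summed absolute arctangent change of the weight vector between
#' consecutive iterations, scaled by the log of the iteration index.  At
#' iteration 1 the log factor is 0, so P = 0.
#'
#' @param weights_t current [weight_vector()].
#' @param weights_prev previous [weight_vector()].
#' @param iteration iteration index (>= 1).
#' @return scalar P >= 0.
#' @export
effective_parameters <- function(weights_t, weights_prev, iteration) {
  if (iteration < 1) stop("iteration must be >= 1")
  ka <- paste(weights_t$target, weights_t$source)
  kb <- paste(weights_prev$target, weights_prev$source)
  if (length(ka) != length(kb) || any(ka != kb))
    stop("KeyMismatch: weight vectors disagree on their keys")
  sum(abs(atan(weights_t$q) - atan(weights_prev$q))) * log(iteration)
}

#' Bayesian information criterion with a bespoke parameter count
#'
#' BIC = N ln(err^2 / N) + P ln(N), the Gaussian-regression Schwarz
#' criterion with the effective parameter count P of
#' [effective_parameters()].  err^2 is floored at machine epsilon.
#'
#' @param residual_sq summed squared one-step residual.
#' @param P effective number of parameters.
#' @param N number of training observations.
#' @return scalar BIC.
#' @export
bic_score <- function(residual_sq, P, N) {
  if (N < 1) stop("N must be >= 1")
  residual_sq <- max(residual_sq, .Machine$double.eps)
  N * log(residual_sq / N) + P * log(N)
}

#' Run the small-sample iterative optimization loop
#'
#' Alternates trust-region kinetics fitting with PLS-directed weight
#' updates: weights are initialised by sign-constrained PLS, then each
#' iteration (i) refits every gene's (k1, k2, k3, d) on the one-step
#' objective, (ii) refines the weights along the normalised PLS direction
#' computed from re-simulated trajectories, (iii) records the full
#' one-step residual, the effective parameter count and the BIC.  The loop
#' stops when the relative L1 change of the weight vector falls below
#' `config$tol` or `config$max_iterations` is reached; the iterate with
#' the minimum BIC is returned as the fit.
#'
#' @param series an [expression_series()] covering every network gene.
#' @param net a [regulatory_network()].
#' @param config an [ssio_config()].
#' @return object of class `ssio_fit`: list with `best` (the minimum-BIC
#'   iteration), `history` (all iterations), `converged`, `stop_reason`
#'   (`"weight_convergence"` or `"max_iterations"`), `N` and
#'   `total_ss` (total sum of squares of the predicted observations).
#' @export
run_ssio <- function(series, net, config = ssio_config()) {
  v <- validate_network(net)
  if (length(v))
    stop("invalid network: ", paste(v, collapse = "; "))
  miss <- setdiff(net$genes, series$genes)
  if (length(miss))
    stop("series missing gene(s): ", paste(miss, collapse = ", "))
  w <- initialize_weights(series, net, config)
  kin <- config$kinetics_init
  if (is.null(kin))
    kin <- default_kinetics_init(series, net, w, config$schedule)
  history <- list()
  converged <- FALSE
  stop_reason <- "max_iterations"
  N <- NULL
  for (iter in seq_len(config$max_iterations)) {
    kin <- fit_kinetics(series, net, w, kinetics_init = kin,
                        config = config)
    w_new <- update_weights(series, net, w, kin, config = config)
    model <- grn_model(net, kin, w_new, schedule = config$schedule)
    res <- one_step_residual(series, model,
                             exclude_times = config$exclude_times)
    N <- res$n_obs
    P <- effective_parameters(w_new, w, iter)
    bic <- bic_score(res$residual_sq, P, N)
    rel <- sum(abs(w_new$q - w$q)) / max(sum(abs(w$q)), 1e-12)
    history[[iter]] <- structure(
      list(index = iter, kinetics = kin, weights = w_new,
           residual_sq = res$residual_sq, per_gene = res$per_gene,
           effective_params = P, bic = bic, rel_change = rel),
      class = "ssio_iteration")
    w <- w_new
    if (rel < config$tol) {
      converged <- TRUE
      stop_reason <- "weight_convergence"
      break
    }
  }
  if (!length(history)) stop("FitError: no iteration completed")
  bics <- vapply(history, `[[`, 0, "bic")
  best <- history[[which.min(bics)]]
  obs <- series$values[net$genes, -1L, drop = FALSE]
  total_ss <- sum((obs - rowMeans(series$values[net$genes, , drop = FALSE]))^2)
  structure(list(best = best, history = history, converged = converged,
                 stop_reason = stop_reason, N = N, total_ss = total_ss,
                 config = config, net = net),
            class = "ssio_fit")
}

#' @export
print.ssio_fit <- function(x, ...) {
  cat(sprintf(
    "ssio_fit: %d iteration(s), %s; best iteration %d (BIC %.4g, err^2 %.4g)\n",
    length(x$history), x$stop_reason, x$best$index, x$best$bic,
    x$best$residual_sq))
  invisible(x)
}

#' Check the response of marker genes to the external stimuli
#'
#' Simulates the fitted model over the training window with the stimulus
#' schedule present and absent.  The fit is behavioural if every marker
#' ends above the midpoint of its observed pre/post levels with stimuli,
#' and below it without (a marker exactly at the midpoint fails).
#'
#' @param model a [grn_model()] (its schedule is the "stimuli on" case).
#' @param series the training [expression_series()].
#' @param markers character vector of marker gene ids (default the three
#'   key adipogenic markers present in the network).
#' @return list with `ok` (logical) and `detail` (per-marker data frame).
#' @export
check_signal_response <- function(model, series,
                                  markers = intersect(
                                    c("CEBPB", "CEBPA", "PPARG"),
                                    model$net$genes)) {
  if (!length(markers)) markers <- model$net$genes
  times <- series$times
  init <- stats::setNames(series$values[, 1L], series$genes)
  on <- simulate_grn(model, init, times)
  model_off <- model; model_off$schedule <- NULL
  off <- simulate_grn(model_off, init, times)
  pre <- series$values[markers, 1L]
  post <- series$values[markers, length(times)]
  thr <- (pre + post) / 2
  lev_on <- on[nrow(on), markers]
  lev_off <- off[nrow(off), markers]
  detail <- data.frame(marker = markers, threshold = thr,
                       with_signals = lev_on, without_signals = lev_off,
                       pass = lev_on > thr & lev_off < thr,
                       row.names = NULL)
  list(ok = all(detail$pass), detail = detail)
}

#' Write a fit result to disk
#'
#' Emits `kinetics.tsv` (gene, k1, k2, k3, d), `weights.tsv` (target,
#' regulator, q) and `fit.json` (history summary) under `dir`.
#'
#' @param fit an `ssio_fit`.
#' @param dir output directory (created if absent).
#' @return invisibly, the directory.
#' @export
write_fit_result <- function(fit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  kin <- data.frame(gene = rownames(fit$best$kinetics),
                    fit$best$kinetics, row.names = NULL)
  utils::write.table(kin, file.path(dir, "kinetics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  w <- fit$best$weights
  utils::write.table(
    data.frame(target = w$target, regulator = w$source, q = w$q),
    file.path(dir, "weights.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  hist <- data.frame(
    iteration = vapply(fit$history, `[[`, 0, "index"),
    residual_sq = vapply(fit$history, `[[`, 0, "residual_sq"),
    effective_params = vapply(fit$history, `[[`, 0, "effective_params"),
    bic = vapply(fit$history, `[[`, 0, "bic"),
    rel_change = vapply(fit$history, `[[`, 0, "rel_change"))
  jsonlite::write_json(
    list(best_iteration = fit$best$index, converged = fit$converged,
         stop_reason = fit$stop_reason, N = fit$N, history = hist),
    file.path(dir, "fit.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
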