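#' Uniform prior ranges for regional sensitivity analysis
#'
#' Builds the per-parameter uniform sampling ranges: degradation constants
#' vary within +/-0.1 of their fitted value (floored just above zero,
#' since too-small degradation lets levels grow unboundedly); TF
#' regulatory weights are sampled on [0, 1]; every other parameter is
#' sampled on [0, 2v] when its value v exceeds 0.25 and on [0, 0.5]
#' otherwise.
#'
#' @param theta named numeric vector of fitted parameter values.
#' @param roles named character vector (same names), each one of
#'   `"degradation"`, `"weight"`, `"other"`.
#' @return data frame of class `prior_spec` with columns parameter, lo, hi.
#' @export
build_prior <- function(theta, roles) {
  if (is.null(names(theta)) || !all(names(theta) %in% names(roles)))
    stop("theta and roles must share names")
  roles <- roles[names(theta)]
  bad <- setdiff(unique(roles), c("degradation", "weight", "other"))
  if (length(bad)) stop("ConfigError: unknown role(s): ",
                        paste(bad, collapse = ", "))
  if (any(!is.finite(theta))) stop("non-finite parameter value")
  lo <- numeric(length(theta)); hi <- numeric(length(theta))
  for (i in seq_along(theta)) {
    v <- theta[i]
    if (roles[i] == "degradation") {
      lo[i] <- max(v - 0.1, 1e-6); hi[i] <- v + 0.1
    } else if (roles[i] == "weight") {
      lo[i] <- 0; hi[i] <- 1
    } else {
      if (v > 0.25) { lo[i] <- 0; hi[i] <- 2 * v }
      else { lo[i] <- 0; hi[i] <- 0.5 }
    }
  }
  structure(data.frame(parameter = names(theta), lo = lo, hi = hi,
                       role = unname(roles), stringsAsFactors = FALSE),
            class = c("prior_spec", "data.frame"))
}

#' Draw one parameter vector from a uniform prior
#' @param prior a [build_prior()] spec.
#' @return named numeric vector.
#' @export
sample_prior <- function(prior) {
  stats::setNames(stats::runif(nrow(prior), prior$lo, prior$hi),
                  prior$parameter)
}

#' One Metropolis-Hastings step with an independence proposal
#'
#' Proposes a fresh draw from the uniform prior (so the transition
#' probabilities cancel), treats the residual error as reciprocal to the
#' posterior probability, and accepts with probability
#' alpha = min(1, (err_n / err*)^exponent).
#'
#' @param theta_n current parameter vector.
#' @param err_n current residual error (> 0).
#' @param prior a [build_prior()] spec.
#' @param err_fn function(theta) -> scalar residual error.
#' @param exponent power applied to the error ratio (default 1).
#' @return list with `theta`, `err`, `accepted`, `proposal`,
#'   `err_proposal`, `alpha`.
#' @export
metropolis_step <- function(theta_n, err_n, prior, err_fn, exponent = 1) {
  if (!is.finite(err_n) || err_n <= 0) stop("err_n must be positive")
  proposal <- sample_prior(prior)
  err_star <- tryCatch(err_fn(proposal), error = function(e) NA_real_)
  if (!is.finite(err_star) || err_star <= 0) {
    return(list(theta = theta_n, err = err_n, accepted = FALSE,
                proposal = proposal, err_proposal = err_star, alpha = 0))
  }
  alpha <- min(1, (err_n / err_star)^exponent)
  accepted <- stats::runif(1) < alpha
  list(theta = if (accepted) proposal else theta_n,
       err = if (accepted) err_star else err_n,
       accepted = accepted, proposal = proposal,
       err_proposal = err_star, alpha = alpha)
}

#' Run a Metropolis chain for regional sensitivity analysis
#'
#' Samples parameter vectors from the uniform prior by
#' [metropolis_step()], classifying every visited state as behavioural or
#' not.  The trace records the chain state at every step (repeats on
#' rejection), so the empirical distributions downstream are those of the
#' chain.
#'
#' @param err_fn function(theta) -> residual error.
#' @param prior a [build_prior()] spec.
#' @param n_samples number of Metropolis steps.
#' @param behavioral_fn optional function(theta) -> logical.
#' @param theta0 starting vector; default the prior midpoint.
#' @param burn_in samples discarded by downstream statistics
#'   (default 10000).
#' @param seed integer seed; the chain is reproducible bit for bit.
#' @param exponent error-ratio exponent of [metropolis_step()].
#' @return object of class `mcmc_trace`: list with `samples` (matrix
#'   n_samples x parameters), `err`, `accepted`, `behavioral`, `burn_in`,
#'   `prior`, `seed`.
#' @export
run_mcmc <- function(err_fn, prior, n_samples, behavioral_fn = NULL,
                     theta0 = NULL, burn_in = 10000, seed = 1,
                     exponent = 1) {
  set.seed(seed)
  p <- nrow(prior)
  if (n_samples < 1) {
    warning("n_samples < 1: returning an empty trace")
    return(structure(list(samples = matrix(numeric(), 0, p,
                                           dimnames = list(NULL, prior$parameter)),
                          err = numeric(), accepted = logical(),
                          behavioral = logical(), burn_in = burn_in,
                          prior = prior, seed = seed),
                     class = "mcmc_trace"))
  }
  if (is.null(theta0))
    theta0 <- stats::setNames((prior$lo + prior$hi) / 2, prior$parameter)
  err0 <- err_fn(theta0)
  if (!is.finite(err0) || err0 <= 0)
    stop("err_fn must be positive and finite at theta0")
  beh0 <- if (is.null(behavioral_fn)) NA else behavioral_fn(theta0)
  samples <- matrix(NA_real_, n_samples, p,
                    dimnames = list(NULL, prior$parameter))
  err <- numeric(n_samples)
  accepted <- logical(n_samples)
  behavioral <- rep(NA, n_samples)
  cur <- theta0; cur_err <- err0; cur_beh <- beh0
  for (i in seq_len(n_samples)) {
    st <- metropolis_step(cur, cur_err, prior, err_fn, exponent)
    if (st$accepted) {
      cur <- st$theta; cur_err <- st$err
      cur_beh <- if (is.null(behavioral_fn)) NA else behavioral_fn(cur)
    }
    samples[i, ] <- cur
    err[i] <- cur_err
    accepted[i] <- st$accepted
    behavioral[i] <- cur_beh
  }
  structure(list(samples = samples, err = err, accepted = accepted,
                 behavioral = as.logical(behavioral), burn_in = burn_in,
                 prior = prior, seed = seed),
            class = "mcmc_trace")
}

#' @export
print.mcmc_trace <- function(x, ...) {
  n <- length(x$err)
  cat(sprintf("mcmc_trace: %d samples, %.1f%% accepted, burn-in %d\n",
              n, if (n) 100 * mean(x$accepted) else 0, x$burn_in))
  invisible(x)
}

#' Binned Kolmogorov-Smirnov regional sensitivity statistics
#'
#' For every parameter, compares the empirical cumulative distributions of
#' the behavioural and non-behavioural chain samples (after burn-in
#' removal) on a fixed grid of `bins` intervals spanning the prior range;
#' the sensitivity is the maximum absolute CDF difference.  If either
#' class is empty the statistics are reported as `NA` (undefined), not
#' raised.
#'
#' @param trace an [run_mcmc()] trace with behavioural flags.
#' @param bins number of intervals of the CDF grid (default 10).
#' @return data frame of class `sensitivity_table` with columns parameter,
#'   statistic, n_behavioral, n_nonbehavioral.
#' @export
ks_sensitivity <- function(trace, bins = 10) {
  keep <- seq_along(trace$err) > trace$burn_in
  S <- trace$samples[keep, , drop = FALSE]
  beh <- trace$behavioral[keep]
  nb <- sum(beh, na.rm = TRUE)
  nn <- sum(!beh, na.rm = TRUE)
  stat <- rep(NA_real_, nrow(trace$prior))
  if (nb > 0 && nn > 0) {
    for (j in seq_len(nrow(trace$prior))) {
      edges <- seq(trace$prior$lo[j], trace$prior$hi[j],
                   length.out = bins + 1L)
      cb <- cumsum(tabulate(findInterval(S[beh %in% TRUE, j], edges,
                                         rightmost.closed = TRUE,
                                         all.inside = TRUE),
                            nbins = bins)) / nb
      cn <- cumsum(tabulate(findInterval(S[beh %in% FALSE, j], edges,
                                         rightmost.closed = TRUE,
                                         all.inside = TRUE),
                            nbins = bins)) / nn
      stat[j] <- max(abs(cb - cn))
    }
  }
  structure(data.frame(parameter = trace$prior$parameter,
                       statistic = stat, n_behavioral = nb,
                       n_nonbehavioral = nn, stringsAsFactors = FALSE),
            class = c("sensitivity_table", "data.frame"))
}

#' Flatten a model's free parameters into a named vector with roles
#'
#' Non-frozen regulatory weights get role `"weight"`, degradation
#' constants `"degradation"`, and k1/k2/k3 `"other"` — the roles used by
#' [build_prior()].
#'
#' @param model a [grn_model()].
#' @param which `"all"` or `"weights"` (TF coefficients only).
#' @return list with `theta` (named vector) and `roles`.
#' @export
flatten_parameters <- function(model, which = c("all", "weights")) {
  which <- match.arg(which)
  w <- model$weights
  free <- !w$frozen
  theta <- stats::setNames(w$q[free],
                           paste0("q.", w$target[free], ".", w$source[free]))
  roles <- stats::setNames(rep("weight", sum(free)), names(theta))
  if (which == "all") {
    kin <- model$kinetics
    for (p in c("k1", "k2", "k3")) {
      v <- stats::setNames(kin[[p]], paste0(p, ".", rownames(kin)))
      theta <- c(theta, v)
      roles <- c(roles, stats::setNames(rep("other", length(v)), names(v)))
    }
    dv <- stats::setNames(kin$d, paste0("d.", rownames(kin)))
    theta <- c(theta, dv)
    roles <- c(roles, stats::setNames(rep("degradation", length(dv)),
                                      names(dv)))
  }
  list(theta = theta, roles = roles)
}

#' Rebuild a model with parameter values from a flat vector
#'
#' Inverse of [flatten_parameters()]: entries named `q.target.source`,
#' `k1.gene`, ..., `d.gene` replace the corresponding model values.
#' Weight magnitudes are applied with the declared regulation sign.
#'
#' @param model a [grn_model()].
#' @param theta named numeric vector.
#' @return a [grn_model()] with the substituted parameters.
#' @export
patch_parameters <- function(model, theta) {
  w <- model$weights
  kin <- model$kinetics
  for (nm in names(theta)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    kind <- parts[1L]
    if (kind == "q") {
      i <- which(w$target == parts[2L] & w$source == parts[3L])
      if (!length(i)) stop("KeyMismatch: no regulation ", nm)
      w$q[i] <- w$sign[i] * abs(theta[[nm]])
    } else if (kind %in% c("k1", "k2", "k3", "d")) {
      if (!parts[2L] %in% rownames(kin))
        stop("KeyMismatch: no gene ", parts[2L])
      kin[parts[2L], kind] <- max(theta[[nm]], 1e-9)
    } else stop("KeyMismatch: unparsable parameter name ", nm)
  }
  w$q[w$frozen] <- 0
  grn_model(model$net, gene_kinetics(rownames(kin), kin$k1, kin$k2,
                                     kin$k3, kin$d),
            w, schedule = model$schedule)
}

#' Behavioural classification of a parameter vector
#'
#' A sample is behavioural when the simulated marker genes respond to the
#' external stimuli properly: high (above the midpoint of their observed
#' pre/post levels) at the end of the training window with stimuli on,
#' and low without.  Integration failures count as non-behavioural.
#'
#' @param theta named parameter vector (see [patch_parameters()]).
#' @param model reference [grn_model()] (must carry a schedule).
#' @param series training [expression_series()].
#' @param markers marker gene ids; defaults to the key adipogenic markers
#'   present in the network, or all genes when none of them is.
#' @return logical flag, with a `diagnostic` attribute on failure.
#' @export
classify_behavioral <- function(theta, model, series,
                                markers = intersect(
                                  c("CEBPB", "CEBPA", "PPARG"),
                                  model$net$genes)) {
  m <- try(patch_parameters(model, theta), silent = TRUE)
  if (inherits(m, "try-error"))
    return(structure(FALSE, diagnostic = attr(m, "condition")$message))
  out <- try(check_signal_response(m, series, markers), silent = TRUE)
  if (inherits(out, "try-error"))
    return(structure(FALSE, diagnostic = attr(out, "condition")$message))
  out$ok
}

#' Scan a transcription-rate parameter for bistability
#'
#' For each value of the control parameter (a gene's k1 by default), the
#' equilibrium is computed from a low and a high initial state with the
#' external signals absent.  Where the system is bistable the two branches
#' separate; the trigger level is the smallest control value at which the
#' previously separated low branch jumps up to rejoin the high branch.
#'
#' @param model a [grn_model()] (its schedule is ignored: signals are off).
#' @param control list with `gene` and `param` (one of k1, k2, k3, d).
#' @param grid increasing vector of control values.
#' @param init_low,init_high named initial state vectors.
#' @param track gene ids whose equilibrium levels decide branch
#'   separation (default all genes).
#' @param separation branch gap (a.u.) above which the system counts as
#'   bistable (default 1).
#' @param horizon passed to [find_equilibrium()].
#' @return object of class `scan_result`: list with `control`, `grid`,
#'   `low`, `high` (grid x gene matrices), `bistable` (logical per grid
#'   point) and `trigger_level` (or NA).
#' @export
bistability_scan <- function(model, control, grid, init_low, init_high,
                             track = NULL, separation = 1,
                             horizon = 100) {
  if (any(diff(grid) <= 0)) stop("grid must be increasing")
  if (!control$param %in% c("k1", "k2", "k3", "d"))
    stop("ConfigError: control parameter must be one of k1, k2, k3, d")
  model$schedule <- NULL
  genes <- model$net$genes
  if (is.null(track)) track <- genes
  low <- matrix(NA_real_, length(grid), length(genes),
                dimnames = list(NULL, genes))
  high <- low
  for (i in seq_along(grid)) {
    kin <- model$kinetics
    kin[control$gene, control$param] <- grid[i]
    m <- grn_model(model$net,
                   gene_kinetics(rownames(kin), kin$k1, kin$k2, kin$k3,
                                 kin$d),
                   model$weights, schedule = NULL)
    lo <- try(find_equilibrium(m, init_low, horizon = horizon),
              silent = TRUE)
    hi <- try(find_equilibrium(m, init_high, horizon = horizon),
              silent = TRUE)
    if (!inherits(lo, "try-error")) low[i, ] <- lo
    if (!inherits(hi, "try-error")) high[i, ] <- hi
  }
  gap <- abs(high[, track, drop = FALSE] - low[, track, drop = FALSE])
  bistable <- apply(gap, 1L, function(g) any(is.finite(g) & g > separation))
  trigger <- NA_real_
  for (i in seq_along(grid)[-1L]) {
    if (isTRUE(bistable[i - 1L]) && isFALSE(bistable[i])) {
      jump <- low[i, track] - low[i - 1L, track]
      if (any(is.finite(jump) & jump > separation)) {
        trigger <- grid[i]
        break
      }
    }
  }
  structure(list(control = control, grid = grid, low = low, high = high,
                 bistable = bistable, trigger_level = trigger,
                 separation = separation),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("scan_result: %s %s over [%g, %g], %d/%d bistable, trigger %s\n",
              x$control$gene, x$control$param, min(x$grid), max(x$grid),
              sum(x$bistable), length(x$grid),
              if (is.na(x$trigger_level)) "none" else
                format(x$trigger_level)))
  invisible(x)
}

#' Local sensitivity of the bistable switch to one parameter
#'
#' Re-runs [bistability_scan()] with one parameter perturbed by each
#' multiplicative delta and reports whether bistability persists and how
#' the trigger level shifts.
#'
#' @param model a [grn_model()].
#' @param control,grid,init_low,init_high,track,separation,horizon passed
#'   to [bistability_scan()].
#' @param param list with either `gene` + `name` (a kinetics entry) or
#'   `target` + `source` (a weight).
#' @param deltas numeric vector of relative perturbations (0 = reference).
#' @return data frame with delta, value, bistable, trigger_level,
#'   trigger_shift.
#' @export
local_sensitivity <- function(model, control, grid, init_low, init_high,
                              param, deltas, track = NULL,
                              separation = 1, horizon = 100) {
  ref <- bistability_scan(model, control, grid, init_low, init_high,
                          track = track, separation = separation,
                          horizon = horizon)
  out <- data.frame(delta = deltas, value = NA_real_, bistable = NA,
                    trigger_level = NA_real_, trigger_shift = NA_real_)
  for (i in seq_along(deltas)) {
    m <- model
    if (!is.null(param$name)) {
      v0 <- m$kinetics[param$gene, param$name]
      v <- v0 * (1 + deltas[i])
      m$kinetics[param$gene, param$name] <- max(v, 1e-9)
      out$value[i] <- v
    } else {
      j <- which(m$weights$target == param$target &
                   m$weights$source == param$source)
      if (!length(j)) stop("KeyMismatch: no such regulation")
      v <- m$weights$q[j] * (1 + deltas[i])
      m$weights$q[j] <- v
      out$value[i] <- v
    }
    sc <- if (deltas[i] == 0) ref else
      bistability_scan(m, control, grid, init_low, init_high,
                       track = track, separation = separation,
                       horizon = horizon)
    out$bistable[i] <- any(sc$bistable)
    out$trigger_level[i] <- sc$trigger_level
    out$trigger_shift[i] <- sc$trigger_level - ref$trigger_level
  }
  attr(out, "reference") <- ref
  out
}

#' Jacobian-based regulator importance ranking
#'
#' The importance of regulator i for target j at a given cellular stage is
#' |d(dY_j/dt)/dX_i| * X_i evaluated at that stage's state: the analytic
#' Jacobian entry of the regulation term, F'(A_j) q_ij, scaled by the
#' regulator's expression level.  Regulators are ranked per target per
#' stage in decreasing importance (zero-weight regulators rank last).
#'
#' @param model a [grn_model()].
#' @param stage_states named list: stage -> named vector of gene levels.
#' @param stage_times optional named vector of days per stage, used to
#'   evaluate signal regulators; signals score 0 without it.
#' @return data frame with stage, target, regulator, importance, rank.
#' @export
importance_rank <- function(model, stage_states, stage_times = NULL) {
  w <- model$weights
  out <- list()
  for (stage in names(stage_states)) {
    lv <- stage_states[[stage]]
    for (g in unique(w$target)) {
      wr <- w[w$target == g, , drop = FALSE]
      A <- 0
      xs <- numeric(nrow(wr))
      for (i in seq_len(nrow(wr))) {
        s <- wr$source[i]
        xs[i] <- if (s %in% names(lv)) lv[[s]]
        else if (!is.null(model$schedule) && s %in% model$net$signals &&
                 !is.null(stage_times))
          signal_level(model$schedule, s, stage_times[[stage]])
        else 0
      }
      A <- sum(wr$q * xs)
      dF <- transcription_rate_deriv(as.list(model$kinetics[g, ]), A)
      imp <- abs(dF * wr$q) * xs
      imp[!is.finite(imp)] <- 0
      ord <- order(-imp)
      out[[length(out) + 1L]] <- data.frame(
        stage = stage, target = g, regulator = wr$source[ord],
        importance = imp[ord], rank = seq_along(ord),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Cross-species comparison of weighted regulator expression
#'
#' Computes the weighted-expression levels q_i * X_i of a target's
#' regulators at the four differentiation stages in each species, takes
#' the per-regulator changes across the three stage transitions
#' (proliferating -> pre, pre -> immature, immature -> mature), z-score
#' normalises each species' changes, and applies the two-sample
#' Kolmogorov-Smirnov test per transition.
#'
#' @param weights_a,weights_b [weight_vector()]s of the two species.
#' @param series_a,series_b matching [expression_series()]s.
#' @param target gene id present in both networks.
#' @param stages_a,stages_b named numeric vectors mapping the four stage
#'   names to days of the respective series (interpolated if needed).
#' @param exact logical; small-sample exact p-values instead of the
#'   asymptotic two-sample distribution (default asymptotic).
#' @return data frame with transition, D, p_value; `NA` (undefined) when
#'   either species has fewer than two gene regulators.
#' @export
weighted_expression_compare <- function(weights_a, series_a, weights_b,
                                        series_b, target, stages_a,
                                        stages_b, exact = FALSE) {
  stage_changes <- function(weights, series, stages) {
    w <- weights[weights$target == target & !weights$frozen, , drop = FALSE]
    w <- w[w$source %in% series$genes, , drop = FALSE]
    if (nrow(w) < 2L) return(NULL)
    si <- interpolate_series(series, sort(unique(c(series$times, stages))))
    lev <- vapply(stages, function(d)
      si$values[w$source, which(si$times == d)], numeric(nrow(w)))
    wx <- w$q * lev                       # regulator x stage
    ch <- wx[, -1L, drop = FALSE] - wx[, -ncol(wx), drop = FALSE]
    (ch - mean(ch)) / stats::sd(ch)
  }
  za <- stage_changes(weights_a, series_a, stages_a)
  zb <- stage_changes(weights_b, series_b, stages_b)
  trans <- paste(names(stages_a)[-length(stages_a)], "->",
                 names(stages_a)[-1L])
  if (is.null(za) || is.null(zb))
    return(data.frame(transition = trans, D = NA_real_,
                      p_value = NA_real_))
  D <- p <- numeric(length(trans))
  for (k in seq_along(trans)) {
    kt <- suppressWarnings(stats::ks.test(za[, k], zb[, k],
                                          exact = exact))
    D[k] <- unname(kt$statistic)
    p[k] <- kt$p.value
  }
  data.frame(transition = trans, D = D, p_value = p)
}

#' Write an MCMC trace as TSV with a JSON sidecar
#'
#' One row per sample: the parameter vector, the residual error and the
#' accepted/behavioural flags.  The sidecar records the seed, burn-in and
#' prior so the run can be reproduced.
#'
#' @param trace an [run_mcmc()] trace.
#' @param path output TSV path (`path` + `.json` gets the sidecar).
#' @export
write_trace <- function(trace, path) {
  tab <- data.frame(trace$samples, err = trace$err,
                    accepted = trace$accepted,
                    behavioral = trace$behavioral, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(seed = trace$seed, burn_in = trace$burn_in,
         n_samples = length(trace$err),
         prior = as.data.frame(trace$prior)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
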