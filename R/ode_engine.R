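#' Bundle a network with its parameters into a simulatable model
#'
#' @param net a [regulatory_network()].
#' @param kinetics a [gene_kinetics()] covering every gene of `net`.
#' @param weights a [weight_vector()] matching `net$regulations`.
#' @param schedule optional [signal_schedule()]; `NULL` means all signals
#'   are absent (level 0).
#' @return object of class `grn_model`.
#' @export
grn_model <- function(net, kinetics, weights, schedule = NULL) {
  miss <- setdiff(net$genes, rownames(kinetics))
  if (length(miss))
    stop("kinetics missing for gene(s): ", paste(miss, collapse = ", "))
  if (nrow(weights) != nrow(net$regulations))
    stop("KeyMismatch: weights do not match network regulations")
  structure(list(net = net, kinetics = kinetics, weights = weights,
                 schedule = schedule),
            class = "grn_model")
}

#' @export
print.grn_model <- function(x, ...) {
  cat("grn_model:\n"); print(x$net); invisible(x)
}

# Precompute per-gene regulator indices for fast right-hand-side evaluation.
.compile_model <- function(model) {
  net <- model$net
  genes <- net$genes
  kin <- as.matrix(model$kinetics[genes, c("k1", "k2", "k3", "d")])
  per_gene <- lapply(genes, function(g) {
    w <- model$weights[model$weights$target == g, , drop = FALSE]
    is_sig <- w$source %in% net$signals
    list(gene_idx = match(w$source[!is_sig], genes),
         q_gene = w$q[!is_sig],
         sig_ids = w$source[is_sig],
         q_sig = w$q[is_sig],
         constitutive = nrow(w) == 0L)
  })
  names(per_gene) <- genes
  list(genes = genes, kin = kin, per_gene = per_gene,
       schedule = model$schedule)
}

# weighted regulator sum A for each gene at state y, time t
.combined_inputs <- function(cm, y, t) {
  vapply(cm$per_gene, function(pg) {
    if (pg$constitutive) return(NA_real_)
    a <- if (length(pg$gene_idx)) sum(pg$q_gene * y[pg$gene_idx]) else 0
    if (length(pg$sig_ids) && !is.null(cm$schedule))
      a <- a + sum(pg$q_sig * vapply(pg$sig_ids, function(s)
        signal_level(cm$schedule, s, t), 0))
    a
  }, 0)
}

#' Weighted sum of regulator levels for one gene
#'
#' A = sum over regulators of q_ij * X_ij, repressors entering through
#' negative weights; signal regulators use the supplied signal levels.
#'
#' @param weights a [weight_vector()].
#' @param target gene id.
#' @param levels named numeric vector of gene expression levels.
#' @param signals named numeric vector of signal intensities.
#' @return scalar A.
#' @export
combine_regulators <- function(weights, target, levels, signals = NULL) {
  w <- weights[weights$target == target, , drop = FALSE]
  if (nrow(w) == 0L) return(0)
  x <- numeric(nrow(w))
  for (i in seq_len(nrow(w))) {
    s <- w$source[i]
    if (!is.null(levels) && s %in% names(levels)) x[i] <- levels[[s]]
    else if (!is.null(signals) && s %in% names(signals)) x[i] <- signals[[s]]
    else stop("MissingRegulator: no level for '", s, "'")
  }
  sum(w$q * x)
}

#' Sigmoid transcription rate
#'
#' Canonical form F(A) = k1 / (1 + k2 exp(-k3 A)), saturating at k1 for
#' strongly activating input.  When repressors dominate (realised A < 0)
#' the reflected form F(A) = k1 k2 exp(k3 A) / (1 + k2 exp(k3 A)) is used,
#' which decays to 0 as A -> -Inf.  Both are written in terms of
#' u = exp(-k3 A) for overflow safety.
#'
#' @param kin list/row with k1, k2, k3 (all > 0).
#' @param A combined regulator input (scalar or vector).
#' @param dominant_negative logical, selects the reflected branch; defaults
#'   to `A < 0`.
#' @return transcription rate(s) in (0, k1), a.u./day.
#' @export
transcription_rate <- function(kin, A, dominant_negative = A < 0) {
  k1 <- kin$k1; k2 <- kin$k2; k3 <- kin$k3
  if (any(c(k1, k2, k3) <= 0) || anyNA(c(k1, k2, k3)))
    stop("InvalidKinetics: k1, k2, k3 must be strictly positive")
  u <- exp(-k3 * A)
  ifelse(dominant_negative, k1 * k2 / (u + k2), k1 / (1 + k2 * u))
}

#' Derivative of the transcription rate with respect to A
#'
#' Analytic dF/dA for both sigmoid branches; used by the Jacobian-based
#' regulator importance ranking.
#'
#' @inheritParams transcription_rate
#' @return dF/dA (a.u./day per a.u.).
#' @export
transcription_rate_deriv <- function(kin, A, dominant_negative = A < 0) {
  k1 <- kin$k1; k2 <- kin$k2; k3 <- kin$k3
  u <- exp(-k3 * A)
  ifelse(dominant_negative,
         k1 * k2 * k3 * u / (u + k2)^2,
         k1 * k2 * k3 * u / (1 + k2 * u)^2)
}

#' Constitutive transcription rate
#'
#' Rate of a gene with no declared regulators: the sigmoid evaluated at
#' A = 0, i.e. k1 / (1 + k2), a constant in (0, k1).
#'
#' @param kin list/row with k1, k2 (> 0).
#' @return constant rate, a.u./day.
#' @export
constitutive_rate <- function(kin) {
  if (any(c(kin$k1, kin$k2) <= 0))
    stop("InvalidKinetics: k1, k2 must be strictly positive")
  kin$k1 / (1 + kin$k2)
}

# rhs on a compiled model: dY_i/dt = F_i(A_i(t)) - d_i Y_i
.rhs_compiled <- function(cm, y, t) {
  A <- .combined_inputs(cm, y, t)
  k1 <- cm$kin[, "k1"]; k2 <- cm$kin[, "k2"]; k3 <- cm$kin[, "k3"]
  cons <- is.na(A)
  Fv <- numeric(length(y))
  Fv[cons] <- k1[cons] / (1 + k2[cons])
  if (any(!cons)) {
    a <- A[!cons]
    u <- exp(-k3[!cons] * a)
    Fv[!cons] <- ifelse(a < 0,
                        k1[!cons] * k2[!cons] / (u + k2[!cons]),
                        k1[!cons] / (1 + k2[!cons] * u))
  }
  Fv - cm$kin[, "d"] * y
}

#' Right-hand side of the regulatory ODE system
#'
#' dY_i/dt = F_i(A_i(t)) - d_i Y_i: sigmoid transcription driven by the
#' weighted regulator sum, minus first-order mRNA degradation.
#'
#' @param model a [grn_model()].
#' @param levels named numeric vector of gene levels (model state).
#' @param t time (day); signals are evaluated here.
#' @return named vector of derivatives (a.u./day).
#' @export
grn_rhs <- function(model, levels, t = 0) {
  cm <- .compile_model(model)
  y <- as.numeric(levels[cm$genes])
  if (anyNA(y)) stop("state does not cover all genes")
  stats::setNames(.rhs_compiled(cm, y, t), cm$genes)
}

#' Simulate the regulatory ODE system
#'
#' Integrates the stiff system with an implicit multistep (BDF, Gear-type)
#' method.  Small negative solver excursions are clamped to zero in the
#' returned trajectory only.
#'
#' @param model a [grn_model()].
#' @param init named vector of initial gene levels.
#' @param times increasing vector of days, first entry the initial time.
#' @param rtol,atol solver tolerances.
#' @param method deSolve integration method (default `"bdf"`).
#' @return matrix time x gene with a leading `time` column attribute
#'   removed: rows are `times`, columns genes.
#' @export
simulate_grn <- function(model, init, times, rtol = 1e-6, atol = 1e-8,
                         method = "bdf") {
  cm <- .compile_model(model)
  y0 <- as.numeric(init[cm$genes])
  if (anyNA(y0)) stop("init does not cover all genes")
  sol <- try(deSolve::ode(y = stats::setNames(y0, cm$genes), times = times,
                          func = function(t, y, p) list(.rhs_compiled(cm, y, t)),
                          parms = NULL, method = method,
                          rtol = rtol, atol = atol), silent = TRUE)
  if (inherits(sol, "try-error") || anyNA(sol))
    stop("IntegrationError: ", if (inherits(sol, "try-error"))
      attr(sol, "condition")$message else "solver produced NA")
  out <- unclass(sol)[, -1L, drop = FALSE]
  out[out < 0] <- 0
  rownames(out) <- format(times, trim = TRUE)
  out
}

#' Locate an equilibrium of the regulatory system
#'
#' Integrates from `init` over an adequately long horizon (default t = 100,
#' i.e. day 98 after induction when starting at day -2) and polishes the
#' endpoint by damped least-squares (trust-region style) root finding on
#' the right-hand side.
#'
#' @param model a [grn_model()]; signals are evaluated at the horizon, so
#'   scans normally pass a signal-free model.
#' @param init named vector of initial levels.
#' @param horizon integration length in days (default 100).
#' @param tol required sup-norm of the right-hand side at the solution.
#' @return named vector of equilibrium levels.
#' @export
find_equilibrium <- function(model, init, horizon = 100, tol = 1e-8) {
  if (horizon <= 0) stop("horizon must be > 0")
  cm <- .compile_model(model)
  y <- as.numeric(init[cm$genes])
  t_end <- 0
  # slow passages (saddle-node ghosts) can leave the state in transit at
  # the first horizon; keep integrating before giving up
  for (round in 1:5) {
    traj <- simulate_grn(model, stats::setNames(y, cm$genes),
                         times = c(t_end, t_end + horizon))
    y <- traj[nrow(traj), ]
    t_end <- t_end + horizon
    fit <- suppressWarnings(minpack.lm::nls.lm(
      par = y,
      fn = function(p) .rhs_compiled(cm, p, t_end),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15)))
    if (max(abs(.rhs_compiled(cm, fit$par, t_end))) < tol) {
      return(stats::setNames(pmax(fit$par, 0), cm$genes))
    }
  }
  r <- .rhs_compiled(cm, y, t_end)
  stop("EquilibriumNotFound: residual ", format(max(abs(r))))
}

#' Write a trajectory as TSV
#'
#' @param trajectory matrix as returned by [simulate_grn()].
#' @param times the day grid used.
#' @param path output path.
#' @export
write_trajectory <- function(trajectory, times, path) {
  tab <- data.frame(time = times, trajectory, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read model parameters (kinetics, weights, schedule) as JSON
#'
#' @param model a [grn_model()].
#' @param path file path.
#' @export
write_model <- function(model, path) {
  kin <- data.frame(gene = rownames(model$kinetics),
                    model$kinetics, row.names = NULL)
  jsonlite::write_json(
    list(genes = model$net$genes, signals = model$net$signals,
         regulations = model$net$regulations, kinetics = kin,
         weights = as.data.frame(model$weights),
         schedule = if (is.null(model$schedule)) NULL else
           lapply(unclass(model$schedule), function(e) e)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- regulatory_network(x$genes, x$regulations, signals = x$signals)
  kin <- gene_kinetics(x$kinetics$gene, x$kinetics$k1, x$kinetics$k2,
                       x$kinetics$k3, x$kinetics$d)
  w <- weight_vector(net, q = x$weights$q)
  sch <- if (is.null(x$schedule) || length(x$schedule) == 0) NULL else
    do.call(signal_schedule, x$schedule)
  grn_model(net, kin, w, schedule = sch)
}
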