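#' Specification for synthetic network/time-series generation
#'
#' Describes the statistical shape of generated benchmark data: network
#' size and density, repressor fraction, the day grid (default the
#' human-style 9-point adipogenesis grid), the multiplicative noise level
#' and the expression floor.
#'
#' @param n_genes number of genes (>= 2).
#' @param edge_density fraction of ordered non-self gene pairs carrying a
#'   regulation, in (0, 1].
#' @param fraction_repressors fraction of edges that repress.
#' @param timepoints increasing day grid (default the human adipogenesis
#'   days -2, 0, 1, 2, 3, 5, 7, 9, 14).
#' @param noise_cv coefficient of variation of the multiplicative
#'   log-normal observation noise (>= 0).
#' @param floor truncation floor (default 20).
#' @param seed integer seed making every draw reproducible.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes, edge_density = 0.25,
                           fraction_repressors = 0.25,
                           timepoints = c(-2, 0, 1, 2, 3, 5, 7, 9, 14),
                           noise_cv = 0.1, floor = 20, seed = 1) {
  if (n_genes < 2) stop("ConfigError: need n_genes >= 2")
  if (edge_density <= 0 || edge_density > 1)
    stop("ConfigError: edge_density must be in (0, 1]")
  if (fraction_repressors < 0 || fraction_repressors > 1)
    stop("ConfigError: fraction_repressors must be in [0, 1]")
  if (noise_cv < 0) stop("ConfigError: noise_cv must be >= 0")
  if (any(diff(timepoints) <= 0))
    stop("ConfigError: timepoints must be increasing")
  structure(list(n_genes = n_genes, edge_density = edge_density,
                 fraction_repressors = fraction_repressors,
                 timepoints = timepoints, noise_cv = noise_cv,
                 floor = floor, seed = seed),
            class = "synthetic_spec")
}

#' Generate a random signed regulatory network
#'
#' Each ordered non-self gene pair carries a regulation with probability
#' `edge_density`; each edge represses with probability
#' `fraction_repressors`.  When the sampled graph leaves no gene
#' constitutive and the graph is not explicitly complete
#' (`edge_density < 1`), the incoming edges of the first such gene are
#' removed so the system keeps an exogenous driver.
#'
#' @param spec a [synthetic_spec()].
#' @return a [regulatory_network()].
#' @export
generate_network <- function(spec) {
  set.seed(spec$seed)
  genes <- sprintf("g%02d", seq_len(spec$n_genes))
  pairs <- expand.grid(source = genes, target = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- stats::runif(nrow(pairs)) <= spec$edge_density
  if (!any(keep)) stop("ConfigError: density produced zero edges")
  reg <- pairs[keep, ]
  reg$sign <- ifelse(stats::runif(nrow(reg)) < spec$fraction_repressors,
                     -1, 1)
  reg$frozen <- FALSE
  if (spec$edge_density < 1 &&
      length(setdiff(genes, unique(reg$target))) == 0L)
    reg <- reg[reg$target != genes[1L], ]
  regulatory_network(genes, reg)
}

#' Simulate a noisy expression time series from a model
#'
#' Integrates the model from a (seeded) random initial state, samples the
#' trajectory at the spec's day grid, applies multiplicative log-normal
#' noise with the requested coefficient of variation, and truncates at
#' the floor.  Log-normal noise respects the positivity of expression.
#'
#' @param net a [regulatory_network()].
#' @param kinetics a [gene_kinetics()].
#' @param weights a [weight_vector()].
#' @param spec a [synthetic_spec()].
#' @param init optional named initial state; default uniform on
#'   [floor, 10 * floor].
#' @param schedule optional [signal_schedule()].
#' @return an [expression_series()].
#' @export
generate_timeseries <- function(net, kinetics, weights, spec,
                                init = NULL, schedule = NULL) {
  set.seed(spec$seed)
  model <- grn_model(net, kinetics, weights, schedule = schedule)
  if (is.null(init))
    init <- stats::setNames(
      stats::runif(length(net$genes), spec$floor, 10 * spec$floor),
      net$genes)
  traj <- simulate_grn(model, init, spec$timepoints)
  vals <- t(traj)                       # gene x time
  if (spec$noise_cv > 0) {
    sigma <- sqrt(log(1 + spec$noise_cv^2))
    vals <- vals * exp(matrix(stats::rnorm(length(vals), 0, sigma),
                              nrow(vals)))
  }
  rownames(vals) <- net$genes
  expression_series(vals, spec$timepoints, floor = spec$floor)
}

#' Curated recovery cases for end-to-end testing
#'
#' Four seed-stable bundles of (network, true parameters, series,
#' expected diagnostics):
#' * `"cascade3"` - a three-gene feed-forward cascade (constitutive driver
#'   g1, g1 -> g2, g1/g2 -> g3) sampled noiselessly at 20 daily
#'   timepoints; the truth records the per-target weight signs and
#'   rankings for recovery checks.
#' * `"feedback_bistable2"` - a self-activating gene with a downstream
#'   reporter; bistable at the reference parameters (two stable fixed
#'   points, verifiable by brute-force 1-D enumeration).
#' * `"adipo_mini5"` - a five-gene miniature of the adipogenesis motif
#'   (stimulus-driven marker cascade locked by positive feedback, one
#'   constitutive repressor) with a pulse stimulus schedule; behavioural
#'   at the reference parameters.
#' * `"model1_like15"` - the full 15-gene model1 topology with invented
#'   parameters (synthetic stand-ins, not fitted values) for end-to-end
#'   smoke testing.
#'
#' @param name one of the four case names.
#' @return list with `name`, `net`, `kinetics`, `weights`, `schedule`,
#'   `spec`, `series`, `truth`.
#' @export
make_recovery_case <- function(name = c("cascade3", "feedback_bistable2",
                                        "adipo_mini5", "model1_like15")) {
  if (!is.character(name) || !name[1] %in%
      c("cascade3", "feedback_bistable2", "adipo_mini5", "model1_like15"))
    stop("ConfigError: unknown case '", name[1], "'")
  name <- name[1]
  switch(name,
    cascade3 = {
      genes <- c("g1", "g2", "g3")
      reg <- rbind(regulation("g1", "g2", 1),
                   regulation("g1", "g3", 1),
                   regulation("g2", "g3", 1))
      net <- regulatory_network(genes, reg)
      kin <- gene_kinetics(genes,
                           k1 = c(200, 300, 400),
                           k2 = c(1, 1, 1),
                           k3 = c(1, 1, 0.5),
                           d = c(0.25, 0.8, 0.35))
      w <- weight_vector(net, q = c(0.01, 0.02, 0.001))
      spec <- synthetic_spec(3, timepoints = 0:19, noise_cv = 0,
                             seed = 401)
      series <- generate_timeseries(net, kin, w, spec,
                                    init = c(g1 = 50, g2 = 50, g3 = 50))
      list(name = name, net = net, kinetics = kin, weights = w,
           schedule = NULL, spec = spec, series = series,
           truth = list(signs = stats::setNames(w$q > 0,
                                                paste(w$target, w$source)),
                        ranking_g3 = c("g1", "g2")))
    },
    feedback_bistable2 = {
      genes <- c("gA", "gB")
      reg <- rbind(regulation("gA", "gA", 1),
                   regulation("gA", "gB", 1))
      net <- regulatory_network(genes, reg)
      kin <- gene_kinetics(genes,
                           k1 = c(30, 30),
                           k2 = c(150, 1),
                           k3 = c(0.05, 0.02),
                           d = c(0.12, 0.3))
      w <- weight_vector(net, q = c(1, 1))
      spec <- synthetic_spec(2, timepoints = 0:12, noise_cv = 0,
                             seed = 402)
      series <- generate_timeseries(net, kin, w, spec,
                                    init = c(gA = 120, gB = 30))
      list(name = name, net = net, kinetics = kin, weights = w,
           schedule = NULL, spec = spec, series = series,
           truth = list(n_stable = 2, control_gene = "gA",
                        control_param = "k1",
                        scan_grid = seq(60, 160, by = 10),
                        init_low = c(gA = 5, gB = 5),
                        init_high = c(gA = 2000, gB = 100)))
    },
    adipo_mini5 = {
      genes <- c("mD", "mB", "mA", "mP", "mR")
      reg <- rbind(regulation("cAMP", "mB", 1),
                   regulation("mD", "mB", 1),
                   regulation("mP", "mB", 1),
                   regulation("mB", "mA", 1),
                   regulation("mP", "mA", 1),
                   regulation("mA", "mP", 1),
                   regulation("mB", "mP", 1),
                   regulation("mR", "mP", -1))
      net <- regulatory_network(genes, reg, signals = "cAMP")
      sch <- signal_schedule(
        cAMP = list(type = "pulse", onset = 0, offset = 3, value_on = 1))
      kin <- gene_kinetics(genes,
                           k1 = c(30, 300, 350, 400, 25),
                           k2 = c(1, 60, 60, 60, 1),
                           k3 = c(1, 1, 0.015, 0.015, 1),
                           d = c(0.3, 0.35, 0.35, 0.4, 0.25))
      w <- weight_vector(net,
                         q = c(6, 0.004, 0.004, 1, 1, 1, 1, -0.1))
      spec <- synthetic_spec(5, timepoints = c(-2, 0, 1, 2, 3, 5, 7, 9, 14),
                             noise_cv = 0, seed = 403)
      series <- generate_timeseries(net, kin, w, spec,
                                    init = stats::setNames(
                                      c(50, 20, 34, 33, 50), genes),
                                    schedule = sch)
      list(name = name, net = net, kinetics = kin, weights = w,
           schedule = sch, spec = spec, series = series,
           truth = list(behavioral = TRUE, markers = c("mB", "mA", "mP")))
    },
    model1_like15 = {
      net <- build_adipogenesis_network("model1", "mouse")
      set.seed(404)
      genes <- net$genes
      kin <- gene_kinetics(genes,
                           k1 = stats::runif(15, 200, 600),
                           k2 = stats::runif(15, 1, 5),
                           k3 = stats::runif(15, 0.002, 0.01),
                           d = stats::runif(15, 0.2, 0.5))
      q <- net$regulations$sign * stats::runif(nrow(net$regulations),
                                               0.2, 1)
      w <- weight_vector(net, q = q)
      sch <- default_signal_schedule("mouse", intensity = 100)
      spec <- synthetic_spec(15, timepoints = c(-2, 0, 1, 2, 3, 5, 7, 9, 14),
                             noise_cv = 0.05, seed = 404)
      series <- generate_timeseries(net, kin, w, spec,
                                    init = stats::setNames(
                                      stats::runif(15, 50, 300), genes),
                                    schedule = sch)
      list(name = name, net = net, kinetics = kin, weights = w,
           schedule = sch, spec = spec, series = series,
           truth = list(smoke = TRUE))
    })
}
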