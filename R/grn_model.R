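#' Signed transcription-factor -> target regulation
#'
#' @param source regulator id (a gene or an external signal).
#' @param target regulated gene id.
#' @param sign +1 for activation, -1 for repression.
#' @param frozen logical; a frozen regulation keeps weight 0 throughout
#'   fitting (used e.g. for human GATA2, whose expression sits at the
#'   truncation floor).
#' @return one-row data frame with columns source, target, sign, frozen.
#' @export
regulation <- function(source, target, sign, frozen = FALSE) {
  if (!nzchar(source)) stop("regulation source must be non-empty")
  if (!sign %in% c(-1, 1)) stop("regulation sign must be +1 or -1")
  data.frame(source = source, target = target, sign = as.numeric(sign),
             frozen = frozen, stringsAsFactors = FALSE)
}

#' Gene regulatory network topology
#'
#' Holds the gene list, the signed regulations and the external signal ids.
#' Genes without incoming regulations are constitutive (transcribed at a
#' constant basal rate).  Construction is permissive; use
#' [validate_network()] to obtain a report of invariant violations.
#'
#' @param genes character vector of gene ids (order defines the state order).
#' @param regulations data frame with columns source, target, sign and
#'   optionally frozen; rows as produced by [regulation()].
#' @param signals character vector of external signal ids (e.g. cAMP, GR, IR).
#' @return object of class `regulatory_network`.
#' @export
regulatory_network <- function(genes, regulations, signals = character()) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicated gene ids")
  if (is.null(regulations) || nrow(regulations) == 0L) {
    regulations <- data.frame(source = character(), target = character(),
                              sign = numeric(), frozen = logical(),
                              stringsAsFactors = FALSE)
  }
  if (is.null(regulations$frozen)) regulations$frozen <- FALSE
  regulations <- regulations[, c("source", "target", "sign", "frozen")]
  rownames(regulations) <- NULL
  structure(list(genes = genes, regulations = regulations,
                 signals = as.character(signals)),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("regulatory_network: %d genes, %d regulations, %d signals\n",
              length(x$genes), nrow(x$regulations), length(x$signals)))
  cons <- constitutive_genes(x)
  if (length(cons))
    cat("constitutive:", paste(cons, collapse = ", "), "\n")
  invisible(x)
}

#' Genes with no incoming regulation
#' @param net a [regulatory_network()].
#' @return character vector of constitutive gene ids.
#' @export
constitutive_genes <- function(net) {
  setdiff(net$genes, unique(net$regulations$target))
}

#' Regulators (genes and signals) of one target gene
#' @param net a [regulatory_network()].
#' @param target gene id.
#' @return data frame of the target's regulation rows.
#' @export
regulators_of <- function(net, target) {
  net$regulations[net$regulations$target == target, , drop = FALSE]
}

#' Report violations of the network invariants
#'
#' Checks that every regulation endpoint is a declared gene or signal, that
#' no target lists the same regulator twice, and that signs are +/-1.
#'
#' @param net a [regulatory_network()].
#' @return character vector of violation messages; empty if well formed.
#' @export
validate_network <- function(net) {
  v <- character()
  reg <- net$regulations
  known <- c(net$genes, net$signals)
  for (i in seq_len(nrow(reg))) {
    if (!nzchar(reg$source[i]))
      v <- c(v, sprintf("edge %d: empty source", i))
    else if (!reg$source[i] %in% known)
      v <- c(v, sprintf("edge %s->%s: undeclared source", reg$source[i], reg$target[i]))
    if (!reg$target[i] %in% net$genes)
      v <- c(v, sprintf("edge %s->%s: undeclared target", reg$source[i], reg$target[i]))
    if (!reg$sign[i] %in% c(-1, 1))
      v <- c(v, sprintf("edge %s->%s: sign %s not in {-1,+1}",
                        reg$source[i], reg$target[i], reg$sign[i]))
  }
  key <- paste(reg$source, reg$target)
  dup <- unique(key[duplicated(key)])
  for (k in dup)
    v <- c(v, sprintf("duplicated regulator for target: %s", k))
  v
}

# gene ids of the adipogenesis models (Model 1 / Model 2); the three key
# differentiation markers are CEBPB, CEBPA and PPARG
.adipo_genes <- c("CEBPB", "CEBPA", "PPARG", "CEBPD", "CREB1", "CREB3",
                  "CREB5", "KLF4", "KLF5", "KLF15", "KLF2", "GATA2",
                  "GATA3", "STAT5A", "STAT5B")
# anti-adipogenic factors: their outgoing regulations default to repression
.adipo_anti <- c("KLF4", "GATA2", "GATA3", "KLF2")

#' Built-in adipogenesis network topologies
#'
#' Constructs the 15-gene adipogenesis regulatory network.  `model1` is the
#' literature-curated core: CEBPB is regulated by CREB3, CREB1, PPARG, KLF4
#' and CREB5 (plus the cAMP and GR signals); CEBPA by CEBPD, CEBPB, GATA3,
#' PPARG and GATA2; PPARG by STAT5B, STAT5A, CEBPB, CEBPD, CEBPA, KLF15,
#' KLF5, GATA2, KLF2 and GATA3 (plus the IR signal).  `model2` adds five
#' candidate feedbacks from the key markers to the strongly differentially
#' expressed genes KLF4, GATA2, STAT5A, STAT5B and KLF15.  Regulations
#' sourced from the anti-adipogenic factors (KLF4, GATA2, GATA3, KLF2)
#' default to repression, all others to activation; both the signs and the
#' feedback sources can be overridden.  For `species = "human"` every
#' GATA2-sourced regulation is frozen at weight zero, since the human GATA2
#' profile is truncated at the expression floor.
#'
#' @param variant `"model1"` (core) or `"model2"` (core + 5 feedbacks).
#' @param species `"human"` or `"mouse"`.
#' @param sign_overrides optional data frame (source, target, sign)
#'   replacing default edge signs.
#' @param feedback_edges optional data frame (source, target, sign)
#'   replacing the default five model2 feedback edges.
#' @return a [regulatory_network()].
#' @export
build_adipogenesis_network <- function(variant = c("model1", "model2"),
                                       species = c("human", "mouse"),
                                       sign_overrides = NULL,
                                       feedback_edges = NULL) {
  if (!is.character(variant) || !variant[1] %in% c("model1", "model2"))
    stop("ConfigError: unknown variant '", variant[1], "'")
  if (!is.character(species) || !species[1] %in% c("human", "mouse"))
    stop("ConfigError: unknown species '", species[1], "'")
  variant <- variant[1]; species <- species[1]

  core <- rbind(
    data.frame(source = c("CREB3", "CREB1", "PPARG", "KLF4", "CREB5",
                          "cAMP", "GR"),
               target = "CEBPB", stringsAsFactors = FALSE),
    data.frame(source = c("CEBPD", "CEBPB", "GATA3", "PPARG", "GATA2"),
               target = "CEBPA", stringsAsFactors = FALSE),
    data.frame(source = c("STAT5B", "STAT5A", "CEBPB", "CEBPD", "CEBPA",
                          "KLF15", "KLF5", "GATA2", "KLF2", "GATA3", "IR"),
               target = "PPARG", stringsAsFactors = FALSE))
  core$sign <- ifelse(core$source %in% .adipo_anti, -1, 1)

  if (variant == "model2") {
    if (is.null(feedback_edges)) {
      feedback_edges <- data.frame(
        source = c("PPARG", "CEBPA", "CEBPB", "CEBPA", "CEBPB"),
        target = c("STAT5A", "STAT5B", "KLF4", "KLF15", "GATA2"),
        sign = c(1, 1, -1, 1, -1), stringsAsFactors = FALSE)
    }
    core <- rbind(core, feedback_edges[, c("source", "target", "sign")])
  }

  if (!is.null(sign_overrides)) {
    for (i in seq_len(nrow(sign_overrides))) {
      hit <- core$source == sign_overrides$source[i] &
        core$target == sign_overrides$target[i]
      core$sign[hit] <- sign_overrides$sign[i]
    }
  }
  core$frozen <- if (species == "human") core$source == "GATA2" else FALSE
  regulatory_network(.adipo_genes, core, signals = c("cAMP", "GR", "IR"))
}

#' External-signal schedule
#'
#' Describes the time course of each external stimulus.  Three profile
#' types are supported: `"pulse"` - active on `[onset, offset)`, the level
#' moving linearly from `value_on` at onset to `value_off` at offset, zero
#' outside (the human cAMP/GR stimuli, which decrease from induction to the
#' immature-adipocyte stage and are withdrawn there); `"constant"` - the
#' constant `value_on` on `[onset, offset]` and zero outside (the mouse
#' stimuli, whose intermediate data are unavailable); `"persistent"` - zero
#' before onset and `value_on` from onset onwards (insulin-receptor
#' signalling, which switches on at the immature-adipocyte stage).
#'
#' @param ... named signal entries, each a list with fields `type`,
#'   `onset`, `offset` (not needed for persistent) and `value_on`
#'   (`value_off` for pulses, default 0).
#' @return object of class `signal_schedule`.
#' @examples
#' sch <- signal_schedule(
#'   cAMP = list(type = "pulse", onset = 0, offset = 3, value_on = 1),
#'   IR   = list(type = "persistent", onset = 3, value_on = 1))
#' signal_level(sch, "cAMP", c(-1, 0, 1.5, 3, 5))
#' @export
signal_schedule <- function(...) {
  entries <- list(...)
  if (length(entries) == 1L && is.null(names(entries)) &&
      is.list(entries[[1L]]) && !is.null(names(entries[[1L]])) &&
      !all(c("type", "value_on") %in% names(entries[[1L]])))
    entries <- entries[[1L]]
  for (nm in names(entries)) {
    e <- entries[[nm]]
    if (!e$type %in% c("pulse", "constant", "persistent"))
      stop("ConfigError: unknown profile type '", e$type, "' for ", nm)
    if (is.null(e$value_off)) entries[[nm]]$value_off <- 0
    if (e$type != "persistent") {
      if (is.null(e$offset) || e$onset >= e$offset)
        stop("ConfigError: need onset < offset for ", nm)
      if (e$type == "pulse" && entries[[nm]]$value_off > e$value_on)
        stop("ConfigError: pulse profile must be non-increasing for ", nm)
    }
    if (e$value_on < 0) stop("ConfigError: negative intensity for ", nm)
  }
  structure(entries, class = "signal_schedule")
}

#' Default stimulus schedules for the adipogenesis models
#'
#' cAMP and GR act from induction (day 0) until the immature-adipocyte
#' stage (day 3 human, day 2 mouse): linearly decreasing for human,
#' constant for mouse.  IR switches on at the immature-adipocyte stage and
#' stays on.
#'
#' @param species `"human"` or `"mouse"`.
#' @param intensity peak signal intensity (a.u., default 1).
#' @return a [signal_schedule()].
#' @export
default_signal_schedule <- function(species = c("human", "mouse"),
                                    intensity = 1) {
  species <- match.arg(species)
  off <- if (species == "human") 3 else 2
  type <- if (species == "human") "pulse" else "constant"
  signal_schedule(
    cAMP = list(type = type, onset = 0, offset = off, value_on = intensity),
    GR   = list(type = type, onset = 0, offset = off, value_on = intensity),
    IR   = list(type = "persistent", onset = off, value_on = intensity))
}

#' Evaluate a signal's intensity at given times
#'
#' @param schedule a [signal_schedule()].
#' @param signal signal id.
#' @param t numeric vector of days.
#' @return numeric vector of intensities (a.u.), zero wherever inactive.
#' @export
signal_level <- function(schedule, signal, t) {
  e <- schedule[[signal]]
  if (is.null(e)) stop("unknown signal id '", signal, "'")
  t <- as.numeric(t)
  switch(e$type,
    pulse = ifelse(t >= e$onset & t < e$offset,
                   e$value_on + (e$value_off - e$value_on) *
                     (t - e$onset) / (e$offset - e$onset), 0),
    constant = ifelse(t >= e$onset & t <= e$offset, e$value_on, 0),
    persistent = ifelse(t >= e$onset, e$value_on, 0))
}

#' Write / read a network topology as JSON
#'
#' The canonical on-disk form lists nodes, signed edges (with the frozen
#' flag) and signals.
#'
#' @param net a [regulatory_network()].
#' @param path file path.
#' @export
write_network <- function(net, path) {
  jsonlite::write_json(
    list(genes = net$genes, signals = net$signals,
         regulations = net$regulations),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  regulatory_network(x$genes, x$regulations, signals = x$signals)
}

#' Import / export a network in SIF format
#'
#' Lines of the form `source activates|represses target`.  Signals must be
#' declared separately since SIF does not distinguish node types.
#'
#' @param path file path.
#' @param signals character vector of node ids to treat as signals.
#' @export
read_sif <- function(path, signals = character()) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- vapply(parts, length, 0L) != 3L
  if (any(bad)) stop("ParseError: malformed SIF line(s)")
  src <- vapply(parts, `[`, "", 1L)
  rel <- vapply(parts, `[`, "", 2L)
  tgt <- vapply(parts, `[`, "", 3L)
  if (!all(rel %in% c("activates", "represses")))
    stop("ParseError: relation must be 'activates' or 'represses'")
  reg <- data.frame(source = src, target = tgt,
                    sign = ifelse(rel == "activates", 1, -1),
                    frozen = FALSE, stringsAsFactors = FALSE)
  genes <- setdiff(unique(c(src, tgt)), signals)
  regulatory_network(genes, reg, signals = signals)
}

#' @rdname read_sif
#' @param net a [regulatory_network()] to export.
#' @export
write_sif <- function(net, path) {
  rel <- ifelse(net$regulations$sign > 0, "activates", "represses")
  writeLines(paste(net$regulations$source, rel, net$regulations$target),
             path)
  invisible(path)
}

#' Per-gene sigmoid kinetics parameters
#'
#' One row per gene: `k1` the maximal transcription rate (a.u./day), `k2`
#' and `k3` the shape and steepness coefficients of the sigmoid, `d` the
#' first-order degradation rate constant (1/day).  All strictly positive.
#'
#' @param genes character vector of gene ids.
#' @param k1,k2,k3,d numeric vectors recycled to `length(genes)`.
#' @return data frame of class `gene_kinetics` with gene rownames.
#' @export
gene_kinetics <- function(genes, k1, k2 = 1, k3 = 1, d = 0.35) {
  n <- length(genes)
  kin <- data.frame(k1 = rep_len(as.numeric(k1), n),
                    k2 = rep_len(as.numeric(k2), n),
                    k3 = rep_len(as.numeric(k3), n),
                    d = rep_len(as.numeric(d), n),
                    row.names = genes)
  if (any(as.matrix(kin) <= 0) || anyNA(kin))
    stop("InvalidKinetics: k1, k2, k3 and d must be strictly positive")
  class(kin) <- c("gene_kinetics", "data.frame")
  kin
}

#' Per-edge regulatory weight vector
#'
#' Holds one weight q per regulation of the network, keyed by (target,
#' source).  Frozen regulations keep q = 0.  Initial weights default to
#' sign * init so the sign constraint holds from the start.
#'
#' @param net a [regulatory_network()].
#' @param q optional numeric vector of weights, one per regulation row of
#'   `net$regulations` (frozen entries are zeroed).
#' @param init magnitude used when `q` is not given (default 0.001).
#' @return data frame of class `weight_vector` with columns target, source,
#'   sign, frozen, q.
#' @export
weight_vector <- function(net, q = NULL, init = 1e-3) {
  w <- net$regulations[, c("target", "source", "sign", "frozen")]
  if (is.null(q)) q <- w$sign * init
  if (length(q) != nrow(w))
    stop("KeyMismatch: need one weight per regulation")
  w$q <- as.numeric(q)
  w$q[w$frozen] <- 0
  rownames(w) <- NULL
  class(w) <- c("weight_vector", "data.frame")
  w
}

#' Look up the weights feeding one target gene
#' @param weights a [weight_vector()].
#' @param target gene id.
#' @return the target's weight rows.
#' @export
weights_of <- function(weights, target) {
  weights[weights$target == target, , drop = FALSE]
}
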