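#' Layer specification for the synthetic generator
#'
#' @param name layer name (also the interaction class written into
#'   records: `grooming`, `proximity` or `agonism` map onto the behaviour
#'   codes; other names are allowed for matrix-only use).
#' @param kind `"duration"` (timed bouts, seconds) or `"count"` (point
#'   events).
#' @param event_rate expected events per dyadic observation hour at unit
#'   propensity (nu > 0).
#' @param mean_bout_s mean bout length in seconds (duration kind only).
#' @param redundancy weight lambda in `[0, 1]` on the shared latent dyadic
#'   affinity: 1 = the layer follows the shared affinity exactly, 0 = fully
#'   independent.
#' @param duplicate_of optional name of an earlier layer whose realized
#'   events are copied exactly (copy mode).
#' @param p_aggression for `count` layers, probability that an event is an
#'   `aggression` record rather than `supplant_avoid`.
#' @return a `layer_spec` list.
#' @export
layer_spec <- function(name, kind = c("duration", "count"),
                       event_rate = 1, mean_bout_s = 60,
                       redundancy = 0.5, duplicate_of = NULL,
                       p_aggression = 0.08) {
  kind <- match.arg(kind)
  stopifnot(event_rate > 0, redundancy >= 0, redundancy <= 1)
  if (kind == "duration") stopifnot(mean_bout_s > 0)
  structure(list(name = name, kind = kind, event_rate = event_rate,
                 mean_bout_s = mean_bout_s, redundancy = redundancy,
                 duplicate_of = duplicate_of, p_aggression = p_aggression),
            class = "layer_spec")
}

#' Synthetic focal-sampling configuration
#'
#' Defaults emulate one observation period of a small matriline of mature
#' females: 6 individuals watched 16 focal hours each, three interaction
#' layers (timed grooming, timed feeding proximity, counted agonism) whose
#' rates reproduce realistic per-dyadic-hour magnitudes (tens of grooming
#' seconds, a few proximity seconds, around one agonistic episode). Latent
#' dyadic affinities are Gamma distributed with a skewed shape so
#' interactions concentrate on a minority of dyads, as focal data on small
#' primate groups typically do. Grooming and proximity share most of their
#' affinity (high redundancy), agonism is mostly independent of both.
#'
#' @param n_individuals number of individuals (>= 3).
#' @param focal_hours focal observation hours, one value recycled to all
#'   individuals or a named vector.
#' @param layers list of [layer_spec()] objects (>= 1).
#' @param affinity_shape,affinity_scale Gamma parameters of the latent
#'   dyadic affinity (and of each layer's independent noise component).
#' @param seed integer RNG seed; every run with the same config is
#'   bit-identical.
#' @param period_id period label written into records.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_individuals = 6,
                         focal_hours = 16,
                         layers = list(
                           layer_spec("grooming", "duration",
                                      event_rate = 0.05, mean_bout_s = 530,
                                      redundancy = 0.6),
                           layer_spec("proximity", "duration",
                                      event_rate = 0.1, mean_bout_s = 84,
                                      redundancy = 0.6),
                           layer_spec("agonism", "count",
                                      event_rate = 0.87, redundancy = 0.1)
                         ),
                         affinity_shape = 0.5, affinity_scale = 2,
                         seed = 1, period_id = "P1") {
  stopifnot(n_individuals >= 3, length(layers) >= 1,
            affinity_shape > 0, affinity_scale > 0)
  ids <- sprintf("F%02d", seq_len(n_individuals))
  hours <- if (length(focal_hours) == 1)
    stats::setNames(rep(focal_hours, n_individuals), ids)
  else sampling_effort(focal_hours)
  stopifnot(all(hours > 0))
  names(layers) <- vapply(layers, `[[`, character(1), "name")
  for (sp in layers)
    if (!is.null(sp$duplicate_of) && !sp$duplicate_of %in% names(layers))
      stop("duplicate_of names an unknown layer: ", sp$duplicate_of,
           call. = FALSE)
  structure(list(n_individuals = n_individuals, ids = names(hours),
                 hours = hours, layers = layers,
                 affinity_shape = affinity_shape,
                 affinity_scale = affinity_scale,
                 seed = as.integer(seed), period_id = period_id),
            class = "synth_config")
}

#' Latent per-layer dyadic propensities
#'
#' Draws a shared latent affinity a(i,j) ~ Gamma(shape, scale) per dyad,
#' plus an independent noise draw e_k(i,j) from the same Gamma per layer;
#' layer k's propensity is lambda_k * a + (1 - lambda_k) * e_k. Layers in
#' copy mode (`duplicate_of`) receive the source layer's matrix verbatim.
#'
#' @param config a `synth_config`.
#' @return named list of symmetric propensity matrices, one per layer.
#' @export
generate_propensities <- function(config) {
  set.seed(config$seed)
  ids <- config$ids
  n <- length(ids)
  nd <- n * (n - 1) / 2
  a <- stats::rgamma(nd, shape = config$affinity_shape,
                     scale = config$affinity_scale)
  out <- list()
  for (sp in config$layers) {
    if (!is.null(sp$duplicate_of)) {
      out[[sp$name]] <- out[[sp$duplicate_of]]
      next
    }
    e <- stats::rgamma(nd, shape = config$affinity_shape,
                       scale = config$affinity_scale)
    p <- sp$redundancy * a + (1 - sp$redundancy) * e
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    m[upper.tri(m)] <- p
    m <- m + t(m)
    out[[sp$name]] <- m
  }
  out
}

# behaviour code(s) for a layer's events
.layer_behavior <- function(sp) {
  switch(sp$name,
         grooming = "groom",
         proximity = "feed_proximity",
         agonism = NULL,            # chosen per event (aggression / supplant)
         if (sp$kind == "duration") "groom" else "supplant_avoid")
}

#' Simulate focal observation records
#'
#' Per dyad and layer, the event count is Poisson with mean
#' nu_k * p_k(i,j) * (h_i + h_j) -- the dyad is on view whenever either
#' member is the focal. Duration-kind events draw an exponential bout
#' length with the configured mean; each event becomes one record assigned
#' to a uniformly chosen member's focal session, with actor/recipient
#' orientation randomized uniformly (all downstream analysis is
#' undirected). Fully reproducible from the config seed.
#'
#' @param config a `synth_config`.
#' @return list with `records` (a `focal_records` data frame), `effort`
#'   (named hours vector) and `propensities`.
#' @export
simulate_focal_records <- function(config) {
  prop <- generate_propensities(config)   # seeds the RNG
  ids <- config$ids
  n <- length(ids)
  pairs <- dyad_pairs(ids)
  rows <- list()
  realized <- list()   # per layer: list of per-dyad event data (for copy mode)
  for (sp in config$layers) {
    if (!is.null(sp$duplicate_of)) {
      src_sp <- config$layers[[sp$duplicate_of]]
      if (src_sp$kind != sp$kind)
        stop("duplicate_of layers must share the same kind", call. = FALSE)
      beh <- .layer_behavior(sp)
      if (is.null(beh) || identical(beh, .layer_behavior(src_sp)))
        stop("duplicate_of requires layers mapping to distinct timed ",
             "behaviour codes (e.g. grooming/proximity)", call. = FALSE)
      lay <- lapply(realized[[sp$duplicate_of]], function(ev) {
        ev$layer <- sp$name
        ev$behavior <- beh
        ev
      })
      realized[[sp$name]] <- lay
      rows <- c(rows, lay)
      next
    }
    p <- prop[[sp$name]]
    lay <- list()
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      mu <- sp$event_rate * p[i, j] * (config$hours[i] + config$hours[j])
      cnt <- stats::rpois(1, mu)
      if (cnt == 0) next
      dur <- if (sp$kind == "duration")
        stats::rexp(cnt, rate = 1 / sp$mean_bout_s) else rep(0, cnt)
      focal <- sample(c(i, j), cnt, replace = TRUE)
      flip <- stats::runif(cnt) < 0.5
      beh <- if (sp$kind == "count")
        ifelse(stats::runif(cnt) < sp$p_aggression,
               "aggression", "supplant_avoid")
      else rep(.layer_behavior(sp), cnt)
      lay[[length(lay) + 1]] <- data.frame(
        layer = sp$name,
        focal_id = focal,
        behavior = beh,
        actor_id = ifelse(flip, i, j),
        recipient_id = ifelse(flip, j, i),
        duration_s = dur,
        stringsAsFactors = FALSE)
    }
    realized[[sp$name]] <- lay
    rows <- c(rows, lay)
  }
  if (length(rows)) {
    df <- do.call(rbind, rows)
    # one 15-min session index per record, within the focal's budget
    n_sessions <- pmax(1, floor(config$hours[df$focal_id] * 4))
    sess <- floor(stats::runif(nrow(df)) * n_sessions) + 1
    records <- data.frame(
      session_id = sprintf("%s-%s-S%03d", config$period_id, df$focal_id, sess),
      period_id = config$period_id,
      focal_id = df$focal_id,
      behavior = df$behavior,
      actor_id = df$actor_id,
      recipient_id = df$recipient_id,
      duration_s = df$duration_s,
      stringsAsFactors = FALSE)
  } else {
    records <- data.frame(session_id = character(0), period_id = character(0),
                          focal_id = character(0), behavior = character(0),
                          actor_id = character(0), recipient_id = character(0),
                          duration_s = numeric(0))
  }
  # duration rounding: keep full precision; records are validated as-is
  records <- validate_focal_records(records)
  list(records = records, effort = config$hours, propensities = prop)
}

#' Write a sampling-effort table to CSV
#'
#' @param effort named hours vector.
#' @param path output path.
#' @param period_id period label.
#' @return `path`, invisibly.
#' @export
write_sampling_effort <- function(effort, path, period_id = "P1") {
  utils::write.csv(data.frame(period_id = period_id,
                              individual_id = names(effort),
                              focal_hours = as.numeric(effort)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
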